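test_that("stems are maximal runs of nested pairs", {
  ss <- parse_dotbracket("((((....))))", "GGGGAAAACCCC")
  st <- find_stems(ss)
  expect_length(st, 1)
  expect_equal(nrow(st[[1]]), 4)

  ss2 <- parse_dotbracket("((..((...))..))", strrep("G", 15))
  st2 <- find_stems(ss2)
  expect_length(st2, 2)
  expect_equal(vapply(st2, nrow, 1L), c(2L, 2L))

  expect_length(find_stems(parse_dotbracket("....", "AAAA")), 0)
})

test_that("single base pairs are opened iteratively to a fixed point", {
  # two isolated single pairs, as in a riboswitch whose pairs 10-40 and
  # 35-39 are opened to merge a large loop
  n <- 45
  pr <- rbind(c(10, 40), c(35, 39),
              c(12, 20), c(13, 19), c(14, 18),
              c(25, 33), c(26, 32))
  ss <- rna_ss(strrep("A", n), pr)
  out <- open_single_pairs(ss)
  key <- paste(out$pairs[, 1], out$pairs[, 2])
  expect_false("10 40" %in% key)
  expect_false("35 39" %in% key)
  expect_equal(nrow(out$pairs), 5)

  # a multi-pair stem is untouched
  ss2 <- parse_dotbracket("((((....))))", strrep("G", 12))
  expect_equal(open_single_pairs(ss2)$pairs, ss2$pairs)

  # nested single pairs vanish one after the other
  ss3 <- parse_dotbracket("(.(.....).)", strrep("A", 11))
  expect_equal(nrow(open_single_pairs(ss3)$pairs), 0)
})

test_that("a hairpin decomposes into a stem and a flanked hairpin loop", {
  ss <- parse_dotbracket("((((....))))", "GGGGAAAACCCC")
  recs <- decompose(ss, "lib2")
  types <- vapply(recs, function(r) r$sse_type, "")
  expect_setequal(types, c("stem", "hairpin_loop"))
  hp <- recs[[which(types == "hairpin_loop")]]
  # two innermost stem pairs annexed: residues 3,4,9,10 plus loop 5..8
  expect_equal(hp$residues, 3:10)
  expect_equal(unname(hp$flanking_pairs),
               unname(rbind(c(3L, 10L), c(4L, 9L))))
  expect_equal(hp$dot_bracket, "((....))")
  expect_equal(hp$length, 8L)
  expect_equal(hp$sequence, "GGAAAACC")
})

test_that("a three-way junction structure decomposes with tails in one open loop", {
  db <- "..((((...((((....))))...((((....))))...)))).."
  recs <- decompose(parse_dotbracket(db, strrep("A", nchar(db))), "lib2")
  types <- vapply(recs, function(r) r$sse_type, "")
  expect_equal(sum(types == "stem"), 3)
  expect_equal(sum(types == "junction"), 1)
  expect_equal(sum(types == "hairpin_loop"), 2)
  expect_equal(sum(types == "open_loop"), 1)
  jn <- recs[[which(types == "junction")]]
  expect_equal(jn$n_stems, 3L)
  op <- recs[[which(types == "open_loop")]]
  expect_true(all(c(1, 2, nchar(db) - 1, nchar(db)) %in% op$residues))
  # every residue is covered by at least one record
  expect_setequal(sort(unique(unlist(lapply(recs, `[[`, "residues")))),
                  1:nchar(db))
})

test_that("a zero-length bulge side is classified as a bulge with an empty segment", {
  # coaxial stack: child helix starts immediately after the parent's inner
  # pair on the 5' side, with unpaired residues only on the 3' side
  db <- "((((((....))..))))"
  recs <- decompose(parse_dotbracket(db, strrep("A", nchar(db))), "lib2")
  types <- vapply(recs, function(r) r$sse_type, "")
  expect_true("bulge_loop" %in% types)
  bl <- recs[[which(types == "bulge_loop")]]
  expect_equal(bl$n_stems, 2L)
  expect_equal(setdiff(bl$residues, as.vector(bl$flanking_pairs)),
               c(13L, 14L))
})

test_that("lib1 opens single pairs before identifying SSEs", {
  # single pair around a hairpin: lib2 sees two stems, lib1 merges
  db <- "(.((((....)))).)"
  sq <- strrep("G", 8) |> paste0(strrep("C", 8))
  ss <- parse_dotbracket(db, sq)
  r2 <- decompose(ss, "lib2")
  r1 <- decompose(ss, "lib1")
  t2 <- vapply(r2, function(r) r$sse_type, "")
  t1 <- vapply(r1, function(r) r$sse_type, "")
  expect_equal(sum(t2 == "stem"), 2)
  expect_equal(sum(t1 == "stem"), 1)
  # lib1: the merged exterior loop covers the formerly paired residues
  open_res <- r1[[which(t1 == "open_loop")]]$residues
  expect_true(all(c(1, 16) %in% open_res))
})

test_that("decomposition refuses pairless structures", {
  expect_error(decompose(parse_dotbracket("....", "AAAA"), "lib2"),
               "ineligible")
  expect_error(decompose(parse_dotbracket("(.......)", strrep("A", 10 - 1)),
                         "lib1"), "ineligible")
})

test_that("lib1 and lib2 agree record-for-record without single-pair stems", {
  set.seed(17)
  for (k in 1:20) {
    sp <- random_nested_ss(sample(10:60, 1))  # generator draws stems >= 2
    ss <- parse_dotbracket(sp$dotbracket, sp$sequence)
    r1 <- decompose(ss, "lib1")
    r2 <- decompose(ss, "lib2")
    expect_equal(length(r1), length(r2))
    for (q in seq_along(r1)) {
      expect_identical(r1[[q]]$sse_type, r2[[q]]$sse_type)
      expect_identical(r1[[q]]$residues, r2[[q]]$residues)
      expect_identical(r1[[q]]$dot_bracket, r2[[q]]$dot_bracket)
    }
  }
})

test_that("loop classification matches the naive stem-tree walker on random structures", {
  set.seed(19)
  for (k in 1:40) {
    n <- sample(6:30, 1)
    p <- local({
      repeat {
        m <- sample.int(n %/% 2, 1)
        pr <- random_matching(min(m, n %/% 2), n)
        ss <- rna_ss(strrep("A", n), pr)
        out <- remove_crossing_pairs(ss)$ss
        if (nrow(out$pairs) > 0) return(rnasse:::ss_partner(out))
      }
    })
    pairs <- cbind(which(p > seq_along(p)), p[p > seq_along(p)])
    ss <- rna_ss(strrep("A", n), pairs)
    recs <- decompose(ss, "lib2")
    expect_identical(record_sse_classify(recs), naive_sse_classify(p))
  }
})

test_that("partition invariants: pairs in one stem, flank residues shared", {
  db <- "..((((...((((....))))...((((....))))...)))).."
  ss <- parse_dotbracket(db, strrep("A", nchar(db)))
  recs <- decompose(ss, "lib2")
  stems <- recs[vapply(recs, function(r) r$sse_type == "stem", TRUE)]
  # every ss pair lies in exactly one stem record
  all_pairs <- paste(ss$pairs[, 1], ss$pairs[, 2])
  in_stems <- unlist(lapply(stems, function(s) {
    r <- s$residues; L <- length(r) / 2
    paste(r[seq_len(L)], rev(r[L + seq_len(L)]))
  }))
  expect_setequal(in_stems, all_pairs)
  expect_equal(anyDuplicated(in_stems), 0)
  # residues shared between a stem and a loop are exactly annexed flanks
  loops <- recs[vapply(recs, function(r) r$sse_type != "stem", TRUE)]
  for (lp in loops) {
    for (s in stems) {
      shared <- intersect(lp$residues, s$residues)
      expect_true(all(shared %in% as.vector(lp$flanking_pairs)))
    }
  }
})

test_that("attach_coordinates copies exactly the member residues", {
  fx <- fixture_chain("((((....))))")
  recs <- decompose(fx$chain$ss, "lib2")
  recs <- attach_coordinates(fx$chain, recs)
  for (r in recs) {
    expect_setequal(unique(r$atoms$res), r$residues)
    expect_equal(r$source_id, "TOYA")
  }
  hp <- recs[[which(vapply(recs, function(r) r$sse_type, "") ==
                    "hairpin_loop")]]
  expect_length(unique(hp$atoms$res), 8)
  st <- recs[[which(vapply(recs, function(r) r$sse_type, "") == "stem")]]
  expect_length(unique(st$atoms$res), 8)  # 2k residues for k = 4 pairs
  # copied, not referenced
  hp$atoms$x[1] <- 999
  expect_false(fx$chain$atoms$x[1] == 999)

  bad <- recs[[1]]
  bad$residues <- c(bad$residues, 99L)
  expect_error(attach_coordinates(fx$chain, list(bad)), "missing")
})
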