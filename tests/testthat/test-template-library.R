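make_library <- function(dbs, ids = paste0("SRC", seq_along(dbs)),
                         sqs = NULL, scheme = "lib2") {
  chains <- lapply(seq_along(dbs), function(k) {
    fixture_chain(dbs[k], sq = if (is.null(sqs)) NULL else sqs[[k]],
                  source_id = ids[k], seed = k)$chain
  })
  build_library(chains, scheme)
}

test_that("building a library from one hairpin chain gives stem + hairpin records", {
  lib <- make_library("((((....))))", "TOYA")
  expect_length(lib$records, 2)
  types <- vapply(lib$records, function(r) r$sse_type, "")
  expect_setequal(types, c("stem", "hairpin_loop"))
  expect_equal(lib$provenance$source_id, "TOYA")

  expect_length(build_library(list(), "lib2")$records, 0)
})

test_that("exact duplicate records are inserted once", {
  fx <- fixture_chain("((((....))))", source_id = "TOYA")
  dup <- fx$chain
  dup$chain_id <- "B"
  lib <- build_library(list(fx$chain, dup), "lib2")
  # identical coordinates + sequence + structure: one copy per record kind
  expect_length(lib$records, 2)
})

test_that("filter_unique keeps one representative per sequence+structure", {
  sq <- NULL
  set.seed(5); sq1 <- comp_sequence("((((....))))")
  a <- fixture_chain("((((....))))", sq = sq1, source_id = "SRCB")$chain
  b <- fixture_chain("((((....))))", sq = sq1, source_id = "SRCA")$chain
  # displace b so coordinates differ (not an exact duplicate)
  b$atoms$x <- b$atoms$x + 0.5
  lib <- build_library(list(a, b), "lib2")
  expect_length(lib$records, 4)
  fl <- filter_unique(lib)
  expect_length(fl$records, 2)
  # the lexicographically smallest source wins
  expect_true(all(vapply(fl$records, function(r) r$source_id, "") == "SRCA"))

  # same structure, different sequence: both kept
  set.seed(6); sq2 <- comp_sequence("((((....))))")
  stopifnot(sq2 != sq1)
  cc <- fixture_chain("((((....))))", sq = sq2, source_id = "SRCC")$chain
  lib2 <- build_library(list(a, cc), "lib2")
  expect_length(filter_unique(lib2)$records, 4)

  expect_length(filter_unique(build_library(list(), "lib2"))$records, 0)
})

test_that("search ranks by sequence identity with deterministic ties", {
  sq1 <- "GGGGAAAACCCC"
  a <- fixture_chain("((((....))))", sq = sq1, source_id = "SRCA")$chain
  b <- fixture_chain("((((....))))", sq = "GGGGAAUACCCC", source_id = "SRCB")$chain
  lib <- build_library(list(a, b), "lib2")
  query <- decompose(parse_dotbracket("((((....))))", sq1), "lib2")
  hp <- query[[which(vapply(query, function(r) r$sse_type, "") ==
                     "hairpin_loop")]]
  hits <- search_templates(lib, hp)
  expect_gte(length(hits), 2)
  expect_equal(hits[[1]]$source_id, "SRCA")
  expect_equal(attr(hits[[1]], "identity"), 1)

  # self-exclusion removes the own record
  hits2 <- search_templates(lib, hp, exclude_source = "SRCA")
  expect_false(any(vapply(hits2, function(r) r$source_id, "") == "SRCA"))

  # absent topology: empty result
  other <- decompose(parse_dotbracket("(((.....)))", strrep("G", 5) |>
    paste0("AAA", strrep("C", 3))), "lib2")
  expect_length(search_templates(lib, other[[2]]), 0)
})

test_that("library statistics bucket junctions by incident stem count", {
  db3 <- "..((((...((((....))))...((((....))))...)))).."
  lib <- make_library(db3, "JUNC")
  st <- library_stats(lib)
  expect_equal(st$all[st$bucket == "3wj"], 1)
  expect_equal(st$all[st$bucket == "nwj"], 0)
  expect_equal(st$all[st$bucket == "hairpin"], 2)
  expect_equal(st$all[st$bucket == "open"], 1)
  expect_equal(st$all[st$bucket == "all"], 4)

  # six-stem junction buckets as nwj
  inner <- strrep("((((....))))", 5)
  db6 <- paste0("((((", inner, "))))")
  lib6 <- make_library(db6, "BIGJ")
  st6 <- library_stats(lib6)
  expect_equal(st6$all[st6$bucket == "nwj"], 1)

  st0 <- library_stats(build_library(list(), "lib2"))
  expect_true(all(st0$all == 0) && all(st0$filter == 0))
})

test_that("update_library is idempotent and equals rebuilding from the union", {
  a <- fixture_chain("((((....))))", source_id = "SRCA", seed = 1)$chain
  b <- fixture_chain("..(((((...)))))", source_id = "SRCB", seed = 2)$chain
  libA <- build_library(list(a), "lib2")

  # already-present source is skipped
  again <- update_library(libA, list(a))
  expect_length(again$records, length(libA$records))

  # update(empty, chains) == build(chains)
  lib0 <- update_library(build_library(list(), "lib2"), list(a))
  expect_equal(length(lib0$records), length(libA$records))

  # update(build(A), B) == build(A u B) as record sets
  libAB <- update_library(libA, list(b))
  libU <- build_library(list(a, b), "lib2")
  sig <- function(lib) sort(vapply(lib$records, rnasse:::record_signature, ""))
  expect_identical(sig(libAB), sig(libU))
  expect_error(update_library(libAB, list()), NA)
})

test_that("persistence round trips records, keys and provenance exactly", {
  lib <- make_library(c("((((....))))", "..(((((...)))))"),
                      c("SRCA", "SRCB"))
  d <- tempfile(); on.exit(unlink(d, recursive = TRUE))
  save_library(lib, d)
  back <- load_library(d)
  expect_equal(back$scheme, lib$scheme)
  expect_identical(back$provenance, lib$provenance)
  expect_identical(sort(names(back$key_index)), sort(names(lib$key_index)))
  expect_length(back$records, length(lib$records))
  for (k in seq_along(lib$records)) {
    a <- lib$records[[k]]; b <- back$records[[k]]
    for (f in c("sse_type", "sequence", "dot_bracket", "length", "family",
                "source_id", "source_chain", "residues", "n_stems"))
      expect_identical(a[[f]], b[[f]], label = f)
    expect_identical(unname(a$flanking_pairs), unname(b$flanking_pairs))
    expect_equal(a$atoms$x, b$atoms$x)
    expect_equal(a$atoms$y, b$atoms$y)
    expect_equal(a$atoms$z, b$atoms$z)
  }
})

test_that("every library chain retrieves its own records at rank 1", {
  dbs <- c("((((....))))", "..(((((...)))))",
           "..((((...((((....))))...((((....))))...))))..")
  ids <- c("SRCA", "SRCB", "SRCC")
  chains <- lapply(seq_along(dbs), function(k)
    fixture_chain(dbs[k], source_id = ids[k], seed = k)$chain)
  lib <- build_library(chains, "lib2")
  for (k in seq_along(chains)) {
    recs <- decompose(chains[[k]]$ss, "lib2")
    for (q in recs) {
      hits <- search_templates(lib, q)
      expect_gte(length(hits), 1)
      expect_equal(attr(hits[[1]], "identity"), 1)
      expect_equal(hits[[1]]$source_id, ids[k])
    }
  }
})
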