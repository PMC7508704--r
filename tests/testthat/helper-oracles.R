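# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive results by enumeration or naive recursion,
# sharing no code with the package implementation.

# All nested partial matchings (partner vectors) of n positions.
enumerate_matchings <- function(n, memo = new.env(parent = emptyenv())) {
  key <- as.character(n)
  if (!is.null(memo[[key]])) return(memo[[key]])
  if (n <= 0) {
    out <- list(integer(0))
  } else {
    out <- lapply(enumerate_matchings(n - 1, memo), function(p) c(0L, p + ifelse(p > 0L, 1L, 0L)))
    # pair position 1 with k = 2..n
    for (k in 2:max(2, n)) {
      if (k > n) break
      inner <- enumerate_matchings(k - 2, memo)
      outer <- enumerate_matchings(n - k, memo)
      for (pi in inner) {
        pin <- ifelse(pi > 0L, pi + 1L, 0L)
        for (po in outer) {
          pout <- ifelse(po > 0L, po + k, 0L)
          out[[length(out) + 1]] <- c(k, pin, 1L, pout)
        }
      }
    }
  }
  memo[[key]] <- out
  out
}

# Naive stem-tree walker: classifies every loop of a nested partner vector
# by walking each region and counting incident helices.  Returns a sorted
# character vector of loop descriptors plus helix pair-run descriptors.
naive_sse_classify <- function(p) {
  n <- length(p)
  loops <- character(0)
  helices <- character(0)
  walk <- function(lo, hi, closing) {
    k <- lo
    nst <- 0L
    seg_lens <- integer(0)
    cur <- 0L
    unpaired <- integer(0)
    while (k <= hi) {
      if (p[k] == 0L) {
        cur <- cur + 1L
        unpaired <- c(unpaired, k)
        k <- k + 1L
      } else {
        nst <- nst + 1L
        seg_lens <- c(seg_lens, cur); cur <- 0L
        i <- k; j <- p[k]
        while (i + 1L < j - 1L && p[i + 1L] == j - 1L) { i <- i + 1L; j <- j - 1L }
        helices <<- c(helices, paste0(k, ":", p[k], "-", i, ":", j))
        walk(i + 1L, j - 1L, c(i, j))
        k <- p[k] + 1L
      }
    }
    seg_lens <- c(seg_lens, cur)
    type <-
      if (is.null(closing)) {
        if (length(unpaired) > 0L || nst >= 2L) "open_loop" else NA_character_
      } else if (nst == 0L) "hairpin_loop"
      else if (nst == 1L && sum(seg_lens > 0L) <= 1L) "bulge_loop"
      else if (nst == 1L) "internal_loop"
      else "junction"
    nstems <- if (is.null(closing)) nst else nst + 1L
    if (!is.na(type))
      loops <<- c(loops, paste0(type, "|", nstems, "|",
                                paste(unpaired, collapse = ",")))
    invisible(NULL)
  }
  walk(1L, n, NULL)
  list(loops = sort(loops), helices = sort(helices))
}

# Descriptors in the same vocabulary, taken from decompose() records.
record_sse_classify <- function(records) {
  loops <- character(0)
  helices <- character(0)
  for (r in records) {
    if (r$sse_type == "stem") {
      m <- r$flanking_pairs  # stems carry their pairs here? no: use segments
      pr <- r$residues
      # reconstruct the pair run from the record's residue set: outermost
      # pair = (min, max), run length = length/2
      L <- length(pr) / 2
      helices <- c(helices, paste0(pr[1], ":", pr[length(pr)], "-",
                                   pr[L], ":", pr[L + 1]))
    } else {
      unpaired <- setdiff(r$residues, as.vector(r$flanking_pairs))
      loops <- c(loops, paste0(r$sse_type, "|", r$n_stems, "|",
                               paste(sort(unpaired), collapse = ",")))
    }
  }
  list(loops = sort(loops), helices = sort(helices))
}

# Brute-force conflict resolution: enumerate all conflict-free candidate
# subsets, compare by the lexicographic sequence of member priority tuples
# (sorted best-first); longer wins on prefix equality.
brute_force_conflicts <- function(cand, sequence) {
  m <- nrow(cand)
  if (m == 0) return(cand[0, c("i", "j")])
  bases <- strsplit(sequence, "")[[1]]
  std <- function(a, b) paste0(min(bases[a], bases[b]), max(bases[a], bases[b])) %in%
    c("AU", "CG", "GU")
  key <- paste(cand$i, cand$j)
  tup <- lapply(seq_len(m), function(k) {
    i <- cand$i[k]; j <- cand$j[k]
    c(as.numeric(j - i > 4),
      as.numeric(std(i, j)),
      as.numeric(paste(i - 1, j + 1) %in% key || paste(i + 1, j - 1) %in% key),
      cand$score[k], -(j - i), -i)
  })
  better <- function(a, b) {  # compare two subsets (index vectors)
    sa <- a[order(sapply(a, function(k) paste(sprintf("%020.9f", 1e6 - unlist(tup[k])), collapse = "")))]
    sb <- b[order(sapply(b, function(k) paste(sprintf("%020.9f", 1e6 - unlist(tup[k])), collapse = "")))]
    la <- length(sa); lb <- length(sb)
    for (q in seq_len(min(la, lb))) {
      ta <- tup[[sa[q]]]; tb <- tup[[sb[q]]]
      for (z in seq_along(ta)) {
        if (ta[z] > tb[z] + 1e-12) return(TRUE)
        if (ta[z] < tb[z] - 1e-12) return(FALSE)
      }
    }
    la > lb
  }
  best <- NULL
  for (mask in 0:(2^m - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (length(idx) > 1) {
      res_used <- c(cand$i[idx], cand$j[idx])
      if (anyDuplicated(res_used)) next
    }
    if (is.null(best) || better(idx, best)) best <- idx
  }
  out <- cand[best, c("i", "j"), drop = FALSE]
  out[order(out$i), , drop = FALSE]
}

# Brute-force maximum crossing-free subset cardinality.
brute_force_noncross <- function(pairs) {
  m <- nrow(pairs)
  if (m == 0) return(0L)
  crossing <- function(a, b) {
    (a[1] < b[1] && b[1] < a[2] && a[2] < b[2]) ||
    (b[1] < a[1] && a[1] < b[2] && b[2] < a[2])
  }
  best <- 0L
  for (mask in 0:(2^m - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (length(idx) <= best) next
    ok <- TRUE
    if (length(idx) > 1) {
      cb <- utils::combn(idx, 2)
      for (q in seq_len(ncol(cb))) {
        if (crossing(pairs[cb[1, q], ], pairs[cb[2, q], ])) { ok <- FALSE; break }
      }
    }
    if (ok) best <- length(idx)
  }
  best
}

# All set partitions of 1..n into k nonempty blocks.
set_partitions <- function(n, k) {
  out <- list()
  rec <- function(item, blocks) {
    if (item > n) {
      if (length(blocks) == k) out[[length(out) + 1]] <<- blocks
      return(invisible(NULL))
    }
    if (length(blocks) + (n - item + 1) < k) return(invisible(NULL))
    for (b in seq_along(blocks)) {
      nb <- blocks; nb[[b]] <- c(nb[[b]], item)
      rec(item + 1, nb)
    }
    if (length(blocks) < k) rec(item + 1, c(blocks, list(item)))
  }
  rec(2L, list(1L))
  out
}

# Brute-force optimal k-medoid cost over all partitions of a distance matrix.
brute_force_medoid_cost <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  for (partn in set_partitions(n, k)) {
    cost <- 0
    for (bl in partn) {
      cost <- cost + min(vapply(bl, function(md) sum(D[bl, md]), numeric(1)))
    }
    if (cost < best) best <- cost
  }
  best
}

# Random candidate base-pair set for the conflict oracle.
random_candidates <- function(m, n = 20) {
  i <- integer(0); j <- integer(0)
  while (length(i) < m) {
    a <- sample.int(n - 2, 1)
    b <- a + 1 + sample.int(n - a - 1, 1)
    if (!any(i == a & j == b)) { i <- c(i, a); j <- c(j, b) }
  }
  data.frame(i = i, j = j, score = round(stats::runif(m), 3))
}

# Random partial matching (one partner per residue), crossings allowed.
random_matching <- function(npairs, n = 24) {
  pos <- sample.int(n, 2 * npairs)
  matrix(c(pmin(pos[seq_len(npairs)], pos[npairs + seq_len(npairs)]),
           pmax(pos[seq_len(npairs)], pos[npairs + seq_len(npairs)])),
         ncol = 2)
}

# Complementary random sequence for a given nested dot-bracket.
comp_sequence <- function(db) {
  n <- nchar(db)
  ss0 <- parse_dotbracket(db, strrep("A", n))
  bases <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  pr <- ss0$pairs
  combos <- list(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"),
                 c("G", "U"), c("U", "G"))
  for (k in seq_len(nrow(pr))) {
    cb <- combos[[sample.int(6, 1)]]
    bases[pr[k, 1]] <- cb[1]; bases[pr[k, 2]] <- cb[2]
  }
  paste(bases, collapse = "")
}
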