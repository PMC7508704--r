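## Decomposition of a nested secondary structure into Smallest Secondary
## Elements (SSEs): stems, and the loop classes (hairpin, bulge, internal,
## junction, open loop), each loop annexing two terminal base pairs from
## every adjoining stem as superposition anchors.  Two schemes are
## supported: lib2 keeps single-base-pair stems, lib1 opens them (removes
## the pair, merging the surrounding loops) before SSE identification.

SSE_TYPES <- c("stem", "hairpin_loop", "bulge_loop", "internal_loop",
               "junction", "open_loop")

#' Find stems (helices)
#'
#' A stem is a maximal run of consecutively nested pairs
#' (i, j), (i+1, j-1), ...  Every pair belongs to exactly one stem.
#'
#' @param ss crossing-free [rna_ss()].
#' @return list of two-column matrices, one per stem, rows ordered from the
#'   outermost pair inward; stems sorted by outermost opening index.
#' @export
find_stems <- function(ss) {
  pr <- ss$pairs
  if (nrow(pr) == 0) return(list())
  p <- ss_partner(ss)
  stems <- list()
  cur <- NULL
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1]; j <- pr[k, 2]
    if (!is.null(cur) && cur[nrow(cur), 1] == i - 1L &&
        cur[nrow(cur), 2] == j + 1L) {
      cur <- rbind(cur, c(i, j))
    } else {
      if (!is.null(cur)) stems[[length(stems) + 1]] <- cur
      cur <- matrix(c(i, j), 1, 2)
    }
  }
  stems[[length(stems) + 1]] <- cur
  stems
}

#' Open single base pairs
#'
#' Removes every stem consisting of exactly one pair, iterating to a fixed
#' point (opening one pair may leave another stem stranded as a single
#' pair).  This is the lib1 pre-processing step; lib2 keeps single pairs.
#'
#' @param ss crossing-free [rna_ss()].
#' @return [rna_ss()] without single-pair stems.
#' @export
open_single_pairs <- function(ss) {
  repeat {
    stems <- find_stems(ss)
    singles <- Filter(function(s) nrow(s) == 1, stems)
    if (length(singles) == 0) return(ss)
    drop <- do.call(rbind, singles)
    keep <- !(paste(ss$pairs[, 1], ss$pairs[, 2]) %in%
              paste(drop[, 1], drop[, 2]))
    ss <- rna_ss(ss$sequence, ss$pairs[keep, , drop = FALSE])
  }
}

## Split a sorted integer vector into maximal contiguous runs.
contiguous_runs <- function(v) {
  if (length(v) == 0) return(list())
  brk <- which(diff(v) > 1L)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(v))
  lapply(seq_along(starts), function(k) c(v[starts[k]], v[ends[k]]))
}

## Build one SSE record (2D) from its member residues and included pairs.
new_sse_record <- function(sse_type, members, incl_pairs, flanking, bases,
                           n_stems = NA_integer_) {
  members <- sort(unique(members))
  runs <- contiguous_runs(members)
  local <- match(incl_pairs, members)
  lp <- matrix(local, ncol = 2)
  seq_local <- paste(bases[members], collapse = "")
  ## record pairs are nested by construction, so the bracket string can be
  ## written directly without layer assignment
  chars <- rep(".", length(members))
  chars[lp[, 1]] <- "("
  chars[lp[, 2]] <- ")"
  db <- paste(chars, collapse = "")
  ## insert '&' separators at run boundaries
  lens <- vapply(runs, function(r) r[2] - r[1] + 1L, integer(1))
  if (length(runs) > 1) {
    cuts <- cumsum(lens)
    piece <- function(s) {
      sp <- substring(s, c(1L, cuts[-length(cuts)] + 1L), cuts)
      paste(sp, collapse = "&")
    }
    seq_out <- piece(seq_local)
    db_out <- piece(db)
  } else {
    seq_out <- seq_local
    db_out <- db
  }
  structure(list(sse_type = sse_type,
                 segments = runs,
                 flanking_pairs = flanking,
                 residues = members,
                 n_stems = n_stems,
                 sequence = seq_out,
                 dot_bracket = db_out,
                 length = length(members),
                 family = "",
                 source_id = "",
                 source_chain = "",
                 atoms = NULL),
            class = "sse_record")
}

#' @export
print.sse_record <- function(x, ...) {
  cat(sprintf("<sse_record %s %s %s (%d nt)%s>\n", x$sse_type, x$sequence,
              x$dot_bracket, x$length,
              if (!is.null(x$atoms)) " +coords" else ""))
  invisible(x)
}

#' Decompose a secondary structure into SSE records
#'
#' Loops are classified from the stem tree: hairpin (one closing stem),
#' bulge (two stems, at most one unpaired segment between them), internal
#' (two stems, two unpaired segments), junction (three or more incident
#' stems), and a single open-loop record for everything incident to the
#' exterior, including the 5'/3' tails.  Each loop annexes the two terminal
#' base pairs of every adjacent stem (or the single pair of a one-pair
#' stem); each stem is emitted as its own record.  Under scheme `"lib1"`,
#' [open_single_pairs()] is applied first.
#'
#' @param ss crossing-free [rna_ss()] with at least one pair.
#' @param scheme `"lib2"` (keep single pairs) or `"lib1"` (open them).
#' @return list of [sse_record] objects (2D only: no coordinates).
#' @export
decompose <- function(ss, scheme = c("lib2", "lib1")) {
  scheme <- match.arg(scheme)
  if (scheme == "lib1") ss <- open_single_pairs(ss)
  if (nrow(ss$pairs) == 0)
    stop("structure has no pairs: chain is library-ineligible")
  n <- ss_length(ss)
  bases <- strsplit(ss$sequence, "")[[1]]
  p <- ss_partner(ss)
  stems <- find_stems(ss)
  ns <- length(stems)
  stem_at_open <- integer(n)  # outermost opening index -> stem id
  for (s in seq_len(ns)) stem_at_open[stems[[s]][1, 1]] <- s
  outer_two <- function(s) {        # two outermost pairs (or all of a short stem)
    m <- stems[[s]]
    m[seq_len(min(2, nrow(m))), , drop = FALSE]
  }
  inner_two <- function(s) {
    m <- stems[[s]]
    m[rev(nrow(m) - seq_len(min(2, nrow(m))) + 1L), , drop = FALSE]
  }
  records <- list()
  for (s in seq_len(ns)) {
    records[[length(records) + 1]] <- local({
      m <- stems[[s]]
      new_sse_record("stem", as.vector(m), m,
                     matrix(integer(), 0, 2), bases)
    })
  }
  ## one loop per stem: the region inside its innermost pair
  for (s in seq_len(ns)) {
    m <- stems[[s]]
    a <- m[nrow(m), 1]; b <- m[nrow(m), 2]
    segs <- list()
    cur <- integer(0)
    children <- integer(0)
    k <- a + 1L
    while (k < b) {
      if (p[k] == 0L) {
        cur <- c(cur, k)
        k <- k + 1L
      } else {
        segs[[length(segs) + 1]] <- cur
        cur <- integer(0)
        children <- c(children, stem_at_open[k])
        k <- p[k] + 1L
      }
    }
    segs[[length(segs) + 1]] <- cur
    nchild <- length(children)
    nseg <- sum(lengths(segs) > 0)
    type <- if (nchild == 0) "hairpin_loop"
            else if (nchild == 1 && nseg <= 1) "bulge_loop"
            else if (nchild == 1) "internal_loop"
            else "junction"
    flank <- inner_two(s)
    for (cs in children) flank <- rbind(flank, outer_two(cs))
    members <- c(unlist(segs), as.vector(flank))
    records[[length(records) + 1]] <-
      new_sse_record(type, members, flank, flank, bases,
                     n_stems = nchild + 1L)
  }
  ## exterior / open loop
  top <- integer(0)
  ext <- integer(0)
  k <- 1L
  while (k <= n) {
    if (p[k] == 0L) {
      ext <- c(ext, k)
      k <- k + 1L
    } else {
      top <- c(top, stem_at_open[k])
      k <- p[k] + 1L
    }
  }
  if (length(ext) > 0 || length(top) >= 2) {
    flank <- do.call(rbind, lapply(top, outer_two))
    if (is.null(flank)) flank <- matrix(integer(), 0, 2)
    members <- c(ext, as.vector(flank))
    records[[length(records) + 1]] <-
      new_sse_record("open_loop", members, flank, flank, bases,
                     n_stems = length(top))
  }
  records
}

#' Attach 3D coordinates to SSE records
#'
#' Copies the chain's heavy-atom coordinates for exactly the member residues
#' of each record (segments plus flanking-pair residues) and stamps the
#' source provenance.
#'
#' @param chain sanitized [rna_chain] whose secondary structure produced
#'   `records`.
#' @param records list of [sse_record] from [decompose()].
#' @return the records, each with an `atoms` data.frame.
#' @export
attach_coordinates <- function(chain, records) {
  n <- chain_length(chain)
  lapply(records, function(rec) {
    if (any(rec$residues < 1 | rec$residues > n))
      stop("record refers to residues missing from the chain")
    sel <- chain$atoms$res %in% rec$residues
    at <- chain$atoms[sel, , drop = FALSE]
    rownames(at) <- NULL
    rec$atoms <- at
    rec$source_id <- chain$source_id
    rec$source_chain <- chain$chain_id
    rec
  })
}
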