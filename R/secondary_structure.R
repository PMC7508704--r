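## Secondary-structure data model: sequences over A/C/G/U plus a set of base
## pairs, serialized in dot-bracket notation with up to four bracket layers
## for crossing (pseudoknot) pairs.

BRACKET_OPEN <- c("(", "[", "{", "<")
BRACKET_CLOSE <- c(")", "]", "}", ">")

#' Is a base combination a standard pair?
#'
#' AU, GC and GU (in either order) are the standard pairs; everything else is
#' non-standard but may still be annotated from geometry.
#'
#' @param b1,b2 single base characters.
#' @return logical.
#' @export
is_standard_pair <- function(b1, b2) {
  key <- paste(pmin(b1, b2), pmax(b1, b2), sep = "")
  key %in% c("AU", "CG", "GU")
}

#' Construct a secondary structure object
#'
#' @param sequence string over A/C/G/U.
#' @param pairs two-column integer matrix of (i, j) residue indices, 1-based,
#'   i < j; may be empty.
#' @return An object of class `rna_ss`: list with `sequence`, `pairs`
#'   (matrix ordered by i) and `standard` (logical per pair).
#' @export
rna_ss <- function(sequence, pairs = matrix(integer(), 0, 2)) {
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1]]
  if (!all(bases %in% RNA_BASES)) stop("sequence must be over A/C/G/U")
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs)) {
    if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must have i < j")
    if (any(pairs < 1L) || any(pairs > length(bases)))
      stop("pair index outside the sequence")
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  std <- if (nrow(pairs)) is_standard_pair(bases[pairs[, 1]], bases[pairs[, 2]])
         else logical(0)
  structure(list(sequence = sequence, pairs = pairs, standard = std),
            class = "rna_ss")
}

#' @export
print.rna_ss <- function(x, ...) {
  cat(x$sequence, "\n", sep = "")
  db <- try(to_dotbracket(x), silent = TRUE)
  if (!inherits(db, "try-error")) cat(db, "\n", sep = "")
  cat(sprintf("<rna_ss: %d nt, %d pairs>\n", nchar(x$sequence), nrow(x$pairs)))
  invisible(x)
}

ss_length <- function(ss) nchar(ss$sequence)

## partner vector: p[i] = j if (i,j) or (j,i) paired, else 0
ss_partner <- function(ss) {
  p <- integer(ss_length(ss))
  if (nrow(ss$pairs)) {
    p[ss$pairs[, 1]] <- ss$pairs[, 2]
    p[ss$pairs[, 2]] <- ss$pairs[, 1]
  }
  p
}

#' Parse dot-bracket notation
#'
#' Each bracket layer `()`, `[]`, `{}`, `<>` is matched independently by a
#' stack, so crossing (pseudoknot) pairs can be encoded in the extra layers.
#'
#' @param text dot-bracket string, same length as `sequence`.
#' @param sequence base string over A/C/G/U.
#' @return [rna_ss()] object.
#' @export
parse_dotbracket <- function(text, sequence) {
  if (nchar(text) != nchar(sequence))
    stop("structure and sequence differ in length")
  chars <- strsplit(text, "")[[1]]
  ok <- chars %in% c(".", BRACKET_OPEN, BRACKET_CLOSE)
  if (!all(ok))
    stop(sprintf("invalid character '%s' at position %d",
                 chars[which(!ok)[1]], which(!ok)[1]))
  pairs <- NULL
  for (layer in seq_along(BRACKET_OPEN)) {
    stack <- integer(0)
    for (k in seq_along(chars)) {
      if (chars[k] == BRACKET_OPEN[layer]) {
        stack <- c(stack, k)
      } else if (chars[k] == BRACKET_CLOSE[layer]) {
        if (length(stack) == 0)
          stop(sprintf("unbalanced '%s' at position %d", chars[k], k))
        pairs <- rbind(pairs, c(stack[length(stack)], k))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack))
      stop(sprintf("unbalanced '%s' at position %d",
                   BRACKET_OPEN[layer], stack[length(stack)]))
  }
  if (is.null(pairs)) pairs <- matrix(integer(), 0, 2)
  rna_ss(sequence, pairs)
}

#' Serialize a secondary structure to dot-bracket notation
#'
#' Nested pairs use `()`; crossing pairs are assigned greedily (by ascending
#' opening index) to the first bracket layer in which they do not cross any
#' pair already placed there.
#'
#' @param ss [rna_ss()] object.
#' @return dot-bracket string.
#' @export
to_dotbracket <- function(ss) {
  n <- ss_length(ss)
  out <- rep(".", n)
  layers <- vector("list", length(BRACKET_OPEN))
  pr <- ss$pairs
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1]; j <- pr[k, 2]
    placed <- FALSE
    for (l in seq_along(layers)) {
      crosses <- FALSE
      for (q in layers[[l]]) {
        a <- q[1]; b <- q[2]
        if ((a < i && i < b && b < j) || (i < a && a < j && j < b)) {
          crosses <- TRUE; break
        }
      }
      if (!crosses) {
        layers[[l]] <- c(layers[[l]], list(c(i, j)))
        out[i] <- BRACKET_OPEN[l]; out[j] <- BRACKET_CLOSE[l]
        placed <- TRUE; break
      }
    }
    if (!placed)
      stop("structure needs more than 4 crossing bracket layers")
  }
  paste(out, collapse = "")
}

#' Resolve conflicts among candidate base pairs
#'
#' When a residue is paired with several partners among the candidates, the
#' keeper is chosen by an ordered criterion tuple: sequence interval
#' `j - i > 4`, standard base combination (AU/GC/GU), and neighbor support (a
#' candidate `(i-1, j+1)` or `(i+1, j-1)` exists), compared lexicographically
#' in that order.  Remaining ties fall through to the geometry score
#' (higher first), then smaller span, then smaller `i`.  Selection is greedy
#' in that total order, which equals a brute-force search over all
#' conflict-free candidate subsets under the same ordering.
#'
#' @param candidates data.frame with columns `i`, `j` and `score`
#'   (nonnegative geometry score); rows may share residues.
#' @param sequence base string.
#' @return [rna_ss()] with one pair per residue at most.
#' @export
resolve_pair_conflicts <- function(candidates, sequence) {
  if (is.null(candidates) || nrow(candidates) == 0) return(rna_ss(sequence))
  bases <- strsplit(toupper(sequence), "")[[1]]
  i <- as.integer(candidates$i); j <- as.integer(candidates$j)
  if (any(i >= j)) stop("candidates must have i < j")
  score <- as.numeric(candidates$score)
  span_ok <- (j - i) > 4
  std <- is_standard_pair(bases[i], bases[j])
  key <- paste(i, j)
  neigh <- (paste(i - 1L, j + 1L) %in% key) | (paste(i + 1L, j - 1L) %in% key)
  ord <- order(-span_ok, -std, -neigh, -score, j - i, i)
  used <- logical(length(bases))
  keep <- integer(0)
  for (k in ord) {
    if (!used[i[k]] && !used[j[k]]) {
      keep <- c(keep, k)
      used[i[k]] <- TRUE; used[j[k]] <- TRUE
    }
  }
  rna_ss(sequence, cbind(i[keep], j[keep]))
}

#' Remove crossing (pseudoknot) pairs
#'
#' Retains a maximum-cardinality crossing-free subset of the pairs, found by
#' dynamic programming over the pair endpoints, with a deterministic
#' traceback that prefers keeping the pair with the smaller opening index on
#' ties.
#'
#' @param ss [rna_ss()] whose pairs satisfy the one-pair-per-residue
#'   invariant.
#' @return list with `ss` (crossing-free structure) and `removed`
#'   (two-column matrix of discarded pairs).
#' @export
remove_crossing_pairs <- function(ss) {
  pr <- ss$pairs
  m <- nrow(pr)
  if (m <= 1) {
    return(list(ss = ss, removed = matrix(integer(), 0, 2)))
  }
  ## compress to pair endpoints
  ends <- sort(unique(as.vector(pr)))
  M <- length(ends)
  pos <- integer(max(ends)); pos[ends] <- seq_len(M)
  partner <- integer(M)  # 0 = none, else compressed partner index
  pair_id <- integer(M)
  for (k in seq_len(m)) {
    a <- pos[pr[k, 1]]; b <- pos[pr[k, 2]]
    partner[a] <- b; partner[b] <- a
    pair_id[a] <- k; pair_id[b] <- k
  }
  ## V[a,b]: max pairs within compressed interval [a, b]
  V <- matrix(0L, M + 1, M + 1)
  for (len in 2:M) {
    for (a in seq_len(M - len + 1)) {
      b <- a + len - 1
      best <- V[a + 1, b]
      cc <- partner[a]
      if (cc > a && cc <= b) {
        inc <- 1L + (if (cc - 1 >= a + 1) V[a + 1, cc - 1] else 0L) +
               (if (b >= cc + 1) V[cc + 1, b] else 0L)
        if (inc >= best) best <- inc  # >= : prefer keeping pair at smaller i
      }
      V[a, b] <- best
    }
  }
  keep <- logical(m)
  tb <- function(a, b) {
    while (a < b) {
      cc <- partner[a]
      if (cc > a && cc <= b) {
        inc <- 1L + (if (cc - 1 >= a + 1) V[a + 1, cc - 1] else 0L) +
               (if (b >= cc + 1) V[cc + 1, b] else 0L)
        if (inc >= V[a + 1, b]) {
          keep[pair_id[a]] <<- TRUE
          if (cc - 1 >= a + 1) tb(a + 1, cc - 1)
          a <- cc + 1
          next
        }
      }
      a <- a + 1
    }
  }
  tb(1L, M)
  list(ss = rna_ss(ss$sequence, pr[keep, , drop = FALSE]),
       removed = pr[!keep, , drop = FALSE])
}

#' Write / read the two-line secondary-structure text format
#'
#' Line 1 is the sequence, line 2 the dot-bracket string.
#'
#' @param ss [rna_ss()] object.
#' @param path file path.
#' @return `read_ss_file` returns an [rna_ss()].
#' @export
write_ss_file <- function(ss, path) {
  writeLines(c(ss$sequence, to_dotbracket(ss)), path)
  invisible(path)
}

#' @rdname write_ss_file
#' @export
read_ss_file <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) < 2) stop("expected a sequence line and a structure line")
  parse_dotbracket(trimws(ln[2]), trimws(ln[1]))
}
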