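## Geometric base-pair annotation.  Candidate pairs are detected from base
## ring geometry (origin distance, plane coplanarity, vertical offset and a
## donor/acceptor edge contact), scored, filtered through the conflict rules
## and stripped of crossing pairs to yield a chain's nested secondary
## structure.

#' Annotation thresholds
#'
#' All geometric cutoffs used by [detect_base_pairs()] in one overridable
#' block.  `d_pair` is a coarse prefilter on ring-centroid distance,
#' `c1_window` the C1'-C1' distance window, `theta_pair` the maximum angle
#' between base-plane normals (or its supplement, since normals of paired
#' antiparallel bases are anti-aligned), `v_pair` the maximum vertical offset
#' (projection of the centroid displacement on the mean normal), and
#' `h_pair` the maximum donor/acceptor heavy-atom contact distance between
#' Watson-Crick edges.
#'
#' @param d_pair angstroms; default 15.
#' @param c1_window angstroms; default 10.5.
#' @param theta_pair degrees; default 65.
#' @param v_pair angstroms; default 2.5.
#' @param h_pair angstroms; default 3.5.
#' @return named list of thresholds.
#' @export
annotation_params <- function(d_pair = 15, c1_window = 10.5, theta_pair = 65,
                              v_pair = 2.5, h_pair = 3.5) {
  list(d_pair = d_pair, c1_window = c1_window, theta_pair = theta_pair,
       v_pair = v_pair, h_pair = h_pair)
}

#' Base reference frame of a residue
#'
#' Origin is the centroid of the base ring atoms; the normal is the
#' least-squares plane normal oriented by the right-hand rule over the ring
#' atom order; `glycosidic_atom` is the position of N9 (purines) or N1
#' (pyrimidines).
#'
#' @param atoms data.frame of one residue's atoms (`atom`, `x`, `y`, `z`).
#' @param base the residue's parent base.
#' @return list with `origin`, `normal`, `glycosidic_atom`.
#' @export
base_frame <- function(atoms, base) {
  ring <- BASE_RING_ATOMS[[base]]
  idx <- match(ring, atoms$atom)
  if (anyNA(idx)) stop("missing base ring atoms: ",
                       paste(ring[is.na(idx)], collapse = ","))
  X <- as.matrix(atoms[idx, c("x", "y", "z")])
  cen <- colMeans(X)
  ctr <- sweep(X, 2, cen)
  z <- svd(ctr)$v[, 3]
  rh <- c(0, 0, 0)
  m <- nrow(ctr)
  for (k in seq_len(m)) rh <- rh + cross3(ctr[k, ], ctr[k %% m + 1, ])
  if (sum(z * rh) < 0) z <- -z
  g <- match(GLYCOSIDIC_N[[base]], atoms$atom)
  list(origin = cen, normal = z,
       glycosidic_atom = as.numeric(atoms[g, c("x", "y", "z")]))
}

## Precompute per-residue frames, C1' positions and edge-atom coordinates.
chain_base_geometry <- function(chain) {
  n <- chain_length(chain)
  origins <- matrix(NA_real_, n, 3)
  normals <- matrix(NA_real_, n, 3)
  c1 <- matrix(NA_real_, n, 3)
  edges <- vector("list", n)
  for (r in seq_len(n)) {
    at <- residue_atoms(chain, r)
    fr <- base_frame(at, chain$seq[r])
    origins[r, ] <- fr$origin
    normals[r, ] <- fr$normal
    k <- match("C1'", at$atom)
    if (is.na(k)) stop("residue ", r, " lacks C1'")
    c1[r, ] <- as.numeric(at[k, c("x", "y", "z")])
    eidx <- match(WC_EDGE_ATOMS[[chain$seq[r]]], at$atom)
    edges[[r]] <- as.matrix(at[eidx[!is.na(eidx)], c("x", "y", "z")])
  }
  list(origins = origins, normals = normals, c1 = c1, edges = edges)
}

#' Detect base pairs from 3D coordinates
#'
#' Emits a candidate pair (i, j), i + 1 < j, when the ring-centroid distance,
#' C1'-C1' distance, normal-plane angle, vertical offset and Watson-Crick
#' edge contact all pass the thresholds in `params`.  Non-standard base
#' combinations are retained.  The geometry score is the equal-weighted mean
#' of the normalized criterion margins (0 at a threshold, 1 at perfect
#' geometry), used downstream only to break conflict-filter ties.
#'
#' @param chain sanitized [rna_chain].
#' @param params [annotation_params()].
#' @return data.frame with columns `i`, `j`, `score` (possibly 0 rows).
#' @export
detect_base_pairs <- function(chain, params = annotation_params()) {
  n <- chain_length(chain)
  empty <- data.frame(i = integer(), j = integer(), score = numeric())
  if (n < 3) return(empty)
  geo <- chain_base_geometry(chain)
  out_i <- integer(0); out_j <- integer(0); out_s <- numeric(0)
  cth <- params$theta_pair * pi / 180
  for (i in seq_len(n - 2)) {
    for (j in seq.int(i + 2, n)) {
      d0 <- vnorm(geo$origins[j, ] - geo$origins[i, ])
      if (d0 > params$d_pair) next
      dc1 <- vnorm(geo$c1[j, ] - geo$c1[i, ])
      if (dc1 > params$c1_window) next
      cosang <- abs(sum(geo$normals[i, ] * geo$normals[j, ]))
      cosang <- min(1, cosang)
      ang <- acos(cosang)  # folded angle: 0 = parallel or antiparallel
      if (ang > cth) next
      mn <- unitv(if (sum(geo$normals[i, ] * geo$normals[j, ]) >= 0)
                    geo$normals[i, ] + geo$normals[j, ]
                  else geo$normals[i, ] - geo$normals[j, ])
      v <- abs(sum((geo$origins[j, ] - geo$origins[i, ]) * mn))
      if (v > params$v_pair) next
      ei <- geo$edges[[i]]; ej <- geo$edges[[j]]
      dd <- sqrt(outer(rowSums(ei^2), rowSums(ej^2), "+") -
                 2 * ei %*% t(ej))
      h <- min(dd)
      if (h > params$h_pair) next
      score <- mean(c(1 - dc1 / params$c1_window,
                      1 - ang / cth,
                      1 - v / params$v_pair,
                      1 - h / params$h_pair))
      out_i <- c(out_i, i); out_j <- c(out_j, j); out_s <- c(out_s, score)
    }
  }
  data.frame(i = out_i, j = out_j, score = out_s)
}

#' Read an externally produced base-pair list
#'
#' Accepts a two-column, 1-based, whitespace-separated index file so that
#' output from a third-party annotator can be used in place of geometric
#' detection.  Lines starting with `#` are ignored.  A third numeric column,
#' if present, is taken as the geometry score (default 0).
#'
#' @param path file path.
#' @return data.frame with columns `i`, `j`, `score`.
#' @export
read_pair_list <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop("expected at least two index columns")
  ij <- cbind(pmin(tab[[1]], tab[[2]]), pmax(tab[[1]], tab[[2]]))
  data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
             score = if (ncol(tab) >= 3) as.numeric(tab[[3]]) else 0)
}

#' Derive a chain's secondary structure
#'
#' Runs [detect_base_pairs()] (or takes an imported candidate list),
#' [resolve_pair_conflicts()] and [remove_crossing_pairs()], attaches the
#' resulting nested structure to the chain, and records the removed crossing
#' pairs as chain metadata.  Chains whose derived structure has zero pairs
#' are flagged library-ineligible.
#'
#' @param chain sanitized [rna_chain].
#' @param params [annotation_params()].
#' @param candidates optional data.frame `i`, `j`, `score` replacing
#'   detection (e.g. from [read_pair_list()]).
#' @return the chain with `ss`, `removed_crossing_pairs` and
#'   `library_eligible` fields set.
#' @export
derive_secondary_structure <- function(chain, params = annotation_params(),
                                       candidates = NULL) {
  if (is.null(candidates)) candidates <- detect_base_pairs(chain, params)
  seq_str <- paste(chain$seq, collapse = "")
  ss <- resolve_pair_conflicts(candidates, seq_str)
  res <- remove_crossing_pairs(ss)
  chain$ss <- res$ss
  chain$removed_crossing_pairs <- res$removed
  chain$library_eligible <- nrow(res$ss$pairs) > 0
  chain
}
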