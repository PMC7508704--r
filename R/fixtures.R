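## Synthetic full heavy-atom RNA fixtures with known secondary structure.
##
## Stems are built as idealized A-form-like helices (fixed twist and rise)
## from the frozen nucleotide templates; unpaired residues are laid out on
## smooth circular arcs (or straight lines) connecting the C1' anchors of
## their neighboring paired residues, bases pointing outward and base planes
## perpendicular to the chain direction so that no spurious pair geometry
## arises.  The generating secondary structure is returned as ground truth.

LOOP_SPACING <- 5.9   # C1'-C1' spacing along unpaired runs, angstroms
LOOP_MAX_WRAP <- 5.9  # arc angle cap, radians (near-circular wrap allowed)
LOOP_BOW <- 4.0       # outward bowing of mid-loop residues, angstroms
ARC_LIFT <- 3.5       # extra elevation of wrapped (>180 degree) arcs, angstroms
ARC_LIFT_BASE <- 3.0  # elevation of every loop arc above its anchors, angstroms
TAIL_CLEARANCE <- 8.5   # gap between a terminal tail and its anchor, angstroms
JUNCTION_BRANCH_ANGLE <- 65 * pi / 180
JUNCTION_RADIAL_OFFSET <- 18
JUNCTION_AXIAL_OFFSET <- 6
EXTERIOR_STEM_SPACING <- 55

#' Build an ideal paired duplex
#'
#' Constructs a heavy-atom helical duplex from the idealized nucleotide
#' templates with fixed twist and rise.  The two strands are stored in
#' pairing register: residue `k` of strand 1 lies directly across residue
#' `n + k`, so the ground-truth pairs are `(k, n + k)`.
#'
#' @param seq5 base string of strand 1 (5' to 3').
#' @param seq3 base string positionally complementary to `seq5` under
#'   AU/GC/GU.
#' @return list with `chain` ([rna_chain] of `2n` residues) and `ss`
#'   ([rna_ss()] carrying the constructed pairs).
#' @export
build_ideal_helix <- function(seq5, seq3) {
  b5 <- strsplit(toupper(seq5), "")[[1]]
  b3 <- strsplit(toupper(seq3), "")[[1]]
  if (length(b5) != length(b3)) stop("strand lengths differ")
  if (!all(is_standard_pair(b5, b3)))
    stop("strands are not complementary under AU/GC/GU")
  n <- length(b5)
  pl <- pair_local_frames()
  base_fr <- list(o = c(0, 0, 0), R = diag(3))
  res <- vector("list", 2 * n)
  for (k in seq_len(n)) {
    pf <- helix_step_frame(base_fr, k - 1)
    res[[k]] <- place_nucleotide(b5[k], compose_frame(pl[[1]], pf))
    res[[n + k]] <- place_nucleotide(b3[k], compose_frame(pl[[2]], pf))
  }
  atoms <- do.call(rbind, lapply(seq_along(res), function(r)
    cbind(data.frame(res = r), res[[r]])))
  rownames(atoms) <- NULL
  chain <- new_rna_chain("DUPLEX", "A", c(b5, b3), c(b5, b3), atoms)
  ss <- rna_ss(paste(c(b5, b3), collapse = ""),
               cbind(seq_len(n), n + seq_len(n)))
  list(chain = chain, ss = ss)
}

## Solve arc angle theta from chord/length ratio; NULL means use a line.
solve_arc_angle <- function(chord, len) {
  if (len <= chord * 1.02) return(NULL)
  f <- function(th) 2 * sin(th / 2) / th - chord / len
  stats::uniroot(f, c(1e-6, 2 * pi - 1e-3), tol = 1e-10)$root
}

## Place m residues between 3D anchors A and B, bulging toward `bulge`.
## Returns list of per-residue frames (positions for C1' on the arc).
arc_frames <- function(A, B, m, bulge, spacing = LOOP_SPACING) {
  if (m == 0) return(list())
  AB <- B - A
  chord <- vnorm(AB)
  ex <- unitv(AB)
  nb <- bulge - sum(bulge * ex) * ex
  if (vnorm(nb) < 1e-6) {
    nb <- c(ex[2], -ex[1], 0)
    if (vnorm(nb) < 1e-6) nb <- c(0, ex[3], -ex[2])
  }
  nb <- unitv(nb)
  L <- (m + 1) * spacing
  th <- solve_arc_angle(chord, L)
  ## arcs ride above their anchors (more so when wrapped) so that neither
  ## the near-anchor residues nor the far sweep reach into the closing helix
  lift <- (ARC_LIFT_BASE + if (!is.null(th) && th > pi) ARC_LIFT else 0) * nb
  A <- A + lift; B <- B + lift
  out <- vector("list", m)
  bow <- function(k) LOOP_BOW * sin(pi * k / (m + 1))
  if (is.null(th)) {
    tvec <- ex
    for (k in seq_len(m)) {
      pos <- A + AB * k / (m + 1) + nb * bow(k)
      out[[k]] <- list(pos = pos, tangent = tvec, outward = nb)
    }
    return(out)
  }
  if (th > LOOP_MAX_WRAP) {
    th <- LOOP_MAX_WRAP
    R <- chord / (2 * sin(th / 2))
  } else {
    R <- L / th
  }
  e <- sqrt(max(R^2 - (chord / 2)^2, 0))
  M <- (A + B) / 2
  C <- if (th <= pi) M - nb * e else M + nb * e
  a2 <- c(sum((A - C) * ex), sum((A - C) * nb))
  phiA <- atan2(a2[2], a2[1])
  pt <- function(phi) C + R * (cos(phi) * ex + sin(phi) * nb)
  sgn <- 1
  mid <- pt(phiA + sgn * th / 2)
  if (sum((mid - M) * nb) < 0) sgn <- -1
  for (k in seq_len(m)) {
    phi <- phiA + sgn * th * k / (m + 1)
    pos <- pt(phi)
    ## blend the radial direction with the bulge normal so bases near the
    ## anchors of a wrapped arc never point back into the closing helix
    outward <- unitv(unitv(pt(phi) - C) + 1.5 * nb)
    tangent <- unitv(sgn * (-sin(phi) * ex + cos(phi) * nb))
    out[[k]] <- list(pos = pos + outward * bow(k), tangent = tangent,
                     outward = outward)
  }
  out
}

## Residue frame for a loop placement: C1' at `pos`, base pointing along
## `outward`, base plane perpendicular to the chain tangent (stack-like
## normals, so consecutive unpaired bases fail the vertical-offset pair
## criterion by construction).
loop_residue_frame <- function(pos, tangent, outward) {
  fr <- make_frame(c(0, 0, 0), -outward, tangent)
  fr$o <- pos - GLYCOSIDIC_BOND * fr$R[1, ]
  fr
}

#' Build a toy RNA with known structure
#'
#' Generates full heavy-atom coordinates for an arbitrary nested secondary
#' structure: stems as idealized helices, unpaired runs on smooth arcs
#' between their anchoring paired residues, junction arms fanned outward,
#' and top-level stems spaced along the x axis.  Optional Gaussian
#' coordinate noise of a given amplitude is applied under the given seed.
#'
#' @param sequence base string over A/C/G/U.
#' @param dotbracket nested (crossing-free) dot-bracket string.
#' @param seed integer seed controlling the noise.
#' @param amplitude coordinate noise standard deviation, angstroms.
#' @param source_id,chain_id provenance labels for the generated chain.
#' @return list with `chain` ([rna_chain]) and `ss` (ground-truth
#'   [rna_ss()]).
#' @export
build_toy_rna <- function(sequence, dotbracket, seed = 1, amplitude = 0,
                          source_id = "TOY1", chain_id = "A") {
  ss <- parse_dotbracket(dotbracket, sequence)
  if (grepl("[\\[{<]", dotbracket))
    stop("fixture structures must be crossing-free (no pseudoknots)")
  bases <- strsplit(ss$sequence, "")[[1]]
  n <- length(bases)
  p <- ss_partner(ss)
  res <- vector("list", n)
  pl <- pair_local_frames()
  stems <- find_stems(ss)
  stem_at_open <- integer(n)
  for (s in seq_along(stems)) stem_at_open[stems[[s]][1, 1]] <- s
  place_stem <- function(s, F) {
    m <- stems[[s]]
    L <- nrow(m)
    for (k in seq_len(L)) {
      pf <- helix_step_frame(F, k - 1)
      i <- m[k, 1]; j <- m[k, 2]
      res[[i]] <<- place_nucleotide(bases[i], compose_frame(pl[[1]], pf))
      res[[j]] <<- place_nucleotide(bases[j], compose_frame(pl[[2]], pf))
    }
    ## children of the loop this stem closes
    a <- m[L, 1]; b <- m[L, 2]
    children <- integer(0)
    segmax <- 0; curlen <- 0
    k <- a + 1L
    while (k < b) {
      if (p[k] == 0L) { curlen <- curlen + 1; k <- k + 1L }
      else {
        children <- c(children, k)
        segmax <- max(segmax, curlen); curlen <- 0
        k <- p[k] + 1L
      }
    }
    segmax <- max(segmax, curlen)
    Fin <- helix_step_frame(F, L - 1)
    if (length(children) == 1) {
      Fc <- helix_step_frame(F, (L - 1) + 1.35 + 0.9 * segmax)
      place_stem(stem_at_open[children[1]], Fc)
    } else if (length(children) >= 2) {
      xin <- Fin$R[1, ]; yin <- Fin$R[2, ]; zin <- Fin$R[3, ]
      for (mi in seq_along(children)) {
        psi <- 2 * pi * mi / (length(children) + 1)
        radial <- cos(psi) * xin + sin(psi) * yin
        dirm <- cos(JUNCTION_BRANCH_ANGLE) * zin +
                sin(JUNCTION_BRANCH_ANGLE) * radial
        om <- Fin$o + JUNCTION_AXIAL_OFFSET * zin +
              JUNCTION_RADIAL_OFFSET * radial
        place_stem(stem_at_open[children[mi]], make_frame(om, radial, dirm))
      }
    }
  }
  ## top level: stems spaced along x
  top <- integer(0)
  k <- 1L
  while (k <= n) {
    if (p[k] == 0L) k <- k + 1L
    else { top <- c(top, stem_at_open[k]); k <- p[k] + 1L }
  }
  for (t in seq_along(top)) {
    F <- list(o = c(EXTERIOR_STEM_SPACING * (t - 1), 0, 0), R = diag(3))
    place_stem(top[t], F)
  }
  ## unpaired runs between placed paired residues
  c1_of <- function(r) as.numeric(res[[r]][match("C1'", res[[r]]$atom),
                                           c("x", "y", "z")])
  paired <- which(p > 0)
  centroid <- if (length(paired))
    colMeans(do.call(rbind, lapply(paired, c1_of))) else c(0, 0, 0)
  ## local reference for the bulge direction: the enclosing helix ends
  local_ref <- function(lo, hi) {
    anchors <- c(lo - 1L, hi + 1L)
    anchors <- anchors[anchors >= 1L & anchors <= n & p[anchors] > 0L]
    pts <- unique(c(anchors, p[anchors]))
    more <- c(anchors - 1L, anchors + 1L)
    more <- more[more >= 1L & more <= n]
    more <- more[p[more] > 0L]
    pts <- unique(c(pts, more, p[more]))
    if (length(pts) == 0) return(centroid)
    colMeans(do.call(rbind, lapply(pts, c1_of)))
  }
  runs <- contiguous_runs(which(p == 0L))
  for (run in runs) {
    lo <- run[1]; hi <- run[2]
    m <- hi - lo + 1L
    hasA <- lo > 1L; hasB <- hi < n
    if (!hasA || !hasB) {
      ## terminal tail (or fully unpaired chain): straight strand walking
      ## away from the anchor with explicit clearance, so the first placed
      ## residue's phosphate moiety cannot reach back into the helix
      anchor <- if (hasB) c1_of(hi + 1L) else if (hasA) c1_of(lo - 1L)
                else c(0, 0, 0)
      u <- anchor - centroid
      u <- if (vnorm(u) < 1e-6) c(1, 0, 0) else unitv(u)
      u <- unitv(u + c(0, 0.4 * (if (hasB) -1 else 1), 0.2))
      lat <- unitv(cross3(u, c(0, 0, 1) + c(0.1, 0.2, 0)))
      for (k in seq_len(m)) {
        dist_from_anchor <- if (hasB) TAIL_CLEARANCE + (m - k + 1) * LOOP_SPACING
                            else TAIL_CLEARANCE + k * LOOP_SPACING
        pos <- anchor + u * dist_from_anchor
        tangent <- if (hasB) -u else u
        fr <- loop_residue_frame(pos, tangent, lat)
        res[[lo + k - 1L]] <- place_nucleotide(bases[lo + k - 1L], fr)
      }
      next
    }
    A <- c1_of(lo - 1L)
    B <- c1_of(hi + 1L)
    ref <- if (hasA || hasB) local_ref(lo, hi) else centroid
    bulge <- (A + B) / 2 - ref
    if (vnorm(bulge) < 1e-6) bulge <- c(0, 0, 1)
    frames <- arc_frames(A, B, m, bulge)
    for (k in seq_len(m)) {
      fr <- loop_residue_frame(frames[[k]]$pos, frames[[k]]$tangent,
                               frames[[k]]$outward)
      res[[lo + k - 1L]] <- place_nucleotide(bases[lo + k - 1L], fr)
    }
  }
  atoms <- do.call(rbind, lapply(seq_len(n), function(r)
    cbind(data.frame(res = r), res[[r]])))
  rownames(atoms) <- NULL
  if (amplitude > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, amplitude)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, amplitude)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, amplitude)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  chain <- new_rna_chain(source_id, chain_id, bases, bases, atoms)
  list(chain = chain, ss = ss)
}

#' Introduce a controlled defect into a fixture chain
#'
#' Supported actions: `"truncate_residue"` (keep only the first `k` atoms of
#' residue `res`), `"duplicate_chain"` (returns a list of the chain and an
#' identical copy with a new chain id), `"displace_strand"` (translate the
#' atoms of the given residues by `offset`).
#'
#' @param chain [rna_chain].
#' @param action one of the actions above.
#' @param res residue index for `truncate_residue`.
#' @param k number of atoms kept by `truncate_residue`.
#' @param residues residue indices for `displace_strand`.
#' @param offset 3-vector translation, angstroms (default 20 A along x).
#' @return the modified chain, or a list of two chains for
#'   `"duplicate_chain"`.
#' @export
corrupt_fixture <- function(chain, action = c("truncate_residue",
                                              "duplicate_chain",
                                              "displace_strand"),
                            res = 1L, k = 8L, residues = integer(),
                            offset = c(20, 0, 0)) {
  action <- match.arg(action)
  if (action == "truncate_residue") {
    sel <- which(chain$atoms$res == res)
    if (length(sel) == 0) stop("no such residue: ", res)
    drop <- sel[-seq_len(min(k, length(sel)))]
    if (length(drop)) chain$atoms <- chain$atoms[-drop, , drop = FALSE]
    rownames(chain$atoms) <- NULL
    chain
  } else if (action == "duplicate_chain") {
    copy <- chain
    copy$chain_id <- paste0(chain$chain_id, "2")
    list(chain, copy)
  } else {
    sel <- chain$atoms$res %in% residues
    chain$atoms$x[sel] <- chain$atoms$x[sel] + offset[1]
    chain$atoms$y[sel] <- chain$atoms$y[sel] + offset[2]
    chain$atoms$z[sel] <- chain$atoms$z[sel] + offset[3]
    chain
  }
}

#' Random nested secondary structure for property tests
#'
#' Draws a random crossing-free structure with stems of 1-5 pairs, hairpin
#' loops of at least 3 nt, and a random sequence whose paired positions are
#' complementary under AU/GC/GU.
#'
#' @param n sequence length.
#' @return list with `sequence` and `dotbracket`.
#' @export
random_nested_ss <- function(n) {
  p <- gen_region(n)
  bases <- sample(RNA_BASES, n, replace = TRUE)
  combos <- list(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"),
                 c("G", "U"), c("U", "G"))
  for (i in seq_len(n)) {
    if (p[i] > i) {
      cb <- combos[[sample.int(6, 1)]]
      bases[i] <- cb[1]; bases[p[i]] <- cb[2]
    }
  }
  pairs <- cbind(which(p > seq_len(n)), p[p > seq_len(n)])
  ss <- rna_ss(paste(bases, collapse = ""), pairs)
  list(sequence = ss$sequence, dotbracket = to_dotbracket(ss))
}

## Recursive random nested partner vector; helix spans >= 8, hairpins >= 3.
gen_region <- function(len) {
  p <- integer(len)
  pos <- 1L
  while (pos <= len) {
    rem <- len - pos + 1L
    if (rem >= 8 && stats::runif(1) < 0.6) {
      span <- 8L + sample.int(rem - 8L + 1L, 1) - 1L
      end <- pos + span - 1L
      ## helices of >= 2 pairs: an isolated pair among flexible loops is
      ## not reliably recoverable by a purely geometric annotator
      hmax <- min(5L, (span - 3L) %/% 2L)
      h <- if (hmax <= 2L) 2L else sample(2:hmax, 1)
      for (t in 0:(h - 1)) {
        p[pos + t] <- end - t
        p[end - t] <- pos + t
      }
      innerlen <- span - 2L * h
      if (innerlen > 0) {
        inner <- gen_region(innerlen)
        shift <- pos + h - 1L
        p[(pos + h):(end - h)] <- ifelse(inner == 0L, 0L, inner + shift)
      }
      pos <- end + 1L
    } else {
      pos <- pos + 1L
    }
  }
  p
}
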