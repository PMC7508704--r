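## Idealized nucleotide geometry.
##
## One frozen heavy-atom template per base (A, C, G, U), stored as plain text
## under inst/extdata and expressed in a canonical glycosidic frame:
## origin at the glycosidic nitrogen (N9 for purines, N1 for pyrimidines),
## x axis along N(gly) -> C1', base ring in the xy plane with the normal
## oriented by the right-hand rule over the ring atom order.  All helix and
## loop construction, base grafting and atom completion place these templates
## by rigid motion.

RNA_BASES <- c("A", "C", "G", "U")

PURINE_RING <- c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6")
PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")

BASE_RING_ATOMS <- list(
  A = PURINE_RING, G = PURINE_RING,
  C = PYRIMIDINE_RING, U = PYRIMIDINE_RING
)

GLYCOSIDIC_N <- c(A = "N9", G = "N9", C = "N1", U = "N1")

## Watson-Crick edge heavy atoms used for the donor/acceptor contact check.
WC_EDGE_ATOMS <- list(
  A = c("N1", "C2", "N6"),
  G = c("N1", "N2", "O6"),
  C = c("N3", "O2", "N4"),
  U = c("N3", "O2", "O4")
)

BASE_ATOMS <- list(
  A = c(PURINE_RING, "N6"),
  G = c(PURINE_RING, "O6", "N2"),
  C = c(PYRIMIDINE_RING, "O2", "N4"),
  U = c(PYRIMIDINE_RING, "O2", "O4")
)

SUGAR_PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                           "C3'", "O3'", "C2'", "O2'", "C1'")

## Helical and pairing constants used by the fixture generator (idealized
## A-form-like values; see the methods vignette for their role).
HELIX_TWIST_DEG <- 32.7
HELIX_RISE <- 2.81
PAIR_C1_C1 <- 10.4        # C1'-C1' distance across a pair, angstroms
GLYCOSIDIC_LAMBDA_DEG <- 58  # angle between glycosidic bond and C1'-C1' line
GLYCOSIDIC_BOND <- 1.465  # N(gly)-C1' bond length, angstroms

.rnasse_env <- new.env(parent = emptyenv())

element_of <- function(atom) substr(sub("^[0-9]*", "", atom), 1, 1)

#' Idealized nucleotide template
#'
#' Returns the frozen heavy-atom template for one RNA base, in the canonical
#' glycosidic frame (glycosidic nitrogen at the origin, C1' on the +x axis,
#' base ring in the xy plane).
#'
#' @param base one of `"A"`, `"C"`, `"G"`, `"U"`.
#' @return data.frame with columns `atom`, `elem`, `x`, `y`, `z`.
#' @export
ideal_nucleotide <- function(base) {
  base <- match.arg(base, RNA_BASES)
  if (is.null(.rnasse_env$templates)) {
    path <- system.file("extdata", "ideal_nucleotides.tsv", package = "rnasse")
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "")
    .rnasse_env$templates <- lapply(split(tab, tab$base), function(d) {
      data.frame(atom = d$atom, elem = element_of(d$atom),
                 x = d$x, y = d$y, z = d$z, stringsAsFactors = FALSE)
    })
  }
  .rnasse_env$templates[[base]]
}

template_xyz <- function(tpl) as.matrix(tpl[, c("x", "y", "z")])

## Glycosidic frame of a placed residue: origin at N(gly), x along
## N(gly) -> C1', z = base-plane normal oriented by the ring atom order.
## `atoms` is a data.frame with atom/x/y/z for one residue of known base.
residue_glyco_frame <- function(atoms, base) {
  ring <- BASE_RING_ATOMS[[base]]
  idx <- match(c(GLYCOSIDIC_N[[base]], "C1'", ring), atoms$atom)
  if (anyNA(idx)) stop("residue lacks base ring or glycosidic atoms")
  X <- as.matrix(atoms[idx, c("x", "y", "z")])
  ngly <- X[1, ]; c1 <- X[2, ]; ringX <- X[-(1:2), , drop = FALSE]
  cen <- colMeans(ringX)
  ctr <- sweep(ringX, 2, cen)
  sv <- svd(ctr)
  z <- sv$v[, 3]
  rh <- c(0, 0, 0)
  m <- nrow(ctr)
  for (k in seq_len(m)) rh <- rh + cross3(ctr[k, ], ctr[k %% m + 1, ])
  if (sum(z * rh) < 0) z <- -z
  make_frame(ngly, c1 - ngly, z)
}

## Place an ideal nucleotide given a target glycosidic frame.
place_nucleotide <- function(base, frame) {
  tpl <- ideal_nucleotide(base)
  xyz <- frame_apply(template_xyz(tpl), frame)
  data.frame(atom = tpl$atom, elem = tpl$elem,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

## Glycosidic frames of the two residues of an idealized pair, in pair-local
## coordinates: C1' atoms at (-d/2, 0, 0) and (+d/2, 0, 0), bases in the
## z = 0 plane, strand 2 flipped (antiparallel).  Calibrated so AU, GC and GU
## all form edge contacts of ~2.8 A.
pair_local_frames <- function() {
  lam <- GLYCOSIDIC_LAMBDA_DEG * pi / 180
  d <- PAIR_C1_C1
  g1 <- c(cos(lam), sin(lam), 0)           # C1' -> N(gly), strand 1
  c11 <- c(-d / 2, 0, 0)
  f1 <- make_frame(c11 + GLYCOSIDIC_BOND * g1, -g1, c(0, 0, 1))
  g2 <- c(-cos(lam), sin(lam), 0)
  c12 <- c(d / 2, 0, 0)
  f2 <- make_frame(c12 + GLYCOSIDIC_BOND * g2, -g2, c(0, 0, -1))
  list(f1, f2)
}

## Compose frames: local frame expressed inside an outer frame.
compose_frame <- function(inner, outer) {
  list(o = as.numeric(frame_apply(rbind(inner$o), outer)),
       R = inner$R %*% outer$R)
}

## Frame of helix step k (0-based) relative to the helix base frame.
helix_step_frame <- function(base_frame, k) {
  ang <- k * HELIX_TWIST_DEG * pi / 180
  step <- list(o = c(0, 0, k * HELIX_RISE), R = rot_axis(c(0, 0, 1), ang))
  compose_frame(step, base_frame)
}

## Replace the base moiety of an observed residue with an idealized base of
## a (possibly different) identity, keeping sugar/phosphate atoms.  Used both
## for imposing a target sequence on a template and for completing bases.
graft_base <- function(atoms, old_base, new_base) {
  fr <- residue_glyco_frame(atoms, old_base)
  keep <- atoms[!(atoms$atom %in% unlist(BASE_ATOMS)), , drop = FALSE]
  tpl <- ideal_nucleotide(new_base)
  tpl <- tpl[tpl$atom %in% BASE_ATOMS[[new_base]], , drop = FALSE]
  xyz <- frame_apply(as.matrix(tpl[, c("x", "y", "z")]), fr)
  new_atoms <- data.frame(atom = tpl$atom, elem = tpl$elem,
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          stringsAsFactors = FALSE)
  rbind(keep, new_atoms)
}

## Complete missing heavy atoms of a residue by least-squares grafting of the
## ideal template onto the observed shared atoms.  Returns atoms in template
## atom order.
complete_residue <- function(atoms, base) {
  tpl <- ideal_nucleotide(base)
  missing <- setdiff(tpl$atom, atoms$atom)
  if (length(missing) == 0) {
    ord <- order(match(atoms$atom, tpl$atom))
    return(atoms[ord, , drop = FALSE])
  }
  shared <- intersect(tpl$atom, atoms$atom)
  if (length(shared) < 3) stop("too few atoms to graft an ideal residue")
  tr <- superpose(template_xyz(tpl[match(shared, tpl$atom), ]),
                  as.matrix(atoms[match(shared, atoms$atom), c("x", "y", "z")]))
  tmiss <- tpl[match(missing, tpl$atom), , drop = FALSE]
  xyz <- transform_coords(template_xyz(tmiss), tr)
  add <- data.frame(atom = tmiss$atom, elem = tmiss$elem,
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    stringsAsFactors = FALSE)
  out <- rbind(atoms[, c("atom", "elem", "x", "y", "z")], add)
  out[order(match(out$atom, tpl$atom)), , drop = FALSE]
}
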