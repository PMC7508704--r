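## Small 3D geometry utilities shared across the package.
## Convention: coordinate sets are n x 3 matrices of row vectors; a frame is
## list(o = origin, R = 3x3 matrix whose ROWS are the x, y, z axis vectors),
## so world = local %*% R + o.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Rotation matrix for row-vector convention: rotated = v %*% rot_axis(u, ang).
## Equals the transpose of the usual column-vector rotation matrix.
rot_axis <- function(axis, angle) {
  u <- unitv(axis)
  ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  Rm <- diag(3) * ca + sa * K + (1 - ca) * (u %o% u)
  t(Rm)
}

frame_apply <- function(local, frame) {
  sweep(local %*% frame$R, 2, frame$o, "+")
}

## Orthonormal frame from an x-axis hint and a z-axis hint (z wins the
## orthogonalization); rows of R are the axes.
make_frame <- function(o, x_hint, z_hint) {
  z <- unitv(z_hint)
  x <- x_hint - sum(x_hint * z) * z
  x <- unitv(x)
  y <- cross3(z, x)
  list(o = as.numeric(o), R = rbind(x, y, z, deparse.level = 0))
}

#' Least-squares rigid-body superposition
#'
#' Computes the proper rotation and translation minimizing the RMSD between
#' two corresponding coordinate sets (the Kabsch algorithm via singular value
#' decomposition).  Reflections are never returned: the rotation determinant
#' is always +1.
#'
#' @param moving n x 3 matrix of coordinates to be moved.
#' @param fixed n x 3 matrix of target coordinates, row-correspondent with
#'   `moving`.
#' @return A list with elements `R` (3 x 3 rotation, row-vector convention:
#'   apply as `x %*% R`), `t` (translation), and `rmsd` (angstroms, after the
#'   fit).  Use [transform_coords()] to apply the result.
#' @examples
#' a <- matrix(rnorm(12), 4, 3)
#' tr <- superpose(a, a)
#' stopifnot(tr$rmsd < 1e-8)
#' @export
superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed)) stop("coordinate sets differ in size")
  if (nrow(moving) < 3) stop("need at least 3 corresponding atoms")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2, cm); B <- sweep(fixed, 2, cf)
  if (svd(A)$d[2] < 1e-8) stop("correspondence atoms are collinear")
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  ## column convention rotation U: B' = U %*% a; rows convention: a %*% t(U)
  U <- s$v %*% D %*% t(s$u)
  Rrow <- t(U)
  fit <- sweep(A %*% Rrow, 2, cf, "+")
  rmsd <- sqrt(mean(rowSums((fit - fixed)^2)))
  tvec <- cf - as.numeric(cm %*% Rrow)
  list(R = Rrow, t = tvec, rmsd = rmsd)
}

#' Apply a rigid transform returned by [superpose()]
#'
#' @param x n x 3 coordinate matrix.
#' @param tr transform list with `R` and `t`.
#' @return Transformed n x 3 matrix.
#' @export
transform_coords <- function(x, tr) {
  sweep(as.matrix(x) %*% tr$R, 2, tr$t, "+")
}

## RMSD without fitting (coordinates already aligned).
raw_rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
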