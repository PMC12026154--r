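# Low-level 3D geometry shared by structure building, hydrogen placement
# and trajectory superposition.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle at `b` formed by points a-b-c, in degrees
#' @noRd
bond_angle <- function(a, b, c) {
  u <- vunit(a - b)
  v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Dihedral angle p1-p2-p3-p4 in degrees, IUPAC sign convention
#' @noRd
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Returns the position `x` such that |x - c| = `bond`, the angle b-c-x is
#' `angle` degrees and the dihedral a-b-c-x is `dihedral` degrees.
#' @noRd
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- -dihedral * pi / 180
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Optimal rigid superposition of two coordinate sets
#'
#' Kabsch algorithm: the proper rotation and translation minimising the
#' (weighted) RMSD between `mobile` and `ref`.
#'
#' @param mobile,ref n x 3 coordinate matrices with matching rows.
#' @param weights optional non-negative per-point weights.
#' @return list with `rotation` (3 x 3, det = +1), `translation` (length 3;
#'   the transform is `x %*% t(rotation) + translation`), and `rmsd` after
#'   superposition.
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' fit <- kabsch_superpose(x, x)
#' fit$rmsd  # 0
#' @export
kabsch_superpose <- function(mobile, ref, weights = NULL) {
  mobile <- as.matrix(mobile)
  ref <- as.matrix(ref)
  if (!all(dim(mobile) == dim(ref)) || ncol(mobile) != 3)
    stop("'mobile' and 'ref' must be matching n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(ref * w)
  x <- sweep(mobile, 2, cm)
  y <- sweep(ref, 2, cr)
  h <- t(x * w) %*% y
  sv <- svd(h)
  if (min(sv$d) < 1e-12 && sum(sv$d > 1e-12) < 2)
    stop("degenerate geometry: points are collinear or coincident")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  xr <- x %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((xr - y)^2)))
  list(rotation = rot, translation = as.numeric(cr - cm %*% t(rot)),
       rmsd = rmsd)
}

apply_transform <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' Deterministic rotation-covariant molecular frame.
#'
#' Principal axes of the coordinates with signs fixed by the third moment of
#' the projections and handedness by the cross product, so that a rigidly
#' rotated molecule yields the identically rotated frame.  Used to orient the
#' SASA sphere lattice in the molecule frame.
#' @noRd
canonical_frame <- function(coords) {
  n <- nrow(coords)
  if (n < 3) return(diag(3))
  x <- sweep(coords, 2, colMeans(coords))
  ev <- eigen(crossprod(x) / n, symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  v2 <- ev$vectors[, 2]
  s1 <- sum((x %*% v1)^3)
  if (abs(s1) > 1e-8 && s1 < 0) v1 <- -v1
  s2 <- sum((x %*% v2)^3)
  if (abs(s2) > 1e-8 && s2 < 0) v2 <- -v2
  v3 <- vcross(v1, v2)
  cbind(v1, v2, v3)
}
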