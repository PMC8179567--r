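#' @useDynLib macrocycler, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DEG <- 180 / pi

#' Signed dihedral angle between four points
#'
#' Returns the IUPAC-convention signed torsion angle defined by four points:
#' 0 degrees for the eclipsed (cis) arrangement, +/-180 for anti (trans),
#' positive for a clockwise rotation of the far bond when sighting down the
#' central bond.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Signed angle in degrees, in the interval (-180, 180].
#' @examples
#' measure_dihedral(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)) # cis, 0
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  c12 <- cross3(b1, b2)
  c23 <- cross3(b2, b3)
  n12 <- sqrt(sum(c12^2))
  n23 <- sqrt(sum(c23^2))
  if (n12 < 1e-10 || n23 < 1e-10) {
    stop("degenerate geometry: three consecutive points are collinear")
  }
  x <- sum(c12 * c23)
  y <- sum(cross3(c12, c23) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Bond angle between three points
#'
#' @param p1,p2,p3 Numeric 3-vectors; the angle is measured at `p2`.
#' @return Angle in degrees, in [0, 180].
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, cosang))) * DEG
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates (NeRF extension)
#'
#' Given three previously placed reference points, returns the position of a
#' new point at the stated bond length from `c3`, bond angle at `c3` relative
#' to `c2`, and torsion about the `c2`-`c3` axis relative to the `c1`-`c2`
#' bond, such that `measure_dihedral(c1, c2, c3, new)` returns `torsion`.
#'
#' @param c1,c2,c3 Reference points (numeric 3-vectors).
#' @param bond Bond length c3-new (Angstrom).
#' @param angle Bond angle c2-c3-new (degrees).
#' @param torsion Dihedral c1-c2-c3-new (degrees).
#' @return Numeric 3-vector.
#' @export
place_atom <- function(c1, c2, c3, bond, angle, torsion) {
  th <- angle / DEG
  ph <- torsion / DEG
  bc <- c3 - c2
  bc <- bc / sqrt(sum(bc^2))
  ab <- c2 - c1
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("degenerate geometry: collinear reference points")
  n <- n / nn
  m <- cross3(n, bc)
  d <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c3 + d[1] * bc + d[2] * m + d[3] * n
}

#' Kabsch superposition of two point sets
#'
#' Finds the proper rotation (det = +1, chirality preserved) and translation
#' minimizing the root-mean-square deviation of `mobile` onto `reference`.
#'
#' @param mobile,reference n x 3 coordinate matrices with matching rows,
#'   n >= 3.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `x %*% t(rotation) + translation`), and `rmsd` (Angstrom).
#' @export
superpose_kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    stop("point sets must have equal length")
  }
  if (nrow(mobile) < 3) stop("insufficient points: need n >= 3")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm)
  b <- sweep(reference, 2, cr)
  h <- t(a) %*% b
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  diag3 <- diag(c(1, 1, d))
  rot <- sv$v %*% diag3 %*% t(sv$u)
  moved <- a %*% t(rot)
  rmsd <- sqrt(mean(rowSums((moved - b)^2)))
  list(rotation = rot, translation = as.numeric(cr - cm %*% t(rot)), rmsd = rmsd)
}

#' Apply a rigid transform returned by [superpose_kabsch()]
#'
#' @param coords n x 3 matrix.
#' @param fit List with `rotation` and `translation`.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, fit) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' Superposition-minimized RMSD between two poses
#'
#' Extracts the selected atoms from both poses in matching order, superposes
#' with [superpose_kabsch()], and returns the minimized RMSD.
#'
#' @param a,b `PeptidePose` objects of the same length.
#' @param atom_selection `"backbone"` (N, CA, C, O) or `"heavy"` (all
#'   non-hydrogen atoms; requires matching atom names).
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b, atom_selection = c("backbone", "heavy")) {
  atom_selection <- match.arg(atom_selection)
  xa <- pose_coords(a, atom_selection)
  xb <- pose_coords(b, atom_selection)
  if (nrow(xa) != nrow(xb) ||
      !identical(rownames(xa), rownames(xb))) {
    stop("atom-mapping error: selections do not match between poses")
  }
  superpose_kabsch(xa, xb)$rmsd
}

wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y <= -180] <- y[y <= -180] + 360
  ifelse(y == -180, 180, y)
}
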