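#' Dihedral (torsion) angle of four points
#'
#' Computes the torsion angle about the p2-p3 bond in the IUPAC sign
#' convention: 0 degrees for an eclipsed (cis) arrangement, 180 for
#' anti (trans), positive for a right-handed (clockwise looking from
#' p2 to p3) rotation of p4 relative to p1.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees in the interval (-180, 180].
#' @examples
#' dihedral(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(1, 1, 1))  # 0 (cis)
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-12 || sum(b1^2) < 1e-24 || sum(b3^2) < 1e-24)
    stop("dihedral: coincident consecutive points")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18)
    stop("dihedral: collinear triple, torsion undefined")
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / nb2
  ang <- atan2(y, x) * 180 / pi
  # map -180 -> +180 so the range is (-180, 180]
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Root-mean-square deviation from the best-fit plane
#'
#' Fits the least-squares plane through a point cloud (the plane through
#' the centroid whose normal is the smallest-variance principal direction)
#' and returns the RMS of the orthogonal point-to-plane distances. Used to
#' quantify co-planarity of the M-motif backbone.
#'
#' @param points numeric matrix, one row per point, 3 columns (Angstrom).
#' @return RMS orthogonal distance in Angstrom (>= 0; 0 iff coplanar).
#' @export
plane_fit_rms <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("plane_fit_rms: need at least 3 points")
  centred <- sweep(points, 2, colMeans(points))
  sv <- svd(centred, nu = 0, nv = 3)
  # guard against collinear input: two near-zero singular values
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12))
    stop("plane_fit_rms: points are collinear, plane undefined")
  sv$d[3] / sqrt(nrow(points))
}

#' Angular separation of two residues on an ideal helical wheel
#'
#' Projects two residues of one alpha-helix onto the helical wheel and
#' returns the angle between their side-chain directions, assuming the
#' ideal periodicity of 100 degrees per residue (3.6 residues/turn).
#' Residues on the same helix face return small angles; 18 residues apart
#' (five full turns) return exactly 0.
#'
#' @param i,j residue indices within one helix (any integers).
#' @param degrees_per_residue wheel step, default 100.
#' @return angle in degrees in [0, 360).
#' @export
wheel_separation <- function(i, j, degrees_per_residue = 100) {
  (abs(j - i) * degrees_per_residue) %% 360
}
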