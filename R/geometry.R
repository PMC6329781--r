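# Low-level vector geometry shared by the dihedral, backbone-building and
# superposition code. Everything here is vectorized over rows so that one call
# handles a whole residue range (or a whole frame set) at once.

.as_row_matrix <- function(p) {
  if (is.matrix(p)) p else matrix(p, nrow = 1L)
}

.row_cross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

.row_norm <- function(a) sqrt(rowSums(a * a))

.row_unit <- function(a) a / .row_norm(a)

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  x - 360 * ceiling((x - 180) / 360)
}

# Torsion without degeneracy checks; returns NA for degenerate quadruples.
# Used internally where missing atoms are tolerated (assign_phi_psi).
.dihedral_raw <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .row_cross(b1, b2)
  n2 <- .row_cross(b2, b3)
  x <- rowSums(n1 * n2)
  y <- rowSums(.row_cross(n1, n2) * .row_unit(b2))
  bad <- .row_norm(n1) < 1e-10 | .row_norm(n2) < 1e-10 | .row_norm(b2) < 1e-10
  ang <- atan2(y, x) * 180 / pi
  ang <- wrap_angle(ang)
  ang[bad] <- NA_real_
  ang
}

#' Signed torsion angle of four points
#'
#' Computes the torsion (dihedral) angle defined by four points using the
#' IUPAC sign convention: looking down the p2 -> p3 bond, a clockwise rotation
#' of the far bond relative to the near bond is positive. The backbone phi
#' angle is `dihedral_angle(C_prev, N, CA, C)` and psi is
#' `dihedral_angle(N, CA, C, N_next)`.
#'
#' @param p1,p2,p3,p4 numeric length-3 vectors, or n x 3 matrices of paired
#'   points (row i of each matrix forms one quadruple).
#' @return angle(s) in degrees in (-180, 180].
#' @examples
#' # trans (anti-periplanar) arrangement
#' dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, -1, 0))
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  p1 <- .as_row_matrix(p1); p2 <- .as_row_matrix(p2)
  p3 <- .as_row_matrix(p3); p4 <- .as_row_matrix(p4)
  ang <- .dihedral_raw(p1, p2, p3, p4)
  if (anyNA(ang)) {
    stop("undefined torsion: three consecutive points are collinear (or coincident)")
  }
  ang
}

# NeRF extension: place point D bonded to C with bond length `bond`, bond
# angle B-C-D `angle_deg`, and torsion A-B-C-D `torsion_deg`. A, B, C are
# n x 3 matrices (vectorized over rows); torsion may be scalar or length n.
.nerf_extend <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  ta <- torsion_deg * pi / 180
  bc <- .row_unit(c - b)
  n <- .row_unit(.row_cross(b - a, bc))
  m <- .row_cross(n, bc)
  d2 <- bond * cos(ta) * sin(th)
  d3 <- bond * sin(ta) * sin(th)
  d1 <- -bond * cos(th)
  c + bc * d1 + m * d2 + n * d3
}

#' Least-squares rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation that best superpose `mobile`
#' onto `fixed` in the least-squares sense. The fit is
#' `mobile %*% t(rotation) + translation`.
#'
#' @param fixed,mobile n x 3 coordinate matrices, paired by row, n >= 3.
#' @return an object of class `superposition`: list with elements `rotation`
#'   (3 x 3, det = +1), `translation` (length 3) and `rmsd` (Angstrom, after
#'   the transform).
#' @seealso [apply_superposition()]
#' @export
superpose <- function(fixed, mobile) {
  fixed <- as.matrix(fixed); mobile <- as.matrix(mobile)
  if (nrow(fixed) != nrow(mobile)) {
    stop("'fixed' and 'mobile' must contain the same number of paired points")
  }
  if (nrow(fixed) < 3L) stop("superposition requires at least 3 paired atoms")
  cf <- colMeans(fixed)
  cm <- colMeans(mobile)
  fc <- sweep(fixed, 2L, cf)
  mc <- sweep(mobile, 2L, cm)
  sv <- svd(crossprod(mc, fc))          # H = t(mobile_c) %*% fixed_c
  if (sv$d[2L] < 1e-10) {
    warning("degenerate (collinear) atom selection; superposition is not unique")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cf - as.vector(rot %*% cm)
  fitted <- mc %*% t(rot) + rep(cf, each = nrow(mc))
  rmsd <- sqrt(mean(rowSums((fitted - fixed)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#'
#' @param sup a `superposition` from [superpose()].
#' @param xyz n x 3 coordinate matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, xyz) {
  stopifnot(inherits(sup, "superposition"))
  xyz <- as.matrix(xyz)
  xyz %*% t(sup$rotation) + rep(sup$translation, each = nrow(xyz))
}

#' @export
print.superposition <- function(x, ...) {
  cat("Rigid-body superposition\n")
  cat(sprintf("  rmsd: %.4f Angstrom\n", x$rmsd))
  cat(sprintf("  det(rotation): %+.4f\n", det(x$rotation)))
  invisible(x)
}
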