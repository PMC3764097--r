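# Exact 3D primitives: torsion measurement, internal-coordinate atom
# placement (NeRF), rigid-body superposition. All angles in degrees,
# all lengths in Angstrom. Points are numeric length-3 vectors; point
# sets are n x 3 matrices.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

# collinearity threshold on cross-product norms (A^2)
.collinear_tol <- 1e-10

#' Wrap an angle to the canonical interval [-180, 180)
#'
#' The upper boundary maps down, so +180 becomes -180: every torsion has a
#' single canonical representative.
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into `[-180, 180)`.
#' @export
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w >= 180] <- -180  # guard against floating %% returning exactly 360
  w
}

.cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

.vnorm <- function(v) sqrt(sum(v * v))

.as_point3 <- function(p, arg = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p))) {
    stop(sprintf("'%s' must be a finite numeric vector of length 3", arg),
         call. = FALSE)
  }
  p
}

#' Measure a torsion (dihedral) angle
#'
#' Returns the torsion p1-p2-p3-p4 under the IUPAC sign convention: looking
#' down the p2 -> p3 bond, a clockwise rotation carrying the p1 side onto the
#' p4 side is positive; the eclipsed (cis) arrangement is 0.
#'
#' @param p1,p2,p3,p4 points as numeric length-3 vectors (Angstrom).
#' @return torsion angle in degrees, in `[-180, 180)`.
#' @seealso [place_atom()] for the inverse construction.
#' @examples
#' measure_dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))  # 0 (cis)
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  p1 <- .as_point3(p1, "p1"); p2 <- .as_point3(p2, "p2")
  p3 <- .as_point3(p3, "p3"); p4 <- .as_point3(p4, "p4")
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (.vnorm(b2) == 0) stop("degenerate torsion: p2 and p3 coincide", call. = FALSE)
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1 * n1) < .collinear_tol || sum(n2 * n2) < .collinear_tol) {
    stop("degenerate torsion: collinear or coincident points", call. = FALSE)
  }
  m <- .cross3(b2 / .vnorm(b2), n1)
  wrap_angle(atan2(sum(m * n2), sum(n1 * n2)) * RAD2DEG)
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three previously placed atoms a-b-c, constructs the position of a
#' fourth atom d bonded to c such that |d - c| equals `bond_length`, the
#' angle b-c-d equals `bond_angle`, and the torsion a-b-c-d equals
#' `dihedral` under the same sign convention as [measure_dihedral()].
#'
#' @param a,b,c frame points, numeric length-3 vectors (Angstrom).
#' @param bond_length c-d distance in Angstrom, > 0.
#' @param bond_angle b-c-d angle in degrees, in (0, 180).
#' @param dihedral a-b-c-d torsion in degrees.
#' @return the placed point as a numeric length-3 vector.
#' @export
place_atom <- function(a, b, c, bond_length, bond_angle, dihedral) {
  a <- .as_point3(a, "a"); b <- .as_point3(b, "b"); c <- .as_point3(c, "c")
  if (!is.finite(bond_length) || bond_length <= 0) {
    stop("'bond_length' must be > 0", call. = FALSE)
  }
  if (!is.finite(bond_angle) || bond_angle <= 0 || bond_angle >= 180) {
    stop("'bond_angle' must be in (0, 180) degrees", call. = FALSE)
  }
  bc <- c - b
  ab <- b - a
  if (sum(.cross3(ab, bc)^2) < .collinear_tol) {
    stop("degenerate frame: a, b, c are collinear or coincident", call. = FALSE)
  }
  bc_hat <- bc / .vnorm(bc)
  n_hat <- .cross3(ab, bc)
  n_hat <- n_hat / .vnorm(n_hat)
  m_hat <- .cross3(n_hat, bc_hat)
  theta <- bond_angle * DEG2RAD
  phi <- dihedral * DEG2RAD
  # local displacement in the (bc, m, n) frame
  d2 <- bond_length * c(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
  c + d2[1L] * bc_hat + d2[2L] * m_hat + d2[3L] * n_hat
}

# non-validating NeRF used in tight conformer-building loops
.nerf <- function(a, b, c, len, theta_rad, phi_rad) {
  bc <- c - b
  bc_hat <- bc / sqrt(sum(bc * bc))
  n <- .cross3(b - a, bc)
  n_hat <- n / sqrt(sum(n * n))
  m_hat <- .cross3(n_hat, bc_hat)
  st <- sin(theta_rad)
  c + len * (-cos(theta_rad) * bc_hat +
             st * cos(phi_rad) * m_hat +
             st * sin(phi_rad) * n_hat)
}

#' Measure the angle at vertex b (degrees)
#'
#' @param a,b,c points; the angle a-b-c is returned in degrees.
#' @return angle in `[0, 180]`.
#' @export
measure_angle <- function(a, b, c) {
  u <- .as_point3(a, "a") - .as_point3(b, "b")
  v <- .as_point3(c, "c") - .as_point3(b, "b")
  nu <- .vnorm(u); nv <- .vnorm(v)
  if (nu == 0 || nv == 0) stop("coincident points in angle measurement", call. = FALSE)
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * RAD2DEG
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the least-squares
#' RMSD between a mobile point set and a reference set, via SVD of the
#' cross-covariance matrix with the usual determinant correction so that
#' the rotation is always proper (no reflection).
#'
#' @param mobile,reference n x 3 matrices of paired points, n >= 3,
#'   not all collinear.
#' @return an object of class `"superposition"`: a list with `rotation`
#'   (3 x 3, det +1), `translation` (length-3), and `rmsd` (Angstrom).
#'   The transform maps mobile points as `p %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- .as_pointset(mobile, "mobile")
  reference <- .as_pointset(reference, "reference")
  n <- nrow(mobile)
  if (nrow(reference) != n) stop("point sets must have equal length", call. = FALSE)
  if (n < 3L) stop("at least 3 points are required", call. = FALSE)
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  x <- sweep(mobile, 2L, cm)
  y <- sweep(reference, 2L, cr)
  # degenerate if mobile points are collinear (rotation under-determined)
  if (.rank3(x) < 2L || .rank3(y) < 2L) {
    stop("degenerate configuration: points are collinear", call. = FALSE)
  }
  h <- crossprod(x, y)            # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- x %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - y)^2)))
  structure(
    list(rotation = rot,
         translation = as.numeric(cr - cm %*% t(rot)),
         rmsd = rmsd),
    class = "superposition"
  )
}

.rank3 <- function(m) {
  s <- svd(m, nu = 0L, nv = 0L)$d
  sum(s > max(s[1L], 1e-12) * 1e-9)
}

.as_pointset <- function(m, arg = "points") {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) != 3L || !all(is.finite(m))) {
    stop(sprintf("'%s' must be a finite numeric n x 3 matrix", arg), call. = FALSE)
  }
  m
}

#' Apply a superposition to a point set
#'
#' @param sup a `"superposition"` from [kabsch_superpose()].
#' @param points n x 3 matrix (or length-3 vector) of points.
#' @return transformed points, same shape as the input.
#' @export
apply_superposition <- function(sup, points) {
  stopifnot(inherits(sup, "superposition"))
  one <- is.null(dim(points))
  m <- if (one) matrix(points, 1L, 3L) else .as_pointset(points)
  out <- m %*% t(sup$rotation)
  out <- sweep(out, 2L, sup$translation, "+")
  if (one) as.numeric(out) else out
}

#' @export
print.superposition <- function(x, ...) {
  cat("Rigid-body superposition (Kabsch)\n")
  cat(sprintf("  rmsd: %.6f A\n", x$rmsd))
  cat("  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", paste(sprintf("%.4f", x$translation), collapse = " "), "\n")
  invisible(x)
}
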