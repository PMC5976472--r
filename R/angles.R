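#' Wrap angles into (-180, 180]
#'
#' All torsion angles in pepscape live on the half-open interval
#' \code{(-180, 180]} degrees. Wrapping is idempotent and maps both -180 and
#' +540 to +180.
#'
#' @param a Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, wrapped into (-180, 180].
#' @export
#' @examples
#' wrap_angle(c(-180, 180, 270, 540))
wrap_angle <- function(a) {
  w <- a %% 360
  w[w > 180] <- w[w > 180] - 360
  # x %% 360 can return 0 for inputs like -360; 0 is inside the interval
  w[w == -180] <- 180
  w
}

#' Circular mean of angles
#'
#' Mean direction of a set of angles in degrees, computed on the unit circle
#' so that e.g. \code{c(179, -179)} averages to 180 rather than 0. Naive
#' arithmetic means of torsions are wrong across the +/-180 seam and are not
#' used anywhere in this package.
#'
#' @param a Numeric vector of angles in degrees; `NA`s are dropped.
#' @return Length-1 numeric, the circular mean in (-180, 180].
#' @export
#' @examples
#' circular_mean(c(179, -179))
circular_mean <- function(a) {
  a <- a[!is.na(a)]
  if (length(a) == 0) return(NA_real_)
  r <- a * pi / 180
  wrap_angle(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

# Row-wise cross product of n x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

as_mat3 <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
}

#' Torsion angle defined by four points
#'
#' Signed dihedral about the p2-p3 axis under the IUPAC convention used by
#' standard trajectory tools (a right-handed alpha-helix has phi close to
#' -57 degrees). Inputs may be single points (length-3 vectors) or n x 3
#' matrices of corresponding points; the result is vectorised over rows.
#'
#' @param p1,p2,p3,p4 Length-3 numeric vectors or n x 3 matrices (Angstrom).
#' @return Numeric vector of torsions in degrees, in (-180, 180].
#' @export
#' @examples
#' dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)) # +90
dihedral <- function(p1, p2, p3, p4) {
  p1 <- as_mat3(p1); p2 <- as_mat3(p2); p3 <- as_mat3(p3); p4 <- as_mat3(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (any(rowSums(b1^2) == 0) || any(rowSums(b2^2) == 0) ||
      any(rowSums(b3^2) == 0)) {
    abort("dihedral(): consecutive points coincide")
  }
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (any(rowSums(n1^2) < 1e-20) || any(rowSums(n2^2) < 1e-20)) {
    abort("dihedral(): degenerate (collinear) geometry")
  }
  b2n <- b2 / sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(cross3(n1, n2) * b2n)
  wrap_angle(atan2(y, x) * 180 / pi)
}

# Natural-extension (NeRF) placement, vectorised over frames.
# A, B, C: n x 3 matrices of already-placed atoms. Places D bonded to C with
# |CD| = r, angle(B, C, D) = theta and dihedral(A, B, C, D) = tau (degrees).
nerf_place <- function(A, B, C, r, theta, tau) {
  A <- as_mat3(A); B <- as_mat3(B); C <- as_mat3(C)
  th <- theta * pi / 180
  ta <- tau * pi / 180
  bc <- C - B
  bc <- bc / sqrt(rowSums(bc^2))
  ab <- B - A
  n <- cross3(ab, bc)
  n <- n / sqrt(rowSums(n^2))
  m <- cross3(n, bc)
  d1 <- -r * cos(th)
  d2 <- r * sin(th) * cos(ta)
  d3 <- r * sin(th) * sin(ta)
  C + bc * d1 + m * d2 + n * d3
}
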