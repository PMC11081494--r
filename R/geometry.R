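# -- polygon geometry ---------------------------------------------------------
# Polygons are n x 2 matrices of (x, y) in micrometres, implicitly closed.
# x is the AP axis (+x posterior), y the DV axis (+y away from the midline).

#' Signed area of a polygon
#'
#' Shoelace formula; positive for counter-clockwise vertex order.
#'
#' @param poly numeric matrix with two columns (x, y).
#' @return Signed area in squared input units.
#' @export
poly_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Centroid of a polygon
#'
#' @param poly numeric matrix with two columns (x, y).
#' @return Length-2 numeric vector (x, y).
#' @export
poly_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Area-normalised second-moment (covariance) tensor of a polygon
#'
#' Returns the 2x2 covariance of the uniform distribution over the polygon's
#' interior, taken about its centroid. This is the shape tensor used for
#' moment ellipses, unstretching and cell-shape strain rates.
#'
#' @param poly numeric matrix with two columns (x, y).
#' @return 2x2 symmetric matrix.
#' @export
poly_second_moment <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) <= 0) stop("degenerate polygon: zero area")
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  exx <- sum(cr * (x^2 + x * xn + xn^2)) / (12 * a) - cx^2
  eyy <- sum(cr * (y^2 + y * yn + yn^2)) / (12 * a) - cy^2
  exy <- sum(cr * (2 * x * y + x * yn + xn * y + 2 * xn * yn)) / (24 * a) - cx * cy
  matrix(c(exx, exy, exy, eyy), 2, 2)
}

#' Acute angle of a direction from the AP axis
#'
#' Undirected angles are reported in [0, 90] degrees from AP, the convention
#' used for interface orientations and cell long-axis orientations.
#'
#' @param dx,dy direction components (AP, DV).
#' @return Angle in degrees in [0, 90].
#' @export
acute_angle_from_ap <- function(dx, dy) {
  ang <- atan2(dy, dx) * 180 / pi
  ang <- ang %% 180
  pmin(ang, 180 - ang)
}

#' Directed angle of a direction from the AP axis, modulo 180
#'
#' Used for axis-bearing quantities (bipolarity phase, long-axis direction)
#' where the two ends of the axis are equivalent: result in [0, 180).
#'
#' @param dx,dy direction components (AP, DV).
#' @return Angle in degrees in [0, 180).
#' @export
directed_angle_from_ap <- function(dx, dy) {
  (atan2(dy, dx) * 180 / pi) %% 180
}

# -- small 2x2 matrix helpers -------------------------------------------------

# eigen-decomposition based functions of symmetric positive-definite 2x2
spd_powm2 <- function(S, p) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(v^p, 2) %*% t(e$vectors)
}

spd_logm2 <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(log(v), 2) %*% t(e$vectors)
}

#' Maximum projected strain-rate deficit from junction misalignment
#'
#' If shrinking junctions are misaligned from an embryonic axis by at most
#' `angle_deg`, the axis-projected strain rate is reduced by at most
#' 100 * (1 - cos(angle)) percent relative to perfect alignment.
#'
#' @param angle_deg misalignment angle in degrees.
#' @return Deficit in percent.
#' @examples
#' projection_deficit_pct(15) # ~3.4
#' @export
projection_deficit_pct <- function(angle_deg) {
  100 * (1 - cos(angle_deg * pi / 180))
}
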