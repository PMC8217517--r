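# Small planar-geometry helpers shared across modules.
#
# Global coordinate convention (used everywhere in the package):
#   * head long axis along +x, sperm neck at the origin;
#   * +y is the sperm's RIGHT, so leftward structures have negative y;
#   * lengths in nm; angles stored in radians, reported in degrees.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# 2x2 rotation matrix; positive angle rotates +x toward +y
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

# rotate points (n x 2 matrix, rows = points) by theta about the origin
rotate_pts <- function(pts, theta) {
  pts %*% t(rot2(theta))
}

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) {
    abort("cannot normalize a zero-length vector")
  }
  v / n
}

# signed angle (radians) from vector `from` to vector `to`, positive toward +y
signed_angle <- function(from, to) {
  atan2(from[1] * to[2] - from[2] * to[1], sum(from * to))
}

# remove +/- pi jumps from a phase sequence before differentiation
unwrap_angles <- function(x) {
  x - c(0, cumsum(round(diff(x) / (2 * pi)))) * 2 * pi
}

# wrap angle into (-pi, pi]
wrap_angle <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

# perpendicular signed distance from point p to the infinite line through
# `origin` with unit direction `dir`; positive on the right-normal side
signed_perp_distance <- function(p, origin, dir) {
  d <- unitize(dir)
  n <- c(-d[2], d[1])
  sum((p - origin) * n)
}

# arclength-weighted (trapezoidal) mean of f sampled on a uniform grid
trapz_mean <- function(f) {
  n <- length(f)
  if (n < 2L) return(f[1])
  (sum(f) - (f[1] + f[n]) / 2) / (n - 1L)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(paste0("`", name, "` must be a single positive finite number"))
  }
  invisible(x)
}
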