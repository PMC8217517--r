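# Sliding-filament quantities of a planar flagellum.
#
# The flagellum is abstracted as two filaments r(s) +/- (a/2) n(s) separated
# by the flagellar diameter a. Curvature forces an arclength mismatch
# between them, Delta(s) = a (theta(s) - theta0), the flagellar sliding in
# the absence of basal sliding (Delta0 is fixed at 0 here; basal sliding is
# measured independently from neck landmarks, never inferred from the
# waveform).

check_uniform_waveform <- function(waveform) {
  s <- waveform$s_nm
  if (length(s) < 3L) abort("waveform needs at least 3 samples")
  dsv <- diff(s)
  if (any(abs(dsv - dsv[1]) > 1e-6 * dsv[1])) {
    abort("waveform must be on a uniform arclength grid (see resample_polyline)")
  }
  if (any(diff(waveform$x_nm) == 0 & diff(waveform$y_nm) == 0)) {
    abort("duplicate consecutive points in waveform")
  }
  dsv[1]
}

# d/ds by central differences, second-order one-sided at the ends
deriv_uniform <- function(v, ds) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * ds)
  d[1] <- (-3 * v[1] + 4 * v[2] - v[3]) / (2 * ds)
  d[n] <- (3 * v[n] - 4 * v[n - 1] + v[n - 2]) / (2 * ds)
  d
}

#' Tangent angle profile of a waveform
#'
#' The angle theta(s) between the head-frame x axis and the centerline
#' tangent, from central differences of the coordinates (second-order
#' one-sided at the ends), unwrapped so no sample jumps by +/- pi.
#'
#' @param waveform uniform-grid waveform tibble (`s_nm`, `x_nm`, `y_nm`).
#' @return tibble with `s_nm` and `theta_rad`; attribute `theta0` is the
#'   tangent angle at s = 0.
#' @export
tangent_angle <- function(waveform) {
  ds <- check_uniform_waveform(waveform)
  dx <- deriv_uniform(waveform$x_nm, ds)
  dy <- deriv_uniform(waveform$y_nm, ds)
  theta <- unwrap_angles(atan2(dy, dx))
  out <- tibble(s_nm = waveform$s_nm, theta_rad = theta)
  attr(out, "theta0") <- theta[1]
  out
}

#' Signed waveform curvature
#'
#' kappa(s) = d theta / d s by central differences on the uniform grid.
#' Under the COSA frame (+y = the sperm's right) a leftward bend gives
#' negative curvature.
#'
#' @param theta a tangent-angle tibble from [tangent_angle()] (or a
#'   waveform, which is converted first).
#' @return tibble with `s_nm` and `kappa_rad_per_nm`.
#' @export
signed_curvature <- function(theta) {
  if (is.null(theta$theta_rad)) theta <- tangent_angle(theta)
  s <- theta$s_nm
  if (length(s) < 3L) abort("need at least 3 samples for curvature")
  ds <- s[2] - s[1]
  tibble(s_nm = s, kappa_rad_per_nm = deriv_uniform(theta$theta_rad, ds))
}

#' Interfilament sliding profile
#'
#' Delta(s) = a (theta(s) - theta0): the arclength mismatch between the two
#' constituent filaments separated by the flagellar diameter `a`, taken in
#' the absence of basal sliding (Delta(0) = 0 exactly).
#'
#' @inheritParams signed_curvature
#' @param a flagellar diameter, nm (default 600).
#' @return tibble with `s_nm` and `delta_nm`.
#' @export
interfilament_sliding <- function(theta, a = 600) {
  if (!is.numeric(a) || length(a) != 1L || a <= 0) abort("`a` must be > 0")
  if (is.null(theta$theta_rad)) theta <- tangent_angle(theta)
  th0 <- attr(theta, "theta0") %||% theta$theta_rad[1]
  tibble(s_nm = theta$s_nm, delta_nm = a * (theta$theta_rad - th0))
}

#' Full sliding-filament profile
#'
#' Convenience wrapper returning theta, kappa and Delta on one grid.
#'
#' @inheritParams tangent_angle
#' @param a flagellar diameter, nm.
#' @return a `sliding_profile` tibble with columns `s_nm`, `theta_rad`,
#'   `kappa_rad_per_nm`, `delta_nm`; attributes `theta0` and `a`.
#' @export
sliding_profile <- function(waveform, a = 600) {
  th <- tangent_angle(waveform)
  ka <- signed_curvature(th)
  de <- interfilament_sliding(th, a = a)
  out <- tibble(s_nm = th$s_nm, theta_rad = th$theta_rad,
                kappa_rad_per_nm = ka$kappa_rad_per_nm,
                delta_nm = de$delta_nm)
  attr(out, "theta0") <- attr(th, "theta0")
  attr(out, "a") <- a
  class(out) <- c("sliding_profile", class(out))
  out
}

#' Arclength-averaged tail variables
#'
#' The three signed waveform characteristics: average beating amplitude
#' `y_bar` (arclength mean of y), average interfilament sliding `delta_bar`
#' (mean of Delta) and average signed curvature `kappa_bar` (mean of kappa,
#' reported in rad/um). Means are signed, not absolute, so a left-biased
#' population is skewed negative in all three. For a population the
#' variables are computed per specimen.
#'
#' @param x a uniform-grid waveform tibble or a `sperm_population`.
#' @param a flagellar diameter, nm.
#' @param ... passed between methods.
#' @return one-row tibble (`y_bar_nm`, `delta_bar_nm`,
#'   `kappa_bar_rad_per_um`, `theta0_deg`), or one row per specimen with
#'   `specimen_id` for a population.
#' @export
tail_variables <- function(x, a = 600, ...) UseMethod("tail_variables")

#' @export
tail_variables.default <- function(x, a = 600, ...) {
  prof <- sliding_profile(x, a = a)
  tibble(
    y_bar_nm = trapz_mean(x$y_nm),
    delta_bar_nm = trapz_mean(prof$delta_nm),
    kappa_bar_rad_per_um = trapz_mean(prof$kappa_rad_per_nm) * 1000,
    theta0_deg = rad2deg(attr(prof, "theta0"))
  )
}

#' @export
tail_variables.sperm_population <- function(x, a = 600, ...) {
  res <- purrr::map(x$centerline, tail_variables, a = a)
  dplyr::bind_cols(tibble(specimen_id = x$specimen_id),
                   dplyr::bind_rows(res))
}
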