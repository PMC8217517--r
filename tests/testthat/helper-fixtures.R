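# Fixtures built in code: analytic curves and toy landmark sets.

# circular-arc waveform of radius R (nm), spanning `arc` radians; bending
# left (toward -y) when left = TRUE. Uniform arclength grid.
arc_waveform <- function(R, arc = pi / 2, ds = R / 1000, left = TRUE) {
  s <- seq(0, R * arc, by = ds)
  sgn <- if (left) -1 else 1
  tibble::tibble(
    s_nm = s,
    x_nm = R * sin(s / R),
    y_nm = sgn * R * (1 - cos(s / R))
  )
}

straight_waveform <- function(L = 50000, ds = 100) {
  s <- seq(0, L, by = ds)
  tibble::tibble(s_nm = s, x_nm = s, y_nm = 0)
}

# sine centerline y = A sin(2 pi x / lambda), resampled to uniform arclength
sine_waveform <- function(A = 2000, lambda = 20000, L = 40000, ds = 50) {
  x <- seq(0, L, by = 5)
  y <- A * sin(2 * pi * x / lambda)
  resample_polyline(tibble::tibble(x_nm = x, y_nm = y), ds = ds)
}

# minimal symmetric landmark set for direct metric tests
toy_landmarks <- function() {
  list(
    head_axis = rbind(c(-9000, 0), c(-300, 0)),
    neck_midline = rbind(c(0, 0), c(1200, 0)),
    pc_axis = rbind(c(100, 250), c(600, 250)),
    rod_left = rbind(c(150, -150), c(850, -150)),
    rod_right = rbind(c(150, 150), c(600, 150)),
    mt_left = rbind(c(150, -180)),
    mt_right = rbind(c(150, 180)),
    mt_center = rbind(c(150, 0)),
    sc_left = cbind(100 + (0:8) * 110, rep(-280, 9)),
    sc_right = cbind(100 + (0:8) * 110, rep(280, 9))
  )
}

# parameters for noise-free geometry
noiseless_params <- function(...) {
  synth_params(landmark_noise_sd = 0, localization_noise_sd = 0, ...)
}

# least-squares (Kasa) circle fit; returns the radius
fit_circle_radius <- function(x, y) {
  fit <- lm(I(x^2 + y^2) ~ x + y)
  a <- coef(fit)[["x"]] / 2
  b <- coef(fit)[["y"]] / 2
  sqrt(coef(fit)[["(Intercept)"]] + a^2 + b^2)
}
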