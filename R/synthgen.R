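#' Generate one flagellar centerline for a beat class
#'
#' Builds an arclength-parametrized centerline in the head-anchored frame
#' (head long axis = +x, neck at the origin, +y = the sperm's right) from a
#' tangent-angle profile
#' \deqn{\theta(s) = \alpha + b\,(s/L) + A_\theta \sin(2\pi s/\lambda)}
#' where \eqn{\alpha} is the head-neck kink carried by the class phase,
#' \eqn{A_\theta = 2\pi A/\lambda} converts the lateral amplitude \eqn{A}
#' into a tangent amplitude, and the bend gain \eqn{b} is solved numerically
#' so that the normalized deflection (arclength mean of \eqn{y} divided by
#' \eqn{L}) equals the class target for the given phase. Left bends have
#' negative mean deflection; no class produces a sharp right bend.
#'
#' Uses the R random stream only when `psi` is not supplied.
#'
#' @param beat_class one of [beat_classes].
#' @param params a [synth_params()] object.
#' @param psi latent bend phase in the class sub-interval; drawn uniformly
#'   within the sub-interval when `NULL`.
#' @param ds arclength sample spacing, nm.
#' @return a tibble with columns `s_nm`, `x_nm`, `y_nm` (a uniform-grid
#'   waveform) and attributes `psi`, `beat_class`, `head_neck_angle_deg`.
#' @examples
#' p <- synth_params()
#' wf <- make_waveform("sharp_left", p, psi = -0.9)
#' mean(wf$y_nm) < 0
#' @export
make_waveform <- function(beat_class, params, psi = NULL, ds = 100) {
  if (!beat_class %in% beat_classes) {
    abort(paste0("unknown beat class: ", beat_class))
  }
  stopifnot_scalar_pos(params$flagellum_length, "flagellum_length")
  iv <- psi_intervals[[beat_class]]
  if (is.null(psi)) psi <- runif(1, iv[1], iv[2])

  L <- params$flagellum_length
  lambda <- params$wavelength
  A_theta <- 2 * pi * params$amplitude_by_class[[beat_class]] / lambda
  alpha <- deg2rad(-psi * params$head_kink_swing / 2)
  target_D <- deflection_target(beat_class, psi)

  s <- seq(0, L, by = ds)
  base_theta <- alpha + A_theta * sin(2 * pi * s / lambda)
  # smoothstep envelope saturating at the end of the midpiece, so the bend
  # develops over the neck/midpiece and the rest of the tail follows
  t_env <- pmin(s / 12000, 1)
  ramp <- t_env^2 * (3 - 2 * t_env)

  mean_defl <- function(b) {
    theta <- base_theta + b * ramp
    y <- as.vector(pracma::cumtrapz(s, sin(theta)))
    trapz_mean(y) / L
  }
  # mean deflection is monotone in the bend gain over this range
  b <- uniroot(function(b) mean_defl(b) - target_D,
               interval = c(-2.2, 1.0), tol = 1e-10)$root

  theta <- base_theta + b * ramp
  x <- as.vector(pracma::cumtrapz(s, cos(theta)))
  y <- as.vector(pracma::cumtrapz(s, sin(theta)))
  out <- tibble(s_nm = s, x_nm = x, y_nm = y)
  attr(out, "psi") <- psi
  attr(out, "beat_class") <- beat_class
  attr(out, "head_neck_angle_deg") <- rad2deg(alpha)
  attr(out, "bend_gain") <- b
  out
}

#' Generate neck landmarks and their ground truth for one specimen
#'
#' Lays out the neck template (rods, microtubule edges, proximal centriole,
#' segmented columns, neck midline) in a neck-local frame, imposes the
#' class-phase couplings, rotates the whole neck by the head-neck kink and
#' finally adds i.i.d. Gaussian noise to every landmark coordinate. All
#' couplings are affine in the latent phase `psi`:
#' `d_rostral = -psi * rod_slide_span / 2`,
#' `pc_dc_angle = -psi * pc_angle_swing / 2`,
#' `head_neck_angle = -psi * head_kink_swing / 2`, and the PC lateral shift
#' adds the coupling `-psi * pc_lateral_span / 2` to the template's 250 nm
#' rightward offset (the PC must stay on the head's right, where it serves
#' as the COSA chirality marker). In left-bent specimens the segmented
#' column chains additionally kink between segments 8 and 9.
#'
#' @inheritParams make_waveform
#' @param noisy add landmark noise? Set `FALSE` for noise-free geometry.
#' @return a list with `landmarks` (named list of point matrices, rows =
#'   points, rostral first) and `truth` (one-row tibble of the noise-free
#'   imposed metrics).
#' @export
make_neck_landmarks <- function(beat_class, params, psi = NULL, noisy = TRUE) {
  if (!beat_class %in% beat_classes) {
    abort(paste0("unknown beat class: ", beat_class))
  }
  iv <- psi_intervals[[beat_class]]
  if (is.null(psi)) psi <- runif(1, iv[1], iv[2])
  tpl <- neck_template

  delta     <- -psi * params$rod_slide_span / 2
  delta_sc  <- -psi * params$sc_slide_span / 2
  pc_angle  <- deg2rad(-psi * params$pc_angle_swing / 2)
  pc_shift  <- tpl$pc_y_offset - psi * params$pc_lateral_span / 2
  alpha     <- deg2rad(-psi * params$head_kink_swing / 2)
  sc_kink   <- if (psi < -0.2) deg2rad(-(psi + 0.2) / 0.8 * tpl$sc_bend_max_deg) else 0

  # neck-local frame: x runs caudally along the neck midline, y to the right
  r0 <- tpl$rod_rostral_x
  rod_left  <- rbind(c(r0 + delta / 2, -tpl$rod_y),
                     c(r0 + delta / 2 + tpl$rod_len_left, -tpl$rod_y))
  rod_right <- rbind(c(r0 - delta / 2, tpl$rod_y),
                     c(r0 - delta / 2 + tpl$rod_len_right, tpl$rod_y))
  mt_left   <- rbind(c(r0 + delta / 2, -tpl$mt_y))
  mt_right  <- rbind(c(r0 - delta / 2, tpl$mt_y))
  mt_center <- rbind(c(r0, 0))
  pc_dir <- c(cos(pc_angle), sin(pc_angle))
  pc_mid <- c(tpl$pc_mid_x, pc_shift)
  pc_axis <- rbind(pc_mid - tpl$pc_half_len * pc_dir,
                   pc_mid + tpl$pc_half_len * pc_dir)
  sc_x <- tpl$sc_x0 + (0:8) * tpl$sc_dx
  sc_left  <- cbind(sc_x + delta_sc / 2, rep(-tpl$sc_y, 9))
  sc_right <- cbind(sc_x - delta_sc / 2, rep(tpl$sc_y, 9))
  if (sc_kink != 0) {
    # rotate the segment 8 -> 9 step toward the left (-y)
    for (chain in c("sc_left", "sc_right")) {
      m <- get(chain)
      step <- m[9, ] - m[8, ]
      m[9, ] <- m[8, ] + as.vector(rot2(-sc_kink) %*% step)
      assign(chain, m)
    }
  }
  neck_midline <- rbind(c(0, 0), c(tpl$neck_length, 0))

  local_names <- c("neck_midline", "pc_axis", "rod_left", "rod_right",
                   "mt_left", "mt_right", "mt_center", "sc_left", "sc_right")
  lm <- list(head_axis = rbind(tpl$head_tip, tpl$head_base))
  for (nm in local_names) lm[[nm]] <- rotate_pts(get(nm), alpha)

  if (noisy && params$landmark_noise_sd > 0) {
    lm <- lapply(lm, function(m) {
      m + matrix(rnorm(length(m), sd = params$landmark_noise_sd), nrow(m), 2L)
    })
  }
  lm <- lapply(lm, function(m) {
    dimnames(m) <- list(NULL, c("x_nm", "y_nm"))
    m
  })

  truth <- tibble(
    psi = psi,
    d_rod_rostral_true = delta,
    d_rod_caudal_true = delta + (tpl$rod_len_left - tpl$rod_len_right),
    d_mt_rostral_true = delta,
    pc_dc_angle_true = rad2deg(pc_angle),
    pc_lateral_shift_true = pc_shift,
    head_neck_angle_true = rad2deg(alpha),
    sc_d_true = delta_sc,
    sc_kink_true = -rad2deg(sc_kink)
  )
  list(landmarks = lm, truth = truth)
}

#' Draw a STORM-like localization cloud for one distal-centriole rod
#'
#' Localizations are placed uniformly along the rod segment and uniformly
#' across its thickness (the left rod is longer and thicker than the right,
#' per the template), then jittered isotropically with the localization
#' noise. Intensities emulate photon counts (gamma distributed); `z_nm`
#' carries a small out-of-plane spread.
#'
#' @param landmarks a landmark list as returned by [make_neck_landmarks()].
#' @param side `"left"` or `"right"`.
#' @param params a [synth_params()] object.
#' @param n number of localizations; defaults to
#'   `params$localizations_per_rod`.
#' @return tibble with columns `side`, `x_nm`, `y_nm`, `z_nm`, `intensity`.
#' @export
make_rod_cloud <- function(landmarks, side = c("left", "right"), params,
                           n = params$localizations_per_rod) {
  side <- match.arg(side)
  if (n < 1) abort("cannot draw an empty rod cloud (0 localizations)")
  rod <- landmarks[[paste0("rod_", side)]]
  if (is.null(rod)) abort(paste0("no rod endpoints for side ", side))
  axis <- rod[2, ] - rod[1, ]
  len <- sqrt(sum(axis^2))
  if (len < .Machine$double.eps) abort("degenerate rod: zero length")
  u <- axis / len
  nvec <- c(-u[2], u[1])
  thick <- if (side == "left") neck_template$rod_thick_left else neck_template$rod_thick_right

  t_along <- runif(n, 0, len)
  off <- runif(n, -thick / 2, thick / 2)
  pts <- matrix(rod[1, ], n, 2L, byrow = TRUE) +
    outer(t_along, u) + outer(off, nvec)
  sdl <- params$localization_noise_sd
  if (sdl > 0) pts <- pts + matrix(rnorm(2L * n, sd = sdl), n, 2L)
  tibble(
    side = side,
    x_nm = pts[, 1],
    y_nm = pts[, 2],
    z_nm = rnorm(n, 0, 60) + if (sdl > 0) rnorm(n, 0, sdl) else 0,
    intensity = stats::rgamma(n, shape = 2, scale = 500)
  )
}

#' Draw beat classes for a population
#'
#' Uses the same counter-derived per-specimen random streams as
#' [make_population()], so the class labels of a population of any size are
#' reproducible without generating full specimens.
#'
#' @param n number of specimens.
#' @param weights named class proportions (summing to 1).
#' @param seed master seed.
#' @return factor vector of length `n` with levels [beat_classes].
#' @export
draw_beat_classes <- function(n, weights, seed) {
  if (n < 1) abort("`n` must be >= 1")
  cw <- cumsum(weights[beat_classes])
  out <- character(n)
  for (i in seq_len(n)) {
    set.seed(specimen_seed(seed, i))
    out[i] <- beat_classes[findInterval(runif(1), cw) + 1L]
  }
  factor(out, levels = beat_classes)
}

#' Generate a synthetic sperm population
#'
#' Draws `params$n_specimens` specimens: beat class (multinomial with the
#' class weights), latent phase `psi` within the class sub-interval, a
#' centerline, neck landmarks with ground truth, and left/right rod
#' localization clouds. Per-specimen random substreams are derived from the
#' master seed by counter, so identical parameters give byte-identical
#' populations and specimen k does not change when `n_specimens` changes.
#'
#' @param params a [synth_params()] object.
#' @param clouds generate rod localization clouds? (disable for speed when
#'   only landmarks/centerlines are needed)
#' @param ds centerline sample spacing, nm.
#' @return a `sperm_population` tibble with one row per specimen: identity
#'   and truth columns plus list-columns `centerline`, `landmarks`,
#'   `clouds`.
#' @examples
#' pop <- make_population(synth_params(n_specimens = 5, seed = 42))
#' dplyr::count(pop, beat_class_true)
#' @export
make_population <- function(params, clouds = TRUE, ds = 100) {
  if (params$n_specimens < 1) abort("`n_specimens` must be positive")
  cw <- cumsum(params$class_weights)
  rows <- vector("list", params$n_specimens)
  for (i in seq_len(params$n_specimens)) {
    set.seed(specimen_seed(params$seed, i))
    cls <- beat_classes[findInterval(runif(1), cw) + 1L]
    iv <- psi_intervals[[cls]]
    psi <- runif(1, iv[1], iv[2])
    wf <- make_waveform(cls, params, psi = psi, ds = ds)
    nl <- make_neck_landmarks(cls, params, psi = psi)
    cl <- if (clouds) {
      dplyr::bind_rows(
        make_rod_cloud(nl$landmarks, "left", params),
        make_rod_cloud(nl$landmarks, "right", params)
      )
    } else NULL
    rows[[i]] <- dplyr::bind_cols(
      tibble(specimen_id = sprintf("sp%04d", i),
             beat_class_true = factor(cls, levels = beat_classes)),
      nl$truth,
      tibble(centerline = list(wf), landmarks = list(nl$landmarks),
             clouds = list(cl))
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sperm_population", class(out))
  attr(out, "params") <- params
  out
}
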