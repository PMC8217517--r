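#' Beat-class labels used throughout the package
#'
#' The four bend categories of centriole orientation-based sperm analysis
#' (COSA), ordered from the strongest left bend to the right bend. No
#' generator or classifier in this package ever produces a "sharp right"
#' category; its absence in snap-frozen populations is treated as a finding.
#'
#' @export
beat_classes <- c("sharp_left", "mild_left", "straight", "slight_right")

# per-class sub-interval of the latent bend-phase coordinate psi.
# psi = -1 is the extreme left of the beat, +1 the extreme right; classes
# occupy ordered sub-intervals so class identity and bend magnitude agree.
psi_intervals <- list(
  sharp_left   = c(-1.0, -0.7),
  mild_left    = c(-0.7, -0.2),
  straight     = c(-0.2,  0.2),
  slight_right = c( 0.2,  0.6)
)

# Normalized-deflection target (mean y over arclength divided by flagellum
# length) as a piecewise-linear function of psi. The 0.01 gaps at the class
# boundaries straddle the classifier thresholds (T1 = 0.03, T2 = 0.12) so a
# noise-free specimen always classifies back to its own class.
deflection_targets <- list(
  sharp_left   = c(-0.200, -0.125),
  mild_left    = c(-0.115, -0.035),
  straight     = c(-0.025,  0.025),
  slight_right = c( 0.035,  0.075)
)

deflection_target <- function(beat_class, psi) {
  iv <- psi_intervals[[beat_class]]
  dv <- deflection_targets[[beat_class]]
  frac <- (psi - iv[1]) / (iv[2] - iv[1])
  dv[1] + frac * (dv[2] - dv[1])
}

# fixed neck-template geometry (nm), shared by the landmark generator and
# documented in the methods vignette. Lengths follow the reported left/right
# rod asymmetry; lateral offsets give a DC ~300 nm wide with the microtubule
# bundle 10% wider at the rostral end.
neck_template <- list(
  head_tip      = c(-9300, 0),
  head_base     = c(-300, 0),
  neck_length   = 1200,
  rod_y         = 150,   # lateral half-offset of the rods
  rod_rostral_x = 150,
  rod_len_left  = 700,
  rod_len_right = 450,
  rod_thick_left  = 120,
  rod_thick_right = 80,
  mt_y          = 180,
  pc_mid_x      = 350,
  pc_y_offset   = 250,   # PC sits right of the neck midline (COSA marker)
  pc_half_len   = 250,
  sc_x0         = 100,
  sc_dx         = 110,
  sc_y          = 280,
  sc_bend_max_deg = 25   # chain kink between segments 8 and 9 at psi = -1
)

#' Parameters of the synthetic sperm-specimen generator
#'
#' Bundles every tunable of the seeded specimen generator. Defaults encode
#' the study conditions the generated populations emulate: the bend-class
#' mixture observed in snap-frozen bovine sperm (15% sharp left, 30% mild
#' left, 36% straight, 19% slight right, and never a sharp right bend), and
#' neck-deformation couplings calibrated so that the sharp-left vs
#' slight-right contrast of the population reproduces the reported swings
#' (~24 degrees of proximal-centriole rocking, ~45 degrees of head-neck
#' kink, a 263-328 nm rostral rod/microtubule displacement and a 140-200 nm
#' proximal-centriole lateral shift). Because class means of the latent
#' phase psi sit at -0.85 and +0.4, the affine coupling
#' `metric = -psi * span / 2` realizes a contrast of `0.625 * span`; the
#' default spans are therefore the target swings divided by 0.625.
#'
#' @param n_specimens number of specimens in a generated population.
#' @param class_weights named non-negative proportions over
#'   [beat_classes]; must sum to 1.
#' @param flagellum_length flagellum arclength in nm.
#' @param wavelength wavelength of the sinusoidal beat component, nm.
#' @param amplitude_by_class lateral beat amplitude (nm) per class.
#' @param rod_slide_span total rostral rod-sliding swing across the beat
#'   (nm of `d` between psi = -1 and psi = +1).
#' @param pc_angle_swing total proximal-centriole rocking swing, degrees.
#' @param pc_lateral_span total proximal-centriole lateral-shift swing, nm.
#' @param head_kink_swing total head-neck kink swing, degrees.
#' @param sc_slide_span total segmented-column sliding swing, nm.
#' @param landmark_noise_sd isotropic Gaussian noise added to every landmark
#'   coordinate, nm.
#' @param localization_noise_sd isotropic jitter of STORM-like
#'   localizations, nm.
#' @param localizations_per_rod localizations drawn per rod point cloud.
#' @param pixel_size raster pixel size in nm.
#' @param seed master integer seed; per-specimen streams are derived from it
#'   by counter, so specimen k is identical in populations of any size.
#'
#' @return an object of class `synth_params` (a validated named list).
#' @examples
#' p <- synth_params(n_specimens = 10)
#' p$class_weights
#' @export
synth_params <- function(n_specimens = 248,
                         class_weights = c(sharp_left = 0.15, mild_left = 0.30,
                                           straight = 0.36, slight_right = 0.19),
                         flagellum_length = 55000,
                         wavelength = 20000,
                         amplitude_by_class = c(sharp_left = 3000, mild_left = 2800,
                                                straight = 2500, slight_right = 2600),
                         rod_slide_span = 472,
                         pc_angle_swing = 38.4,
                         pc_lateral_span = 272,
                         head_kink_swing = 72,
                         sc_slide_span = 200,
                         landmark_noise_sd = 10,
                         localization_noise_sd = 20,
                         localizations_per_rod = 600,
                         pixel_size = 100,
                         seed = 1L) {
  if (!is.numeric(n_specimens) || length(n_specimens) != 1L || n_specimens < 1) {
    abort("`n_specimens` must be a positive count")
  }
  if (length(class_weights) != 4L) {
    abort("`class_weights` must give 4 proportions, one per beat class")
  }
  if (is.null(names(class_weights))) names(class_weights) <- beat_classes
  class_weights <- class_weights[beat_classes]
  if (anyNA(class_weights) || any(class_weights < 0)) {
    abort("`class_weights` must be non-negative and named by beat class")
  }
  if (abs(sum(class_weights) - 1) > 1e-9) {
    abort("`class_weights` must sum to 1 (within 1e-9)")
  }
  stopifnot_scalar_pos(flagellum_length, "flagellum_length")
  stopifnot_scalar_pos(wavelength, "wavelength")
  if (is.null(names(amplitude_by_class))) names(amplitude_by_class) <- beat_classes
  amplitude_by_class <- amplitude_by_class[beat_classes]
  if (anyNA(amplitude_by_class) || any(amplitude_by_class < 0)) {
    abort("`amplitude_by_class` must be non-negative, one value per beat class")
  }
  for (nm in c("rod_slide_span", "pc_angle_swing", "pc_lateral_span",
               "head_kink_swing", "sc_slide_span", "landmark_noise_sd",
               "localization_noise_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      abort(paste0("`", nm, "` must be a single non-negative number"))
    }
  }
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  if (localizations_per_rod < 1) abort("`localizations_per_rod` must be >= 1")

  structure(list(
    n_specimens = as.integer(n_specimens),
    class_weights = class_weights,
    flagellum_length = flagellum_length,
    wavelength = wavelength,
    amplitude_by_class = amplitude_by_class,
    rod_slide_span = rod_slide_span,
    pc_angle_swing = pc_angle_swing,
    pc_lateral_span = pc_lateral_span,
    head_kink_swing = head_kink_swing,
    sc_slide_span = sc_slide_span,
    landmark_noise_sd = landmark_noise_sd,
    localization_noise_sd = localization_noise_sd,
    localizations_per_rod = as.integer(localizations_per_rod),
    pixel_size = pixel_size,
    seed = as.integer(seed)
  ), class = "synth_params")
}

#' @export
print.synth_params <- function(x, ...) {
  cat("<synth_params>\n")
  cat("  n_specimens:", x$n_specimens, " seed:", x$seed, "\n")
  cat("  class_weights:", paste(sprintf("%s=%.2f", names(x$class_weights),
                                        x$class_weights), collapse = " "), "\n")
  cat(sprintf("  flagellum %g nm, wavelength %g nm, pixel %g nm\n",
              x$flagellum_length, x$wavelength, x$pixel_size))
  cat(sprintf("  couplings: rod %g nm, PC angle %g deg, PC lateral %g nm, kink %g deg\n",
              x$rod_slide_span, x$pc_angle_swing, x$pc_lateral_span, x$head_kink_swing))
  cat(sprintf("  noise: landmarks %g nm, localizations %g nm (%d per rod)\n",
              x$landmark_noise_sd, x$localization_noise_sd, x$localizations_per_rod))
  invisible(x)
}

# deterministic per-specimen substream seed (counter-derived, < 2^31)
specimen_seed <- function(master_seed, i) {
  as.integer((as.double(master_seed) * 1000003 + i) %% 2147483647)
}
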