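# Centriole orientation-based sperm analysis (COSA).
#
# Each cell is first oriented so the proximal centriole (PC) lies on the
# sperm's right (+y) and the bigger rod on the left; bend direction is then
# comparable across cells, and the tail bend is classified into four
# categories. Classification thresholds are conventions (the original
# scoring was by eye) and are reported in the output.

pc_side_of <- function(landmarks) {
  pc <- landmarks$pc_axis
  if (is.null(pc)) return(NA_real_)
  mean(pc[, 2])
}

#' Normalize specimen chirality
#'
#' Mirror-flips the specimen about the head axis iff the PC marker lies on
#' the -y side, so that after normalization the PC is on the sperm's right.
#' When no PC marker is present, rod-size asymmetry is the proxy: the
#' longer rod belongs on the left. Applying the operation twice is the
#' identity.
#'
#' @param specimen one-row `sperm_population` tibble (centerline +
#'   landmarks in the head frame).
#' @param tol_nm rod-length difference below which the rod proxy is
#'   considered unusable.
#' @return the specimen with a logical `flip_applied` column added.
#' @export
normalize_orientation <- function(specimen, tol_nm = 20) {
  lm <- specimen$landmarks[[1]]
  pc_y <- pc_side_of(lm)
  flip <- NA
  if (is.finite(pc_y) && abs(pc_y) > 1e-9) {
    flip <- pc_y < 0
  } else {
    len <- function(m) sqrt(sum((m[2, ] - m[1, ])^2))
    if (!is.null(lm$rod_left) && !is.null(lm$rod_right)) {
      l1 <- len(lm$rod_left)
      l2 <- len(lm$rod_right)
      if (abs(l1 - l2) > tol_nm) {
        # the longer rod must sit on the left (-y)
        longer_y <- if (l1 >= l2) mean(lm$rod_left[, 2]) else mean(lm$rod_right[, 2])
        flip <- longer_y > 0
      }
    }
  }
  if (is.na(flip)) {
    abort("no usable chirality marker: PC absent and rods equal within tolerance")
  }
  out <- if (flip) mirror_specimen(specimen) else specimen
  out$flip_applied <- flip
  out
}

#' Classify the tail bend of an oriented specimen
#'
#' Computes the normalized deflection `D = y_bar / L` (arclength mean of y
#' over the traced flagellum length) and assigns:
#' straight for `|D| < T1`; slight right for `D >= T1`; mild left for
#' `-T2 < D <= -T1`; sharp left for `D <= -T2`. Left bends carry a
#' subtype: type 1 when the head-neck kink dominates
#' (`|head-neck angle| >= K`), else type 2. A rightward deflection beyond
#' `T2` is still reported as slight right but flags a warning counter,
#' since the absence of sharp right bends is a population-level finding,
#' not an impossibility.
#'
#' @param x an oriented specimen (one-row `sperm_population`) or a
#'   uniform-grid waveform tibble.
#' @param head_neck_angle_deg the measured head-neck angle (degrees);
#'   taken from the specimen's landmarks when omitted. Required only for
#'   subtyping of left bends.
#' @param T1,T2 deflection thresholds as fractions of flagellum length.
#' @param K kink threshold, degrees, separating type 1 from type 2.
#' @return one-row tibble: `category`, `subtype`, `deflection`,
#'   `sharp_right_flag`.
#' @export
classify_bend <- function(x, head_neck_angle_deg = NULL,
                          T1 = 0.03, T2 = 0.12, K = 30) {
  if (is.data.frame(x) && !is.null(x[["centerline"]])) {
    wf <- x$centerline[[1]]
    if (is.null(head_neck_angle_deg) && !is.null(x[["landmarks"]])) {
      lm <- x$landmarks[[1]]
      head_neck_angle_deg <- head_neck_angle(lm)
    }
  } else {
    wf <- x
  }
  D <- trapz_mean(wf$y_nm) / max(wf$s_nm)
  flag <- FALSE
  if (D <= -T2) {
    category <- "sharp_left"
  } else if (D <= -T1) {
    category <- "mild_left"
  } else if (D < T1) {
    category <- "straight"
  } else {
    category <- "slight_right"
    if (D >= T2) flag <- TRUE
  }
  subtype <- "none"
  if (category %in% c("sharp_left", "mild_left")) {
    if (is.null(head_neck_angle_deg)) {
      abort("`head_neck_angle_deg` is required to subtype a left bend")
    }
    subtype <- if (abs(head_neck_angle_deg) >= K) "type1" else "type2"
  }
  tibble(
    category = factor(category, levels = beat_classes),
    subtype = factor(subtype, levels = c("type1", "type2", "none")),
    deflection = D,
    sharp_right_flag = flag
  )
}

#' Orient and classify every specimen of a population
#'
#' @param pop a `sperm_population` tibble.
#' @inheritParams classify_bend
#' @return tibble with one row per specimen: `specimen_id`, `category`,
#'   `subtype`, `deflection`, `flip_applied`, `sharp_right_flag`.
#' @export
classify_population <- function(pop, T1 = 0.03, T2 = 0.12, K = 30) {
  rows <- purrr::map(seq_len(nrow(pop)), function(i) {
    sp <- normalize_orientation(pop[i, ])
    cb <- classify_bend(sp, T1 = T1, T2 = T2, K = K)
    dplyr::bind_cols(tibble(specimen_id = sp$specimen_id,
                            flip_applied = sp$flip_applied), cb)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "thresholds") <- c(T1 = T1, T2 = T2, K = K)
  out
}

#' Bend-class distribution of a population
#'
#' @param classes factor/character vector of categories, or a tibble with a
#'   `category` column (e.g. from [classify_population()]).
#' @return tibble with `category`, `n`, `fraction`; fractions sum to 1.
#' @export
population_distribution <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$category
  if (length(classes) == 0L) abort("empty class list")
  classes <- factor(classes, levels = beat_classes)
  tab <- table(classes)
  tibble(
    category = factor(names(tab), levels = beat_classes),
    n = as.integer(tab),
    fraction = as.numeric(tab) / length(classes)
  )
}
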