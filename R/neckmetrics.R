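# Signed nanometric measurements of neck substructures.
#
# Sign conventions (COSA frame, +y = sperm's right):
#   * displacement d = projection difference (right minus left) on the
#     rostral direction of the neck midline; +d means the right-side
#     structure sits more rostrally ("higher") than the left;
#   * angles are signed, positive toward the sperm's right, in (-180, 180];
#   * all signed metrics are odd under a mirror flip of the specimen.

neck_rostral_dir <- function(landmarks) {
  nm <- landmarks$neck_midline
  if (is.null(nm)) abort("neck midline landmarks are missing")
  unitize(nm[1, ] - nm[2, ])   # rows: rostral, caudal
}

neck_caudal_dir <- function(landmarks) -neck_rostral_dir(landmarks)

#' Rod and microtubule sliding from landmarks
#'
#' Projects the rod endpoints (and the microtubule rostral edges) on the
#' rostral direction of the neck midline and reports
#' `d = right projection - left projection` at the caudal and rostral rod
#' ends. The DC microtubules are connected to the axoneme, so only their
#' rostral distance is measured. Note that the caudal rod distance carries
#' the rods' built-in length asymmetry on top of any sliding.
#'
#' @param landmarks named landmark list (see [make_neck_landmarks()] /
#'   [read_landmarks()]).
#' @return one-row tibble: `d_rod_rostral`, `d_rod_caudal`,
#'   `d_mt_rostral` (signed nm).
#' @export
rod_sliding <- function(landmarks) {
  u <- neck_rostral_dir(landmarks)
  need <- c("rod_left", "rod_right", "mt_left", "mt_right")
  if (any(vapply(need, function(x) is.null(landmarks[[x]]), logical(1)))) {
    abort("missing rod or microtubule endpoints")
  }
  proj <- function(p) sum(p * u)
  tibble(
    d_rod_rostral = proj(landmarks$rod_right[1, ]) - proj(landmarks$rod_left[1, ]),
    d_rod_caudal = proj(landmarks$rod_right[2, ]) - proj(landmarks$rod_left[2, ]),
    d_mt_rostral = proj(landmarks$mt_right[1, ]) - proj(landmarks$mt_left[1, ])
  )
}

#' Proximal-centriole rocking angle and lateral shift
#'
#' The rocking angle is the signed angle from the neck midline direction to
#' the PC axis direction; the lateral shift is the signed perpendicular
#' distance from the PC midpoint to the neck midline (negative = the
#' sperm's left).
#'
#' @inheritParams rod_sliding
#' @return one-row tibble: `pc_dc_angle_deg`, `pc_lateral_shift_nm`.
#' @export
pc_metrics <- function(landmarks) {
  if (is.null(landmarks$pc_axis)) abort("PC axis landmarks are missing")
  d_neck <- neck_caudal_dir(landmarks)
  pc <- landmarks$pc_axis
  pc_dir <- pc[2, ] - pc[1, ]
  if (sqrt(sum(pc_dir^2)) < .Machine$double.eps) abort("degenerate PC axis")
  ang <- rad2deg(signed_angle(d_neck, pc_dir))
  mid <- colMeans(pc)
  shift <- signed_perp_distance(mid, landmarks$neck_midline[1, ], d_neck)
  tibble(pc_dc_angle_deg = ang, pc_lateral_shift_nm = shift)
}

#' Head-neck kink angle
#'
#' Signed angle from the head long axis to the neck midline, degrees.
#' Negative values mean the neck deflects toward the sperm's left relative
#' to the head axis. (When the head kinks left during a left beat, the
#' neck midline lies to the head's right, so left-class specimens show
#' positive values under this convention.)
#'
#' @param head_axis 2x2 matrix (rows rostral, caudal) or a full landmark
#'   list, in which case `neck_midline` may be omitted.
#' @param neck_midline 2x2 matrix (rows rostral, caudal).
#' @return signed angle in degrees, in (-180, 180].
#' @export
head_neck_angle <- function(head_axis, neck_midline = NULL) {
  if (is.list(head_axis) && !is.matrix(head_axis)) {
    lm <- head_axis
    neck_midline <- lm$neck_midline
    head_axis <- lm$head_axis
  }
  if (is.null(head_axis) || is.null(neck_midline)) {
    abort("both head axis and neck midline are required")
  }
  h <- head_axis[2, ] - head_axis[1, ]
  n <- neck_midline[2, ] - neck_midline[1, ]
  if (sqrt(sum(h^2)) < .Machine$double.eps ||
      sqrt(sum(n^2)) < .Machine$double.eps) {
    abort("degenerate axis")
  }
  rad2deg(signed_angle(h, n))
}

#' Segmented-column displacements and segment angles
#'
#' Per-segment signed displacement `d` between each right-column segment
#' and its corresponding left segment (same convention as [rod_sliding()]),
#' and, for each of the 8 segment-to-segment steps of the mean chain, the
#' signed angle of the step relative to the neck midline. In left-bent
#' specimens the largest angle occurs at the step between segments 8 and 9.
#'
#' @inheritParams rod_sliding
#' @return tibble with 9 rows: `segment`, `d_nm`, `step_angle_deg` (angle
#'   of the step leaving this segment; `NA` for segment 9).
#' @export
sc_metrics <- function(landmarks) {
  L <- landmarks$sc_left
  R <- landmarks$sc_right
  if (is.null(L) || is.null(R)) abort("segmented-column chains are missing")
  if (nrow(L) != nrow(R)) abort("unequal segmented-column chain lengths")
  u <- neck_rostral_dir(landmarks)
  d <- (R %*% u) - (L %*% u)
  mid <- (L + R) / 2
  dn <- neck_caudal_dir(landmarks)
  steps <- diff(mid)
  ang <- apply(steps, 1, function(v) rad2deg(signed_angle(dn, v)))
  tibble(
    segment = seq_len(nrow(L)),
    d_nm = as.vector(d),
    step_angle_deg = c(ang, NA_real_)
  )
}

#' Distances from the PC centerline to the microtubule bundle
#'
#' Perpendicular distance from each microtubule rostral edge (left, center,
#' right) to the infinite line through the PC long axis.
#'
#' @inheritParams rod_sliding
#' @return one-row tibble: `mt_dist_left`, `mt_dist_center`,
#'   `mt_dist_right` (nm, non-negative).
#' @export
mt_distances_from_pc <- function(landmarks) {
  pc <- landmarks$pc_axis
  if (is.null(pc)) abort("PC axis landmarks are missing")
  dir <- pc[2, ] - pc[1, ]
  if (sqrt(sum(dir^2)) < .Machine$double.eps) abort("degenerate PC axis")
  dst <- function(p) abs(signed_perp_distance(p, pc[1, ], dir))
  tibble(
    mt_dist_left = dst(landmarks$mt_left[1, ]),
    mt_dist_center = dst(landmarks$mt_center[1, ]),
    mt_dist_right = dst(landmarks$mt_right[1, ])
  )
}

#' Structure extent by the 50%-of-peak rule
#'
#' Projects localizations on an axis, forms an intensity-weighted histogram
#' and measures the distance between the 50%-of-peak crossings outward of
#' the first and last local intensity maxima (linear interpolation between
#' bin centers). This is the rod length/width rule; it is invariant to
#' rescaling all intensities by a positive constant.
#'
#' @param cloud tibble with `x_nm`, `y_nm` and optionally `intensity`
#'   columns (a rod localization cloud).
#' @param axis length-2 direction to measure along (defaults to +x).
#' @param bin_nm histogram bin width, nm (default 20, about the
#'   localization precision of the imaging this emulates).
#' @return extent in nm.
#' @export
profile_extent_50 <- function(cloud, axis = c(1, 0), bin_nm = 20) {
  if (nrow(cloud) < 10L) abort("need at least 10 localizations")
  stopifnot_scalar_pos(bin_nm, "bin_nm")
  u <- unitize(axis)
  t <- cloud$x_nm * u[1] + cloud$y_nm * u[2]
  if (diff(range(t)) < .Machine$double.eps) {
    abort("all localizations project to a single point")
  }
  w <- cloud[["intensity"]] %||% rep(1, nrow(cloud))
  breaks <- seq(floor(min(t) / bin_nm) * bin_nm - bin_nm,
                ceiling(max(t) / bin_nm) * bin_nm + bin_nm, by = bin_nm)
  bin <- findInterval(t, breaks, rightmost.closed = TRUE)
  counts <- numeric(length(breaks) - 1L)
  agg <- tapply(w, bin, sum)
  counts[as.integer(names(agg))] <- agg
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2

  n <- length(counts)
  cpad <- c(0, counts, 0)
  is_max <- counts > 0 & counts >= cpad[1:n] & counts >= cpad[3:(n + 2)]
  if (!any(is_max)) abort("no local intensity maximum found")
  first <- which(is_max)[1]
  last <- tail(which(is_max), 1)

  cross_out <- function(peak, dir) {
    half <- counts[peak] / 2
    k <- peak
    while (k + dir >= 1 && k + dir <= n && counts[k + dir] >= half) k <- k + dir
    k2 <- k + dir
    if (k2 < 1 || k2 > n) return(centers[k] + dir * bin_nm / 2)
    # linear interpolation between bin centers across the crossing
    frac <- (counts[k] - half) / (counts[k] - counts[k2])
    centers[k] + dir * frac * bin_nm
  }
  cross_out(last, +1L) - cross_out(first, -1L)
}

#' Pixel-sum intensity in a round ROI
#'
#' Sums the pixels whose centers fall inside a disc (default diameter
#' 1.5 um) centered on the given point — the intensity readout used to
#' quantify protein amounts around the PC and DC.
#'
#' @param image image matrix with `pixel_size_nm`/`x0_nm`/`y0_nm`
#'   attributes (see [rasterize_centerline()]), or a plain matrix with
#'   `pixel_size` given.
#' @param center length-2 ROI center, nm.
#' @param diameter_nm ROI diameter, nm.
#' @param pixel_size pixel size override, nm.
#' @return summed pixel intensity.
#' @export
roi_sum_intensity <- function(image, center, diameter_nm = 1500,
                              pixel_size = NULL) {
  px <- pixel_size %||% attr(image, "pixel_size_nm")
  if (is.null(px)) abort("pixel size unknown")
  x0 <- attr(image, "x0_nm") %||% 0
  y0 <- attr(image, "y0_nm") %||% 0
  xs <- x0 + (seq_len(ncol(image)) - 1) * px
  ys <- y0 + (seq_len(nrow(image)) - 1) * px
  inside <- outer((ys - center[2])^2, (xs - center[1])^2, "+") <=
    (diameter_nm / 2)^2
  if (!any(inside)) abort("ROI lies fully outside the image")
  sum(unclass(image)[inside])
}

#' Measure all neck metrics for a population
#'
#' Runs the landmark-based metrics (rod/microtubule sliding, PC rocking and
#' lateral shift, head-neck kink, segmented-column summary, PC-line to
#' microtubule distances) and, when localization clouds are present, the
#' 50%-peak rod length and width for both sides.
#'
#' @param pop a `sperm_population` tibble (oriented specimens).
#' @param extents measure rod length/width from the localization clouds?
#' @param bin_nm histogram bin for [profile_extent_50()].
#' @return tibble with one row per specimen.
#' @export
measure_neck <- function(pop, extents = TRUE, bin_nm = 20) {
  rows <- purrr::map(seq_len(nrow(pop)), function(i) {
    lm <- pop$landmarks[[i]]
    sc <- sc_metrics(lm)
    out <- dplyr::bind_cols(
      tibble(specimen_id = pop$specimen_id[i]),
      rod_sliding(lm),
      pc_metrics(lm),
      tibble(head_neck_angle_deg = head_neck_angle(lm)),
      tibble(sc_d_mean_nm = mean(sc$d_nm),
             sc_max_step_angle_deg = sc$step_angle_deg[
               which.max(abs(sc$step_angle_deg))]),
      mt_distances_from_pc(lm)
    )
    cl <- pop$clouds[[i]]
    if (extents && !is.null(cl)) {
      ext <- purrr::map(c(left = "left", right = "right"), function(sd) {
        sub <- cl[cl$side == sd, ]
        rod <- lm[[paste0("rod_", sd)]]
        axis <- rod[2, ] - rod[1, ]
        c(len = profile_extent_50(sub, axis, bin_nm),
          wid = profile_extent_50(sub, c(-axis[2], axis[1]), bin_nm))
      })
      out <- dplyr::bind_cols(out, tibble(
        rod_length_left = ext$left[["len"]], rod_width_left = ext$left[["wid"]],
        rod_length_right = ext$right[["len"]], rod_width_right = ext$right[["wid"]]
      ))
    }
    out
  })
  dplyr::bind_rows(rows)
}
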