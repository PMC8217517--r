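#' Express a traced polyline in the head-anchored frame
#'
#' Applies the rigid rotation and translation that aligns the head long
#' axis with the +x axis and centers the sperm neck at the origin. If a
#' proximal-centriole marker is supplied and falls on the sperm's left
#' (-y) after alignment, the specimen is mirror-flipped about the x axis
#' so the PC always leans to the head's right — the COSA chirality
#' convention — and the flip is recorded. Positive y then means a
#' flagellar point on the sperm's right.
#'
#' @param polyline tibble/data frame with `x_nm`, `y_nm` (and optionally
#'   `s_nm`) columns, ordered from the neck outward.
#' @param head_axis unit vector of the head long axis (pointing caudally,
#'   from head tip toward the neck), length-2 numeric.
#' @param neck_point position of the neck, length-2 numeric (nm).
#' @param pc_point optional proximal-centriole marker position (same frame
#'   as the polyline); triggers the chirality flip when needed.
#' @return the aligned waveform tibble (`x_nm`, `y_nm`, `s_nm`) with
#'   attribute `head_frame = list(origin, x_axis, flipped)`.
#' @export
align_to_head_frame <- function(polyline, head_axis, neck_point,
                                pc_point = NULL) {
  if (sqrt(sum(head_axis^2)) < .Machine$double.eps) {
    abort("zero-length head axis")
  }
  if (any(!is.finite(neck_point))) abort("`neck_point` must be finite")
  u <- unitize(head_axis)
  ang <- atan2(u[2], u[1])
  R <- rot2(-ang)
  pts <- cbind(polyline$x_nm, polyline$y_nm)
  pts <- sweep(pts, 2, neck_point) %*% t(R)
  flipped <- FALSE
  if (!is.null(pc_point)) {
    pc <- as.vector(R %*% (pc_point - neck_point))
    if (pc[2] < 0) {
      pts[, 2] <- -pts[, 2]
      flipped <- TRUE
    }
  }
  s <- polyline[["s_nm"]] %||% c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  out <- tibble(s_nm = s, x_nm = pts[, 1], y_nm = pts[, 2])
  attr(out, "head_frame") <- list(origin = neck_point, x_axis = u,
                                  flipped = flipped)
  out
}

#' Resample a polyline onto a uniform arclength grid
#'
#' Linear interpolation of x and y along cumulative arclength onto the grid
#' `0, ds, 2 ds, ...`. A uniform grid is required by the finite-difference
#' operators downstream.
#'
#' @param polyline tibble with `x_nm`, `y_nm` and optionally `s_nm`.
#' @param ds grid spacing, nm; must be positive and smaller than the total
#'   length.
#' @return waveform tibble (`s_nm`, `x_nm`, `y_nm`) on the uniform grid.
#' @export
resample_polyline <- function(polyline, ds) {
  xy <- cbind(polyline$x_nm, polyline$y_nm)
  s <- polyline[["s_nm"]] %||% c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
  total <- s[length(s)]
  if (!is.numeric(ds) || ds <= 0 || ds >= total) {
    abort("`ds` must satisfy 0 < ds < total length")
  }
  grid <- seq(0, total, by = ds)
  tibble(
    s_nm = grid,
    x_nm = approx(s, xy[, 1], xout = grid)$y,
    y_nm = approx(s, xy[, 2], xout = grid)$y
  )
}

#' Mirror a specimen about the head axis
#'
#' Negates the y coordinate of the centerline, every landmark and every
#' localization, and the signed truth metrics. Used for chirality
#' normalization and for the antisymmetry property tests: all signed
#' waveform and neck metrics are odd under this flip.
#'
#' @param specimen one-row `sperm_population` tibble (or a plain waveform
#'   tibble, in which case only `y_nm` is negated).
#' @return the mirrored object.
#' @export
mirror_specimen <- function(specimen) {
  if (is.data.frame(specimen) && !is.null(specimen[["y_nm"]])) {
    specimen$y_nm <- -specimen$y_nm
    return(specimen)
  }
  row <- specimen
  if (!is.null(row[["centerline"]])) {
    row$centerline <- lapply(row$centerline, function(wf) {
      wf$y_nm <- -wf$y_nm
      wf
    })
  }
  if (!is.null(row[["landmarks"]])) {
    row$landmarks <- lapply(row$landmarks, function(lm) {
      lm <- lapply(lm, function(m) {
        m[, 2] <- -m[, 2]
        m
      })
      # left/right labels refer to the sperm's own sides, which swap
      for (pair in list(c("rod_left", "rod_right"), c("mt_left", "mt_right"),
                        c("sc_left", "sc_right"),
                        c("bars_left", "bars_right"))) {
        if (!is.null(lm[[pair[1]]]) || !is.null(lm[[pair[2]]])) {
          tmp <- lm[[pair[1]]]
          lm[[pair[1]]] <- lm[[pair[2]]]
          lm[[pair[2]]] <- tmp
        }
      }
      lm
    })
  }
  if (!is.null(row[["clouds"]])) {
    row$clouds <- lapply(row$clouds, function(cl) {
      if (!is.null(cl)) {
        cl$y_nm <- -cl$y_nm
        cl$side <- c(left = "right", right = "left")[cl$side]
      }
      cl
    })
  }
  for (col in c("d_rod_rostral_true", "d_rod_caudal_true", "d_mt_rostral_true",
                "pc_dc_angle_true", "pc_lateral_shift_true",
                "head_neck_angle_true", "sc_d_true", "sc_kink_true")) {
    if (!is.null(row[[col]])) row[[col]] <- -row[[col]]
  }
  row
}
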