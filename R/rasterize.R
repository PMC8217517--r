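#' Rasterize a centerline into a grayscale image
#'
#' Draws the flagellar centerline with a Gaussian cross-section (peak 1) on
#' a pixel grid that covers the curve with the requested margin. Used to
#' turn generated specimens into image fixtures for the tracer.
#'
#' @param xy two-column matrix or data frame of centerline points, nm.
#' @param pixel_size pixel size, nm.
#' @param line_width full width at half maximum of the line profile, nm.
#' @param margin_nm margin added around the curve's bounding box.
#' @return numeric matrix (rows = y, columns = x) in `[0, 1]` with
#'   attributes `pixel_size_nm`, `x0_nm`, `y0_nm` (nm position of the
#'   center of pixel `[1, 1]`).
#' @export
rasterize_centerline <- function(xy, pixel_size, line_width = 300,
                                 margin_nm = 2000) {
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  xy <- as.matrix(xy[, 1:2])
  x0 <- min(xy[, 1]) - margin_nm
  y0 <- min(xy[, 2]) - margin_nm
  nx <- ceiling((max(xy[, 1]) + margin_nm - x0) / pixel_size) + 1L
  ny <- ceiling((max(xy[, 2]) + margin_nm - y0) / pixel_size) + 1L
  img <- matrix(0, ny, nx)
  sigma <- line_width / (2 * sqrt(2 * log(2)))

  # dense resample along the polyline so stamps overlap
  seg <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seg))
  sd_grid <- seq(0, s[length(s)], by = pixel_size / 2)
  px <- approx(s, xy[, 1], xout = sd_grid)$y
  py <- approx(s, xy[, 2], xout = sd_grid)$y

  r <- max(1L, ceiling(3 * sigma / pixel_size))
  for (k in seq_along(px)) {
    jc <- 1 + (px[k] - x0) / pixel_size
    ic <- 1 + (py[k] - y0) / pixel_size
    jj <- max(1L, floor(jc) - r):min(nx, ceiling(jc) + r)
    ii <- max(1L, floor(ic) - r):min(ny, ceiling(ic) + r)
    d2 <- outer((ii - ic)^2, (jj - jc)^2, "+") * pixel_size^2
    img[ii, jj] <- pmax(img[ii, jj], exp(-d2 / (2 * sigma^2)))
  }
  attr(img, "pixel_size_nm") <- pixel_size
  attr(img, "x0_nm") <- x0
  attr(img, "y0_nm") <- y0
  class(img) <- c("sperm_image", class(img))
  img
}

#' Rasterize a generated specimen
#'
#' Renders one specimen's centerline (and optionally the head, as a filled
#' ellipse) into a grayscale image. The head is off by default so the
#' resulting image is a clean tracer fixture; enable it for display.
#'
#' @param specimen a one-row `sperm_population` tibble, or any list with a
#'   `centerline` element.
#' @param pixel_size pixel size, nm; must be smaller than the flagellum.
#' @param line_width FWHM of the flagellar line profile, nm.
#' @param draw_head render the head as a filled ellipse?
#' @param margin_nm margin around the specimen.
#' @return grayscale image matrix as in [rasterize_centerline()].
#' @export
rasterize_specimen <- function(specimen, pixel_size = 100, line_width = 300,
                               draw_head = FALSE, margin_nm = 2000) {
  cl <- specimen$centerline
  if (is.list(cl) && !is.data.frame(cl)) cl <- cl[[1]]
  if (is.null(cl)) abort("specimen carries no centerline")
  total_len <- max(cl$s_nm)
  if (pixel_size >= total_len) {
    abort("`pixel_size` is larger than the flagellum length")
  }
  xy <- cbind(cl$x_nm, cl$y_nm)
  if (draw_head) {
    # extend the bounding box to the head before rasterizing
    xy_all <- rbind(xy, neck_template$head_tip, c(-300, 2600), c(-300, -2600))
    img <- rasterize_centerline(xy_all, pixel_size, line_width, margin_nm)
    # overwrite: re-stamp only the centerline, then fill the head ellipse
    img2 <- rasterize_centerline(xy, pixel_size, line_width, margin_nm)
    # align img2 into img (same pixel size; offsets may differ)
    img[] <- 0
    ox <- round((attr(img2, "x0_nm") - attr(img, "x0_nm")) / pixel_size)
    oy <- round((attr(img2, "y0_nm") - attr(img, "y0_nm")) / pixel_size)
    img[oy + seq_len(nrow(img2)), ox + seq_len(ncol(img2))] <- img2
    cx <- (neck_template$head_tip[1] + neck_template$head_base[1]) / 2
    ax <- abs(neck_template$head_tip[1] - neck_template$head_base[1]) / 2
    by <- 2500
    xs <- attr(img, "x0_nm") + (seq_len(ncol(img)) - 1) * pixel_size
    ys <- attr(img, "y0_nm") + (seq_len(nrow(img)) - 1) * pixel_size
    inside <- outer((ys / by)^2, ((xs - cx) / ax)^2, "+") <= 1
    img[inside] <- 1
    return(img)
  }
  rasterize_centerline(xy, pixel_size, line_width, margin_nm)
}

#' Write a grayscale image as 16-bit TIFF
#'
#' @param img image matrix in `[0, 1]`.
#' @param path output file path.
#' @export
write_image_tiff <- function(img, path) {
  m <- unclass(img)
  attributes(m) <- list(dim = dim(m))
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a grayscale image (TIFF or PNG)
#'
#' Multi-channel images are averaged to one channel.
#'
#' @param path image file path.
#' @param pixel_size_nm optional pixel size to attach to the result.
#' @return numeric image matrix in `[0, 1]`.
#' @export
read_image <- function(path, pixel_size_nm = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    abort(paste0("unsupported image format: ", ext))
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  if (!is.null(pixel_size_nm)) attr(img, "pixel_size_nm") <- pixel_size_nm
  img
}
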