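# Readers and writers for the on-disk formats. All coordinates on disk are
# in nm (never pixels); CSV dialect is comma-separated, UTF-8, '.' decimal,
# header mandatory. Every writer's output is re-readable by the matching
# reader (round-trip tested).

#' Flatten a landmark list to a long table
#'
#' @param landmarks named list of point matrices.
#' @param specimen_id id to attach.
#' @return tibble: `specimen_id`, `landmark`, `point`, `x_nm`, `y_nm`.
#' @export
landmarks_to_table <- function(landmarks, specimen_id = "sp0001") {
  purrr::imap(landmarks, function(m, nm) {
    tibble(specimen_id = specimen_id, landmark = nm,
           point = seq_len(nrow(m)), x_nm = m[, 1], y_nm = m[, 2])
  }) |>
    dplyr::bind_rows()
}

#' Rebuild landmark lists from a long table
#'
#' @param tbl long landmark table (see [landmarks_to_table()]).
#' @return tibble with `specimen_id` and a `landmarks` list-column.
#' @export
table_to_landmarks <- function(tbl) {
  dup <- tbl |>
    dplyr::count(.data$specimen_id, .data$landmark, .data$point) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate landmark for specimen ", dup$specimen_id[1],
                 ": ", dup$landmark[1]))
  }
  tbl |>
    dplyr::group_by(.data$specimen_id) |>
    dplyr::group_map(function(g, key) {
      lms <- split(g, g$landmark)
      lm <- lapply(lms, function(x) {
        x <- x[order(x$point), ]
        m <- cbind(x_nm = x$x_nm, y_nm = x$y_nm)
        m
      })
      tibble(specimen_id = key$specimen_id, landmarks = list(lm))
    }) |>
    dplyr::bind_rows()
}

#' Write / read landmark tables
#'
#' @param pop a `sperm_population` (or any tibble with `specimen_id` and a
#'   `landmarks` list-column).
#' @param path CSV path.
#' @return `write_landmarks` the path, invisibly; `read_landmarks` a
#'   tibble with `specimen_id` + `landmarks` list-column.
#' @export
write_landmarks <- function(pop, path) {
  tbl <- purrr::map2(pop$landmarks, pop$specimen_id, landmarks_to_table) |>
    dplyr::bind_rows() |>
    dplyr::select("specimen_id", "landmark", "point", "x_nm", "y_nm")
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("specimen_id", "landmark", "point", "x_nm", "y_nm")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) abort(paste0("landmark file lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  table_to_landmarks(tbl)
}

#' Write / read localization tables
#'
#' The on-disk dialect mirrors common single-molecule localization
#' exports: columns `id`, `side`, `frame`, `x_nm`, `y_nm`, `z_nm`,
#' `intensity`. Only `x_nm` and `y_nm` are mandatory on read; unknown
#' columns are preserved.
#'
#' @param pop a `sperm_population` with a `clouds` list-column, or a tidy
#'   localization tibble with an `id` column.
#' @param path CSV path.
#' @export
write_localizations <- function(pop, path) {
  tbl <- if (!is.null(pop[["clouds"]])) {
    purrr::map2(pop$clouds, pop$specimen_id, function(cl, id) {
      if (is.null(cl)) return(NULL)
      dplyr::mutate(cl, id = id, frame = dplyr::row_number(), .before = 1)
    }) |> dplyr::bind_rows()
  } else pop
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  for (col in c("x_nm", "y_nm")) {
    if (!col %in% names(tbl)) {
      abort(paste0("localization file lacks mandatory column `", col, "`"))
    }
    if (!is.numeric(tbl[[col]])) {
      abort(paste0("non-numeric coordinates in column `", col, "`"))
    }
  }
  tbl
}

#' Write / read waveform tables
#'
#' One row per centerline sample: `specimen_id`, `s_nm`, `x_nm`, `y_nm`.
#'
#' @param pop a `sperm_population` (or tibble with `specimen_id` +
#'   `centerline` list-column).
#' @param path CSV path.
#' @export
write_waveforms <- function(pop, path) {
  tbl <- purrr::map2(pop$centerline, pop$specimen_id, function(wf, id) {
    dplyr::mutate(wf, specimen_id = id, .before = 1)
  }) |> dplyr::bind_rows()
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_waveforms
#' @export
read_waveforms <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("specimen_id", "s_nm", "x_nm", "y_nm")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) abort(paste0("waveform file lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  tbl |>
    dplyr::group_by(.data$specimen_id) |>
    tidyr::nest(centerline = c("s_nm", "x_nm", "y_nm")) |>
    dplyr::ungroup()
}

#' Write a specimen summary table
#'
#' One row per specimen: id, true class, latent phase and the noise-free
#' truth metrics.
#'
#' @param pop a `sperm_population`.
#' @param path CSV path.
#' @export
write_specimens <- function(pop, path) {
  tbl <- pop |>
    dplyr::select(-dplyr::any_of(c("centerline", "landmarks", "clouds"))) |>
    as_tibble()
  readr::write_csv(tbl, path)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the dimensional defaults of a pipeline run. All fields are
#' validated; `load(save(c))` is the identity.
#'
#' @param pixel_size raster pixel size, nm.
#' @param a flagellar diameter used for interfilament sliding, nm.
#' @param ds arclength resampling step, nm.
#' @param T1,T2 COSA deflection thresholds (fractions of flagellum length).
#' @param K COSA kink-subtype threshold, degrees.
#' @param bin_nm histogram bin for intensity-profile extents, nm.
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(pixel_size = 100, a = 600, ds = 100,
                       T1 = 0.03, T2 = 0.12, K = 30, bin_nm = 20, seed = 1L) {
  for (nm in c("pixel_size", "a", "ds", "T1", "T2", "K", "bin_nm")) {
    stopifnot_scalar_pos(get(nm), nm)
  }
  structure(list(pixel_size = pixel_size, a = a, ds = ds, T1 = T1, T2 = T2,
                 K = K, bin_nm = bin_nm, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}
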