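#' Run the full analysis pipeline on a synthetic population
#'
#' Executes the stages in order — simulate, (optionally rasterize + trace),
#' orient + classify, tail variables, neck metrics, statistics — and, when
#' `out_dir` is given, writes every intermediate table as CSV plus a JSON
#' summary carrying the seed and a hash of the configuration. Identical
#' parameters and seed give bit-identical results.
#'
#' Tracing from rasterized images is off by default: the generator's exact
#' centerlines are used, which keeps the run fast and separates waveform
#' noise from landmark noise. With `trace_images = TRUE` each specimen is
#' rasterized and re-traced before analysis.
#'
#' @param params a [synth_params()] object (the simulated study design).
#' @param config a [run_config()] with the analysis constants.
#' @param out_dir optional output directory (created if missing).
#' @param trace_images re-trace centerlines from rasterized images?
#' @param efa run the exploratory factor analysis on the metric table?
#' @param quiet suppress per-stage messages?
#' @return (invisibly) a list: `population`, `classes`, `tail_vars`,
#'   `neck`, `metrics` (joined per-specimen table), `correlations`,
#'   `efa`, `log`, `paths`.
#' @export
run_pipeline <- function(params = synth_params(), config = run_config(),
                         out_dir = NULL, trace_images = FALSE, efa = TRUE,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) inform(sprintf(...))
  logs <- list()
  stage <- function(name, n, status = "ok") {
    logs[[length(logs) + 1L]] <<- tibble(stage = name, n = n, status = status)
  }

  say("simulate: n = %d, seed = %d", params$n_specimens, params$seed)
  pop <- make_population(params, ds = config$ds)
  stage("simulate", nrow(pop))

  if (trace_images) {
    for (i in seq_len(nrow(pop))) {
      img <- rasterize_specimen(pop[i, ], pixel_size = config$pixel_size)
      tr <- tryCatch(
        trace_centerline(img, seed_point = c(0, 0)),
        error = function(e) {
          abort(paste0("stage trace failed for specimen ",
                       pop$specimen_id[i], ": ", conditionMessage(e)))
        }
      )
      wf <- resample_polyline(tr, ds = config$ds)
      # re-anchor: the traced curve starts near the neck, not exactly at it
      wf$x_nm <- wf$x_nm - wf$x_nm[1]
      wf$y_nm <- wf$y_nm - wf$y_nm[1]
      pop$centerline[[i]] <- wf
    }
    stage("trace", nrow(pop))
    say("trace: %d centerlines re-traced from images", nrow(pop))
  }

  classes <- classify_population(pop, T1 = config$T1, T2 = config$T2,
                                 K = config$K)
  stage("classify", nrow(classes))
  say("classify: %d sharp-right warnings", sum(classes$sharp_right_flag))

  tv <- tail_variables(pop, a = config$a)
  stage("variables", nrow(tv))

  neck <- measure_neck(pop, bin_nm = config$bin_nm)
  stage("neck", nrow(neck))

  metrics <- classes |>
    dplyr::left_join(tv, by = "specimen_id") |>
    dplyr::left_join(neck, by = "specimen_id")

  corr_pairs <- list(
    c("d_rod_rostral", "y_bar_nm"),
    c("d_rod_rostral", "delta_bar_nm"),
    c("d_rod_rostral", "kappa_bar_rad_per_um"),
    c("pc_dc_angle_deg", "y_bar_nm"),
    c("head_neck_angle_deg", "y_bar_nm")
  )
  correlations <- purrr::map(corr_pairs, function(pr) {
    rep <- pearson_regression(metrics[[pr[1]]], metrics[[pr[2]]])
    tibble(var_y = pr[1], var_x = pr[2], r = rep$r, r2 = rep$r2,
           slope = rep$slope, intercept = rep$intercept,
           n = rep$n, p_two_tailed = rep$p_two_tailed)
  }) |> dplyr::bind_rows()
  stage("stats", nrow(correlations))

  efa_res <- NULL
  if (efa) {
    efa_vars <- metrics |>
      dplyr::select(dplyr::any_of(c(
        "y_bar_nm", "delta_bar_nm", "kappa_bar_rad_per_um",
        "d_rod_rostral", "d_rod_caudal", "d_mt_rostral",
        "pc_dc_angle_deg", "pc_lateral_shift_nm", "head_neck_angle_deg",
        "sc_d_mean_nm")))
    efa_res <- withCallingHandlers(
      run_efa(efa_vars),
      warning = function(w) invokeRestart("muffleWarning")
    )
    stage("efa", efa_res$n_factors)
  }

  log_tbl <- dplyr::bind_rows(logs)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(out_dir, f)
    write_specimens(pop, fp("specimens.csv"))
    write_landmarks(pop, fp("landmarks.csv"))
    write_localizations(pop, fp("localizations.csv"))
    write_waveforms(pop, fp("waveforms.csv"))
    readr::write_csv(classes, fp("classes.csv"))
    readr::write_csv(tv, fp("tail_variables.csv"))
    readr::write_csv(neck, fp("neck_metrics.csv"))
    readr::write_csv(correlations, fp("correlation_report.csv"))
    readr::write_csv(log_tbl, fp("run_log.csv"))
    summary <- list(
      seed = params$seed,
      n_specimens = params$n_specimens,
      config_hash = rlang::hash(list(unclass(params), unclass(config))),
      class_distribution = as.list(stats::setNames(
        population_distribution(classes)$fraction, beat_classes)),
      sharp_right_warnings = sum(classes$sharp_right_flag)
    )
    if (!is.null(efa_res)) {
      readr::write_csv(tidy(efa_res), fp("efa_loadings.csv"))
      summary$efa <- list(
        n_factors = efa_res$n_factors,
        kmo = efa_res$kmo_overall,
        bartlett_chi2 = efa_res$bartlett_chi2,
        bartlett_p = efa_res$bartlett_p
      )
    }
    jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                         digits = NA)
    paths <- list(dir = out_dir)
  }

  invisible(list(population = pop, classes = classes, tail_vars = tv,
                 neck = neck, metrics = metrics,
                 correlations = correlations, efa = efa_res,
                 log = log_tbl, paths = paths))
}
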