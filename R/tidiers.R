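# broom-style tidiers for the fitted/report objects.

#' @exportS3Method generics::tidy
tidy.correlation_report <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @exportS3Method generics::glance
glance.correlation_report <- function(x, ...) {
  tibble(r = x$r, r.squared = x$r2, statistic = x$t, df = x$df,
         p.value = x$p_two_tailed, nobs = x$n)
}

#' @exportS3Method generics::tidy
tidy.ttest2_report <- function(x, ...) {
  tibble(estimate = x$mean_x - x$mean_y, statistic = x$t, df = x$df,
         p.value = x$p_two_tailed,
         method = if (x$welch) "welch" else "student")
}

#' @exportS3Method generics::glance
glance.ttest2_report <- tidy.ttest2_report

#' Tidy the loadings of an EFA
#'
#' One row per variable-factor pair with the unrotated and rotated
#' loadings and the significance flag (`|loading| >` cutoff).
#'
#' @param x an `efa_result`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.efa_result <- function(x, ...) {
  p <- nrow(x$loadings_rotated)
  k <- ncol(x$loadings_rotated)
  tibble(
    variable = rep(rownames(x$loadings_rotated) %||% paste0("V", seq_len(p)),
                   times = k),
    factor = rep(colnames(x$loadings_rotated), each = p),
    loading = as.vector(x$loadings_rotated),
    loading_unrotated = as.vector(x$loadings_unrotated),
    significant = as.vector(x$significant_mask)
  )
}

#' One-row summary of an EFA
#'
#' @inheritParams tidy.efa_result
#' @exportS3Method generics::glance
glance.efa_result <- function(x, ...) {
  tibble(
    n = x$n,
    n_variables = ncol(x$corr_matrix),
    n_factors = x$n_factors,
    kmo = x$kmo_overall,
    bartlett_chi2 = x$bartlett_chi2,
    bartlett_df = x$bartlett_df,
    bartlett_p = x$bartlett_p,
    prop_variance = sum(x$eigenvalues[seq_len(x$n_factors)]) /
      length(x$eigenvalues)
  )
}
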