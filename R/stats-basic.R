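# First-principles implementations of the statistical layer. Base-R
# distribution tails (pt, pchisq) supply p-values; test files cross-check
# every statistic against independent routes.

#' Pearson correlation with least-squares regression
#'
#' Product-moment correlation `r`, coefficient of determination `r^2`,
#' least-squares slope and intercept, and the two-tailed p-value from the
#' t distribution with n - 2 degrees of freedom.
#'
#' Called either with two numeric vectors, or data-frame-first with two
#' column names, so it composes with the pipe:
#' `metrics |> pearson_regression(y_bar_nm, d_rod_rostral)`.
#'
#' @param x numeric vector, or a data frame.
#' @param y numeric vector, or (data-frame form) the x column.
#' @param ... (data-frame form) the y column.
#' @return object of class `correlation_report`.
#' @examples
#' pearson_regression(1:10, 2 * (1:10) + 1)$slope
#' @export
pearson_regression <- function(x, y, ...) {
  if (is.data.frame(x)) {
    vars <- c(rlang::as_name(rlang::enquo(y)),
              vapply(rlang::enquos(...), rlang::as_name, character(1)))
    if (length(vars) != 2L) abort("supply exactly two columns")
    df <- x
    x <- df[[vars[1]]]
    y <- df[[vars[2]]]
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L || length(y) != n) abort("need equal-length vectors with n >= 3")
  if (var(x) == 0 || var(y) == 0) abort("constant input vector")
  mx <- mean(x); my <- mean(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  slope <- sxy / sxx
  intercept <- my - slope * mx
  tstat <- if (abs(r) >= 1) Inf else r * sqrt((n - 2) / (1 - r^2))
  p <- if (is.infinite(tstat)) 0 else 2 * pt(-abs(tstat), df = n - 2)
  structure(list(r = r, r2 = r^2, slope = slope, intercept = intercept,
                 n = n, t = tstat, df = n - 2L, p_two_tailed = p),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Pearson R = %.4f (R2 = %.4f), slope = %.4g, intercept = %.4g\n",
              x$r, x$r2, x$slope, x$intercept))
  cat(sprintf("n = %d, t(%d) = %.3f, two-tailed p = %.3g %s\n",
              x$n, x$df, x$t, x$p_two_tailed, p_stars(x$p_two_tailed)))
  invisible(x)
}

# star conventions used in the figures this mirrors
p_stars <- function(p) {
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Unpaired two-tailed t test
#'
#' Pooled-variance Student t by default; Welch's unequal-variance form via
#' `welch = TRUE`.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @param welch use the Welch approximation?
#' @return object of class `ttest2_report`: `t`, `df`, `p_two_tailed`,
#'   group means.
#' @export
ttest2 <- function(x, y, welch = FALSE) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) abort("each group needs at least 2 observations")
  mx <- mean(x); my <- mean(y)
  vx <- var(x); vy <- var(y)
  if (welch) {
    se2 <- vx / nx + vy / ny
    tstat <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    tstat <- (mx - my) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  p <- 2 * pt(-abs(tstat), df = df)
  structure(list(t = tstat, df = df, p_two_tailed = p,
                 mean_x = mx, mean_y = my, welch = welch),
            class = "ttest2_report")
}

#' @export
print.ttest2_report <- function(x, ...) {
  cat(sprintf("%s t = %.4f, df = %.2f, two-tailed p = %.3g %s\n",
              if (x$welch) "Welch" else "Student", x$t, x$df,
              x$p_two_tailed, p_stars(x$p_two_tailed)))
  invisible(x)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix differs from the identity:
#' `chi2 = -(n - 1 - (2 p + 5)/6) * ln det(R)` with `p (p - 1)/2` degrees
#' of freedom. A singular matrix (det <= 0) is reported as `chi2 = Inf`
#' with `singular = TRUE`, never silently.
#'
#' @param corr p x p correlation matrix.
#' @param n number of observations behind the matrix (n > p).
#' @return list: `chi2`, `df`, `p`, `singular`.
#' @export
bartlett_sphericity <- function(corr, n) {
  p <- ncol(corr)
  if (!isTRUE(all.equal(as.numeric(diag(corr)), rep(1, p), tolerance = 1e-8))) {
    abort("`corr` must have unit diagonal")
  }
  if (n <= p) abort("`n` must exceed the number of variables")
  dt <- det(corr)
  df <- p * (p - 1) / 2
  if (dt <= 0) {
    warn("singular correlation matrix in Bartlett's test")
    return(list(chi2 = Inf, df = df, p = 0, singular = TRUE))
  }
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(dt)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       singular = FALSE)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Compares correlations against partial correlations (from the inverse
#' correlation matrix): `KMO = sum r^2 / (sum r^2 + sum q^2)` over
#' off-diagonal entries, overall and per variable. Values above 0.5
#' indicate sampling adequacy. For p = 2 the partial correlation equals
#' the simple correlation, so the overall KMO is exactly 0.5.
#'
#' @param corr invertible p x p correlation matrix.
#' @return list: `overall`, `per_variable` (named when `corr` has
#'   dimnames).
#' @export
kmo <- function(corr) {
  p <- ncol(corr)
  inv <- tryCatch(solve(corr), error = function(e) {
    abort("correlation matrix is not invertible")
  })
  d <- 1 / sqrt(diag(inv))
  q <- -inv * outer(d, d)        # partial correlations
  off <- !diag(p)
  r2 <- corr^2 * off
  q2 <- q^2 * off
  denom <- sum(r2) + sum(q2)
  if (denom < .Machine$double.eps) {
    abort("KMO is undefined: all off-diagonal correlations and partials are zero")
  }
  per <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(per) <- colnames(corr)
  list(overall = sum(r2) / denom, per_variable = per)
}
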