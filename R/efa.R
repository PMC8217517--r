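# Exploratory factor analysis: principal-component extraction, varimax
# rotation with Kaiser normalization, eigenvalue-rule factor count, and the
# |loading| > 0.40 significance mask.

#' Eigen extraction of factor loadings
#'
#' Principal-component extraction: eigendecomposition of the correlation
#' matrix; loading column j is `eigvec_j * sqrt(eigval_j)` for the top
#' `n_factors` components. Eigenvalues are returned in descending order
#' (the scree vector). Column signs are fixed so each column's largest
#' loading is positive.
#'
#' @param corr p x p correlation matrix.
#' @param n_factors number of factors, between 1 and p.
#' @return list: `eigenvalues` (length p), `loadings` (p x n_factors).
#' @export
extract_factors <- function(corr, n_factors) {
  p <- ncol(corr)
  if (n_factors < 1 || n_factors > p) abort("`n_factors` out of range")
  ei <- eigen(corr, symmetric = TRUE)
  load <- ei$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(pmax(ei$values[seq_len(n_factors)], 0)), n_factors)
  for (j in seq_len(n_factors)) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(corr)
  colnames(load) <- paste0("F", seq_len(n_factors))
  list(eigenvalues = ei$values, loadings = load)
}

#' Varimax criterion
#'
#' The quantity varimax maximizes: the summed per-factor variance of
#' squared loadings.
#'
#' @param loadings p x k loading matrix.
#' @return scalar criterion value.
#' @export
varimax_criterion <- function(loadings) {
  p <- nrow(loadings)
  L2 <- loadings^2
  sum(colSums(L2^2) / p - (colSums(L2) / p)^2)
}

#' Varimax rotation
#'
#' Orthogonal rotation maximizing [varimax_criterion()] by iterated
#' pairwise planar rotations (Kaiser's closed-form angle per pair), with
#' Kaiser row-normalization applied before and undone after rotation
#' (switchable). Iteration stops when a full sweep improves the criterion
#' by less than `tol`. The criterion never decreases and communalities
#' (row sums of squared loadings) are invariant under the rotation.
#'
#' @param loadings p x k loading matrix; k = 1 is returned unchanged.
#' @param normalize apply Kaiser row normalization?
#' @param max_iter maximum number of sweeps.
#' @param tol convergence tolerance on the (normalized) criterion gain.
#' @return list: `loadings` (rotated), `rotmat` (k x k orthogonal),
#'   `iterations`, `criterion`.
#' @export
varimax_rotate <- function(loadings, normalize = TRUE, max_iter = 1000,
                           tol = 1e-10) {
  if (any(!is.finite(loadings))) abort("non-finite loadings")
  L <- as.matrix(loadings)
  k <- ncol(L)
  if (k < 2L) {
    return(list(loadings = L, rotmat = diag(k), iterations = 0L,
                criterion = varimax_criterion(L)))
  }
  h <- sqrt(rowSums(L^2))
  h[h < .Machine$double.eps] <- 1
  Ln <- if (normalize) L / h else L
  p <- nrow(Ln)
  R <- diag(k)
  crit <- varimax_criterion(Ln)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        x <- Ln[, i]; y <- Ln[, j]
        u <- x^2 - y^2
        v <- 2 * x * y
        A <- sum(u); B <- sum(v)
        C <- sum(u^2 - v^2); D <- 2 * sum(u * v)
        num <- D - 2 * A * B / p
        den <- C - (A^2 - B^2) / p
        phi <- atan2(num, den) / 4
        if (abs(phi) > 1e-12) {
          G <- rot2(phi)
          Ln[, c(i, j)] <- Ln[, c(i, j)] %*% G
          R[, c(i, j)] <- R[, c(i, j)] %*% G
        }
      }
    }
    new_crit <- varimax_criterion(Ln)
    if (new_crit - crit < tol || iter >= max_iter) break
    crit <- new_crit
  }
  Lr <- if (normalize) Ln * h else Ln
  list(loadings = Lr, rotmat = R, iterations = iter,
       criterion = varimax_criterion(Ln))
}

#' Run an exploratory factor analysis
#'
#' Full pipeline on an n x p data table: correlation matrix, KMO (warns
#' below 0.5), Bartlett's sphericity (warns when p >= 0.05), eigen
#' extraction with the eigenvalue-greater-than-1 rule when
#' `n_factors = "auto"` (the scree vector is always reported so the count
#' can be overridden), varimax rotation, and the significance mask
#' `|loading| > loading_cutoff`.
#'
#' @param data numeric data frame (n rows > p columns).
#' @param n_factors `"auto"` (eigenvalue > 1) or an integer.
#' @param loading_cutoff threshold for a variable to contribute to a
#'   factor (default 0.40).
#' @param normalize Kaiser row normalization for the rotation.
#' @return object of class `efa_result`: correlation matrix, KMO, Bartlett
#'   statistics, eigenvalues, unrotated and rotated loadings, rotation
#'   matrix, significance mask, factor count.
#' @examples
#' set.seed(1)
#' f <- rnorm(200)
#' d <- data.frame(a = f + rnorm(200, 0, .5), b = f + rnorm(200, 0, .5),
#'                 c = rnorm(200), d = rnorm(200))
#' res <- run_efa(d)
#' res$n_factors
#' @export
run_efa <- function(data, n_factors = "auto", loading_cutoff = 0.40,
                    normalize = TRUE) {
  X <- as.data.frame(data)
  num <- vapply(X, is.numeric, logical(1))
  X <- X[num]
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) abort("need more observations than variables (n > p)")
  corr <- stats::cor(as.matrix(X))

  km <- tryCatch(kmo(corr), error = function(e) list(overall = NA_real_,
                                                     per_variable = NULL))
  if (is.finite(km$overall) && km$overall < 0.5) {
    warn(sprintf("KMO = %.3f < 0.5: sampling adequacy is questionable",
                 km$overall))
  }
  ba <- bartlett_sphericity(corr, n)
  if (ba$p >= 0.05) {
    warn(sprintf("Bartlett's sphericity p = %.3g >= 0.05: variables may be uncorrelated",
                 ba$p))
  }

  ei_all <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  k <- if (identical(n_factors, "auto")) max(1L, sum(ei_all > 1)) else {
    as.integer(n_factors)
  }
  ex <- extract_factors(corr, k)
  vr <- varimax_rotate(ex$loadings, normalize = normalize)
  mask <- abs(vr$loadings) > loading_cutoff

  structure(list(
    corr_matrix = corr,
    n = n,
    kmo_overall = km$overall,
    kmo_per_variable = km$per_variable,
    bartlett_chi2 = ba$chi2,
    bartlett_df = ba$df,
    bartlett_p = ba$p,
    eigenvalues = ei_all,
    n_factors = k,
    loadings_unrotated = ex$loadings,
    loadings_rotated = vr$loadings,
    rotation_matrix = vr$rotmat,
    significant_mask = mask,
    loading_cutoff = loading_cutoff
  ), class = "efa_result")
}

#' @export
print.efa_result <- function(x, ...) {
  cat(sprintf("Exploratory factor analysis: %d variables, n = %d\n",
              ncol(x$corr_matrix), x$n))
  cat(sprintf("  KMO = %.3f; Bartlett chi2(%d) = %.2f, p = %.3g\n",
              x$kmo_overall, x$bartlett_df, x$bartlett_chi2, x$bartlett_p))
  cat(sprintf("  %d factor(s) retained (eigenvalues: %s ...)\n", x$n_factors,
              paste(sprintf("%.2f", head(x$eigenvalues, 5)), collapse = ", ")))
  cat(sprintf("  variance explained by retained factors: %.1f%%\n",
              100 * sum(x$eigenvalues[seq_len(x$n_factors)]) /
                length(x$eigenvalues)))
  invisible(x)
}
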