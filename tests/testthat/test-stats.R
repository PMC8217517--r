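test_that("pearson regression recovers exact linear relations", {
  x <- 1:10
  r1 <- pearson_regression(x, 2 * x + 1)
  expect_equal(r1$r, 1)
  expect_equal(r1$slope, 2)
  expect_equal(r1$intercept, 1)
  expect_equal(r1$p_two_tailed, 0)
  expect_equal(pearson_regression(x, -x)$r, -1)
  expect_error(pearson_regression(x, rep(1, 10)), "constant")
})

test_that("pearson statistics match direct-formula and base-R oracles", {
  set.seed(4)
  x <- rnorm(6); y <- 0.7 * x + rnorm(6)
  rep <- pearson_regression(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(rep$r, r_direct, tolerance = 1e-12)
  expect_equal(rep$r2, rep$r^2, tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(rep$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(rep$p_two_tailed, ct$p.value, tolerance = 1e-12)
  lmfit <- lm(y ~ x)
  expect_equal(rep$slope, unname(coef(lmfit)[2]), tolerance = 1e-12)
  expect_equal(rep$intercept, unname(coef(lmfit)[1]), tolerance = 1e-12)
  # r invariant under positive affine rescaling; slope covariant
  rep2 <- pearson_regression(10 * x + 3, 2 * y - 5)
  expect_equal(rep2$r, rep$r, tolerance = 1e-12)
  expect_equal(rep2$slope, rep$slope * 2 / 10, tolerance = 1e-12)
  # data-frame-first form
  df <- tibble::tibble(a = x, b = y)
  expect_equal(pearson_regression(df, a, b)$r, rep$r)
})

test_that("two-sample t test matches the pooled formula and t.test", {
  same <- ttest2(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_two_tailed, 1)

  x <- c(4.1, 5.2, 6.3, 5.5, 4.9)
  y <- c(3.2, 4.4, 3.9, 4.1, 3.6)
  res <- ttest2(x, y)
  sp2 <- (4 * var(x) + 4 * var(y)) / 8
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 5))
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  bt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$t, unname(bt$statistic), tolerance = 1e-12)
  expect_equal(res$p_two_tailed, bt$p.value, tolerance = 1e-12)

  wt <- t.test(x, y)
  resw <- ttest2(x, y, welch = TRUE)
  expect_equal(resw$t, unname(wt$statistic), tolerance = 1e-12)
  expect_equal(resw$df, unname(wt$parameter), tolerance = 1e-12)
  expect_error(ttest2(1, y), "at least 2")
})

test_that("Bartlett's sphericity matches its closed form", {
  expect_equal(bartlett_sphericity(diag(4), n = 50)$chi2, 0)
  expect_equal(bartlett_sphericity(diag(4), n = 50)$p, 1)
  expect_equal(bartlett_sphericity(diag(4), n = 50)$df, 6)

  set.seed(11)
  X <- matrix(rnorm(40 * 5), 40, 5)
  X[, 2] <- X[, 1] + rnorm(40, 0, 0.6)
  R <- cor(X)
  res <- bartlett_sphericity(R, n = 40)
  chi2_direct <- -(40 - 1 - (2 * 5 + 5) / 6) * log(det(R))
  expect_equal(res$chi2, chi2_direct, tolerance = 1e-10)
  expect_equal(res$p, pchisq(chi2_direct, 10, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(bartlett_sphericity(R, n = 4), "exceed")

  sing <- matrix(1, 3, 3)
  expect_warning(out <- bartlett_sphericity(sing, n = 30), "singular")
  expect_true(is.infinite(out$chi2) && out$singular)
})

test_that("KMO equals 0.5 for two variables and matches a partials oracle", {
  R2 <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(kmo(R2)$overall, 0.5, tolerance = 1e-12)
  expect_error(kmo(diag(3)), "undefined")

  set.seed(12)
  f <- rnorm(200)
  X <- sapply(1:6, function(i) 0.7 * f + rnorm(200, 0, 0.7))
  R <- cor(X)
  res <- kmo(R)
  # oracle: partial correlations via explicit inverse, summed by formula
  P <- solve(R)
  q <- -P / sqrt(outer(diag(P), diag(P)))
  off <- row(R) != col(R)
  oracle <- sum(R[off]^2) / (sum(R[off]^2) + sum(q[off]^2))
  expect_equal(res$overall, oracle, tolerance = 1e-10)
  expect_gt(res$overall, 0.5)
  expect_length(res$per_variable, 6)
})

test_that("eigen extraction reproduces compound-symmetry structure", {
  ex <- extract_factors(diag(4), 4)
  expect_equal(ex$eigenvalues, rep(1, 4))

  R <- matrix(0.64, 4, 4); diag(R) <- 1
  ex1 <- extract_factors(R, 1)
  expect_equal(ex1$eigenvalues[1], 1 + 3 * 0.64, tolerance = 1e-12)
  expect_equal(as.vector(ex1$loadings),
               rep(sqrt(1 + 3 * 0.64) / 2, 4), tolerance = 1e-10)
  expect_equal(as.vector(ex1$loadings), rep(0.8, 4), tolerance = 0.1)

  # reconstruction error is bounded by the discarded eigenvalues
  set.seed(13)
  X <- matrix(rnorm(60 * 5), 60, 5)
  R5 <- cor(X)
  ex2 <- extract_factors(R5, 2)
  recon <- ex2$loadings %*% t(ex2$loadings)
  discarded <- ex2$eigenvalues[3:5]
  expect_lte(norm(recon - R5, "F"), sum(discarded) + 1e-10)
  expect_error(extract_factors(R5, 0), "out of range")
})

test_that("varimax improves the criterion and preserves structure", {
  # perfect simple structure is a fixed point (up to column sign/permutation)
  L <- rbind(c(0.9, 0), c(0.8, 0), c(0, 0.7), c(0, 0.85))
  vr <- varimax_rotate(L)
  perm <- apply(abs(t(vr$loadings) %*% L), 2, which.max)
  expect_equal(sort(perm), 1:2)
  aligned <- vr$loadings[, perm] %*% diag(sign(diag(t(vr$loadings[, perm]) %*% L)))
  expect_equal(aligned, L, tolerance = 1e-8)

  # k = 1 is returned unchanged
  one <- matrix(c(0.5, 0.6, 0.7), 3, 1)
  expect_identical(varimax_rotate(one)$loadings, one)

  set.seed(14)
  L8 <- matrix(rnorm(24, 0, 0.4), 8, 3)
  vr8 <- varimax_rotate(L8)
  # orthogonal rotation, communalities preserved
  expect_equal(t(vr8$rotmat) %*% vr8$rotmat, diag(3), tolerance = 1e-10)
  expect_equal(rowSums(vr8$loadings^2), rowSums(L8^2), tolerance = 1e-10)
  # criterion never decreases (on the normalized matrix it is maximized)
  h <- sqrt(rowSums(L8^2))
  expect_gte(varimax_criterion(vr8$loadings / h) + 1e-12,
             varimax_criterion(L8 / h))

  # brute-force hill-climb oracle over pairwise rotations
  hill_climb <- function(Ln) {
    best <- varimax_criterion(Ln)
    repeat {
      improved <- FALSE
      for (i in 1:2) for (j in (i + 1):3) {
        crit_at <- function(a) {
          G <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
          M <- Ln
          M[, c(i, j)] <- M[, c(i, j)] %*% G
          varimax_criterion(M)
        }
        opt <- optimize(crit_at, c(-pi / 4, pi / 4), maximum = TRUE,
                        tol = 1e-12)
        if (opt$objective > best + 1e-13) {
          a <- opt$maximum
          G <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
          Ln[, c(i, j)] <- Ln[, c(i, j)] %*% G
          best <- opt$objective
          improved <- TRUE
        }
      }
      if (!improved) return(best)
    }
  }
  Ln <- L8 / h
  expect_equal(varimax_criterion(vr8$loadings / h), hill_climb(Ln),
               tolerance = 1e-8)

  # independent cross-check against the reference rotation
  sv <- stats::varimax(L8, normalize = TRUE, eps = 1e-10)
  expect_equal(varimax_criterion(vr8$loadings / h),
               varimax_criterion(sv$loadings / h), tolerance = 1e-8)
  expect_error(varimax_rotate(matrix(c(1, NA), 1, 2)), "non-finite")
})

test_that("a planted three-factor model is recovered end to end", {
  set.seed(15)
  n <- 500; p <- 21; k <- 3
  group <- rep(1:3, each = 7)
  F <- matrix(rnorm(n * k), n, k)
  load_true <- matrix(0, p, k)
  load_true[cbind(1:p, group)] <- 0.7
  X <- F %*% t(load_true) +
    matrix(rnorm(n * p, 0, sqrt(1 - 0.49)), n, p)
  res <- run_efa(as.data.frame(X))
  expect_equal(res$n_factors, 3L)
  expect_equal(res$bartlett_df, p * (p - 1) / 2)
  expect_gt(res$kmo_overall, 0.5)
  expect_lt(res$bartlett_p, 1e-10)
  # masked structure equals the planted grouping up to permutation/sign
  mask <- res$significant_mask
  expect_true(all(rowSums(mask) == 1))
  assigned <- apply(mask, 1, which.max)
  expect_equal(length(unique(assigned[group == 1])), 1L)
  expect_equal(length(unique(assigned[group == 2])), 1L)
  expect_equal(length(unique(assigned[group == 3])), 1L)
  expect_equal(length(unique(c(assigned[group == 1][1],
                               assigned[group == 2][1],
                               assigned[group == 3][1]))), 3L)
  # rotation invariants from the result object
  expect_equal(t(res$rotation_matrix) %*% res$rotation_matrix, diag(3),
               tolerance = 1e-10)
  expect_equal(rowSums(res$loadings_rotated^2),
               rowSums(res$loadings_unrotated^2), tolerance = 1e-10)
})

test_that("degenerate EFA inputs warn or fail as specified", {
  set.seed(16)
  noise <- as.data.frame(matrix(rnorm(30 * 4), 30, 4))
  w <- capture_warnings(run_efa(noise))
  expect_true(any(grepl("Bartlett", w)))
  expect_error(run_efa(noise[1:3, ]), "n > p")
})

test_that("tidiers return well-formed tables", {
  set.seed(17)
  x <- rnorm(20); y <- x + rnorm(20, 0, 0.5)
  rep <- pearson_regression(x, y)
  td <- generics::tidy(rep)
  expect_equal(td$term, c("intercept", "slope"))
  gl <- generics::glance(rep)
  expect_equal(gl$r.squared, rep$r2)

  f <- rnorm(100)
  d <- data.frame(a = f + rnorm(100, 0, 0.4), b = f + rnorm(100, 0, 0.4),
                  c = f + rnorm(100, 0, 0.4), e = rnorm(100),
                  g = rnorm(100))
  res <- suppressWarnings(run_efa(d))
  tl <- generics::tidy(res)
  expect_true(all(c("variable", "factor", "loading", "significant") %in%
                    names(tl)))
  expect_equal(nrow(tl), 5 * res$n_factors)
  expect_equal(generics::glance(res)$n_factors, res$n_factors)
})
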