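# Univariate spatial mixed model: design pieces, REML likelihood,
# model-comparison tests, heritability.

test_that("orthogonal polynomial basis is orthonormal and spans x, x^2", {
  x <- 1:20
  B <- orthogonal_polynomial_basis(x, 2)
  expect_equal(crossprod(B), diag(2), tolerance = 1e-10)
  # first column spans the centered linear trend
  xc <- x - mean(x)
  expect_lt(abs(abs(cor(B[, 1], xc)) - 1), 1e-12)
  # basis + intercept spans x^2: projection residual vanishes
  r <- residuals(lm(I(xc^2) ~ B))
  expect_lt(sqrt(sum(r^2)), 1e-10)
  expect_error(orthogonal_polynomial_basis(rep(2, 10), 2), "distinct")
})

test_that("AR1 correlation matrices are exact and positive definite", {
  expect_equal(ar1_correlation(0, 1:4), diag(4))
  M <- ar1_correlation(0.5, c(1, 2, 3))
  expect_equal(M, matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3),
               tolerance = 1e-15)
  ev <- eigen(ar1_correlation(0.95, 1:50), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_error(ar1_correlation(1, 1:3), "rho")
})

test_that("residual covariance equals the Kronecker construction", {
  lay <- expand.grid(row = 1:3, col = 1:3)
  lay$tree_id <- sprintf("t%d", 1:9)
  lay$clone_id <- "c1"
  R <- residual_covariance(lay, sigma2 = 2, rho_row = 0.6, rho_col = -0.3,
                           structure = "ar1xar1")
  # explicit Kronecker: ordering of expand.grid is row fastest, so the
  # position index is (col-1)*3 + row = kronecker(AR1(col), AR1(row))
  K <- 2 * kronecker(ar1_correlation(-0.3, 1:3), ar1_correlation(0.6, 1:3))
  expect_equal(R, K, tolerance = 1e-12)
  # deleting one tree = deleting the matching row/column
  R8 <- residual_covariance(lay[-4, ], 2, 0.6, -0.3, "ar1xar1")
  expect_equal(R8, K[-4, -4], tolerance = 1e-12)
  expect_equal(residual_covariance(lay, 3, structure = "iid"), 3 * diag(9))
})

test_that("REML log-likelihood equals the dense restricted density", {
  lay <- simulate_layout(4, 5, 6, 3, seed = 31)
  y <- sim_response(lay, 0.5, 0.8, 0.4, 0.2, seed = 32)
  for (struct in c("ar1xar1", "iid")) {
    fit <- reml_fit(y, lay, structure = struct, compute_vcov = FALSE)
    expect_equal(fit$loglik,
                 oracle_restricted_ll(fit$y, fit$X,
                                      oracle_V_univariate(fit)),
                 tolerance = 1e-6)
  }
})

test_that("null clone variance is recovered near the boundary", {
  # Under sigma2_c = 0 the REML estimate is truncated at the boundary, so its
  # mean equals the positive-part bias of the sampling distribution. The
  # independent oracle is the boundary-truncated ANOVA (method-of-moments)
  # estimator max(0, (MSB - MSW)/r) on the same replicates: REML should be at
  # the boundary at least as often and no more biased.
  lay <- simulate_layout(10, 10, 30, 3, seed = 41)
  cl <- factor(lay$clone_id)
  est <- numeric(500); est_aov <- numeric(500)
  for (r in 1:500) {
    y <- sim_response(lay, 0, 1, 0, 0, seed = 10000 + 2 * r)
    fit <- reml_fit(y, lay, structure = "iid", compute_vcov = FALSE)
    est[r] <- fit$sigma2_c
    ms <- summary(stats::aov(y ~ cl))[[1]]$`Mean Sq`
    est_aov[r] <- max(0, (ms[1] - ms[2]) / 3)
  }
  mc_se <- sd(est_aov) / sqrt(500)
  expect_lte(mean(est), mean(est_aov) + 3 * mc_se)
  expect_gte(mean(est == 0), 0.4)  # boundary hit about half the time
})

test_that("the fit is invariant to lag-preserving relabeling", {
  lay <- simulate_layout(5, 6, 6, 4, seed = 51)
  y <- sim_response(lay, 0.4, 0.6, 0.5, 0.5, seed = 52)
  lay2 <- lay
  lay2$row <- lay$row + 7
  lay2$col <- lay$col + 3
  f1 <- reml_fit(y, lay, compute_vcov = FALSE)
  f2 <- reml_fit(y, lay2, compute_vcov = FALSE)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$sigma2_c, f2$sigma2_c, tolerance = 1e-8)
  expect_equal(c(f1$rho_row, f1$rho_col), c(f2$rho_row, f2$rho_col),
               tolerance = 1e-8)
})

test_that("missing responses are dropped listwise, lags preserved", {
  lay <- simulate_layout(5, 6, 6, 4, seed = 61)
  y <- sim_response(lay, 0.4, 0.6, 0.3, 0.3, seed = 62)
  y[c(2, 11)] <- NA
  fit <- reml_fit(y, lay, compute_vcov = FALSE)
  expect_equal(fit$n, 22)
  ydrop <- y[-c(2, 11)]
  fit2 <- reml_fit(ydrop, lay[-c(2, 11), ], compute_vcov = FALSE)
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-10)
})

test_that("likelihood-ratio test handles identity, nesting and boundaries", {
  lay <- simulate_layout(6, 6, 8, 4, seed = 71)
  y <- sim_response(lay, 0.5, 0.7, 0.3, 0.3, seed = 72)
  full <- reml_fit(y, lay, structure = "ar1xar1", compute_vcov = FALSE)
  # identical fits: statistic 0, p 1 under both references
  same <- likelihood_ratio_test(full, full, boundary = "none")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # clone variance on the boundary: mixture reference auto-detected
  red_clone <- reml_fit(y, lay, structure = "ar1xar1",
                        include_clone = FALSE, compute_vcov = FALSE)
  lrt <- likelihood_ratio_test(full, red_clone)
  expect_identical(lrt$boundary, "variance")
  expect_equal(lrt$df, 1)
  if (lrt$statistic > 0) {
    expect_equal(lrt$p_value,
                 0.5 * pchisq(lrt$statistic, 1, lower.tail = FALSE))
  }
  # rho parameters: interior null, plain chi-square with df 2
  red_iid <- reml_fit(y, lay, structure = "iid", compute_vcov = FALSE)
  lrt2 <- likelihood_ratio_test(full, red_iid)
  expect_identical(lrt2$boundary, "none")
  expect_equal(lrt2$df, 2)
  # differing fixed parts are not comparable
  nopoly <- reml_fit(y, lay, poly_row = FALSE, compute_vcov = FALSE)
  expect_error(likelihood_ratio_test(full, nopoly), "fixed parts")
})

test_that("Wald F on a single coefficient equals (estimate/SE)^2", {
  lay <- simulate_layout(6, 6, 8, 4, seed = 81)
  y <- sim_response(lay, 0.3, 0.7, 0, 0, seed = 82)
  fit <- reml_fit(y, lay, structure = "iid", degree = 1L,
                  poly_col = FALSE, compute_vcov = FALSE)
  w <- wald_f_test(fit, "poly_row")
  est <- fit$beta[["poly_row1"]]
  se <- sqrt(fit$beta_vcov[2, 2])
  expect_equal(w$F, (est / se)^2, tolerance = 1e-10)
  expect_equal(w$df2, fit$n - fit$p)
  expect_error(wald_f_test(fit, "poly_col"), "not in the fixed part")
})

test_that("Wald F on a null fixed term rejects at about its nominal level", {
  lay <- simulate_layout(5, 8, 10, 4, seed = 91)
  rej <- logical(500)
  for (r in 1:500) {
    y <- sim_response(lay, 0.3, 0.7, 0, 0, seed = 20000 + 2 * r)
    fit <- reml_fit(y, lay, structure = "iid", compute_vcov = FALSE)
    rej[r] <- wald_f_test(fit, "poly_col")$p_value < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("heritability formula, SE and guards behave as specified", {
  fake <- structure(list(sigma2_c = 2, sigma2 = 2, include_clone = TRUE,
                         vcov = matrix(NA_real_, 0, 0)),
                    class = "spatial_lmm")
  expect_equal(heritability(fake)$H2, 0.5)
  fake$sigma2_c <- 0
  expect_equal(heritability(fake)$H2, 0)
  fake$sigma2_c <- 0; fake$sigma2 <- 0
  expect_error(heritability(fake), "total variance")
  # delta-method spot value
  expect_equal(h2_delta_se(1, 1, diag(0.1, 2)), sqrt(0.0125),
               tolerance = 1e-12)
})
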