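# Synthetic clonal-trial generator: layouts, genetic values, spatial
# surfaces, trait assembly, spectra.

test_that("layout respects counts, capacity and determinism", {
  lay <- simulate_layout(1, 3, 1, 3, seed = 1)
  expect_equal(nrow(lay), 3)
  expect_equal(length(unique(lay$clone_id)), 1)

  a <- simulate_layout(10, 10, 30, 3, seed = 7)
  b <- simulate_layout(10, 10, 30, 3, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 90)
  expect_true(all(table(a$clone_id) == 3))
  expect_false(anyDuplicated(a[, c("row", "col")]) > 0)

  expect_error(simulate_layout(3, 3, 5, 2, seed = 1), "capacity")
})

test_that("ecotype is constant within clone and fractions are honored", {
  lay <- simulate_layout(12, 12, 30, 4, seed = 3)
  per_clone <- tapply(lay$ecotype, lay$clone_id,
                      function(e) length(unique(e)))
  expect_true(all(per_clone == 1))
  eco_clones <- table(tapply(lay$ecotype, lay$clone_id, unique))
  expect_equal(sum(eco_clones), 30)
  expect_true(all(eco_clones == 10))
})

test_that("clonal_rows places ramets contiguously in row-major order", {
  lay <- simulate_layout(4, 6, 6, 4, arrangement = "clonal_rows", seed = 5)
  ord <- order(lay$row, lay$col)
  runs <- rle(lay$clone_id[ord])$lengths
  expect_true(all(runs == 4))
})

test_that("genetic values have the requested covariance", {
  expect_equal(unname(simulate_genetic_values(c("a", "b"),
                                              matrix(0, 2, 2), seed = 1)),
               matrix(0, 2, 2))
  ids <- sprintf("C%05d", 1:10000)
  g0 <- simulate_genetic_values(ids, diag(2), seed = 11)
  expect_lt(abs(cor(g0[, 1], g0[, 2])), 0.03)
  G <- matrix(c(1, 0.8, 0.8, 1), 2)
  g8 <- simulate_genetic_values(ids, G, seed = 12)
  expect_lt(abs(cor(g8[, 1], g8[, 2]) - 0.8), 0.02)
  expect_error(simulate_genetic_values(ids, matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
})

test_that("spatial surface reproduces the AR1xAR1 moments", {
  lay <- simulate_layout(20, 20, 100, 4, seed = 2)
  # empirical row-lag-1 correlation over replicate fields
  pos <- matrix(NA_integer_, 20, 20)
  pos[cbind(lay$row, lay$col)] <- seq_len(nrow(lay))
  i1 <- pos[1:19, ]; i2 <- pos[2:20, ]
  lag0 <- numeric(0); lag1 <- numeric(0)
  vars <- numeric(200)
  for (r in 1:200) {
    s <- simulate_spatial_surface(lay, rho_row = 0.6, rho_col = 0,
                                  sigma2 = 4, seed = 100 + r)
    lag0 <- c(lag0, s[i1]); lag1 <- c(lag1, s[i2])
    vars[r] <- var(s)
  }
  expect_lt(abs(cor(lag0, lag1) - 0.6), 0.03)
  expect_lt(abs(mean(vars) - 4) / 4, 0.05)
  # independence when rho = 0
  s0a <- numeric(0); s0b <- numeric(0)
  for (r in 1:50) {
    s <- simulate_spatial_surface(lay, 0, 0, 1, seed = 300 + r)
    s0a <- c(s0a, s[i1]); s0b <- c(s0b, s[i2])
  }
  expect_lt(abs(cor(s0a, s0b)), 3 / sqrt(length(s0a)))
  expect_error(simulate_spatial_surface(lay, rho_row = 1), "rho_row")
})

test_that("trait assembly adds mean, genetic value and surface", {
  lay <- simulate_layout(5, 6, 6, 5, seed = 4)
  gv <- simulate_genetic_values(unique(lay$clone_id),
                                matrix(0, 1, 1, dimnames = list("y", "y")),
                                seed = 1)
  tr <- simulate_traits(lay, gv, matrix(0, nrow(lay), 1,
                                        dimnames = list(NULL, "y")),
                        c(y = 3.5))
  expect_true(all(tr$y == 3.5))
  expect_error(
    simulate_traits(lay, gv, matrix(0, 3, 1), c(y = 3.5)),
    "n_trees"
  )
})

test_that("clone variance is recoverable from replicate trait tables", {
  # method-of-moments oracle: balanced one-way ANOVA on clones,
  # sigma2_c_hat = (MSB - MSW) / ramets
  lay <- simulate_layout(10, 10, 30, 3, seed = 8)
  G <- matrix(0.4, 1, 1, dimnames = list("y", "y"))
  est <- numeric(500)
  for (r in 1:500) {
    gv <- simulate_genetic_values(unique(lay$clone_id), G, seed = 1000 + r)
    surf <- simulate_spatial_surface(lay, 0, 0, 0.6, seed = 5000 + r)
    y <- 10 + gv[lay$clone_id, "y"] + surf
    fitaov <- stats::aov(y ~ factor(lay$clone_id))
    ms <- summary(fitaov)[[1]]$`Mean Sq`
    est[r] <- (ms[1] - ms[2]) / 3
  }
  expect_lt(abs(mean(est) - 0.4), 3 * sd(est) / sqrt(500))
})

test_that("spectra respond monotonically to their linked traits", {
  tr <- data.frame(tree_id = c("t1", "t2"),
                   chl_a = c(2, 4), chl_b = c(1, 2),
                   water = c(1, 1), structure = c(1, 1))
  sp <- simulate_spectra(tr, noise_sd = 0)
  expect_lt(sp["t2", "680"], sp["t1", "680"])
  expect_lt(sp["t2", "550"], sp["t1", "550"])
  # water and structure responses at their wavelengths
  tr2 <- data.frame(tree_id = c("t1", "t2"),
                    chl_a = c(2, 2), chl_b = c(1, 1),
                    water = c(1, 2), structure = c(1, 1))
  sp2 <- simulate_spectra(tr2, noise_sd = 0)
  for (wl in c("970", "1200", "1450", "1930")) {
    expect_lt(sp2["t2", wl], sp2["t1", wl])
  }
  tr3 <- data.frame(tree_id = c("t1", "t2"),
                    chl_a = c(2, 2), chl_b = c(1, 1),
                    water = c(1, 1), structure = c(1, 2))
  sp3 <- simulate_spectra(tr3, noise_sd = 0)
  expect_gt(sp3["t2", "1000"], sp3["t1", "1000"])
  expect_true(all(sp >= 0 & sp <= 1))
})

test_that("zero links and zero noise give the shared baseline", {
  tr <- data.frame(tree_id = c("t1", "t2"), chl_a = c(2, 5),
                   chl_b = c(1, 2), water = c(0, 3), structure = c(1, 4))
  sp <- simulate_spectra(tr, links = list(chlorophyll = 0, water = 0,
                                          structure = 0), noise_sd = 0)
  expect_equal(sp["t1", ], sp["t2", ])
})

test_that("regression on R680 recovers the chlorophyll link coefficient", {
  set.seed(21)
  n <- 1000
  tr <- data.frame(tree_id = sprintf("t%04d", 1:n),
                   chl_a = rnorm(n, 3, 0.5), chl_b = rnorm(n, 1, 0.2),
                   water = 1, structure = 1)
  sp <- simulate_spectra(tr, noise_sd = 0.001, seed = 22)
  chl_tot <- tr$chl_a + tr$chl_b
  slope <- coef(lm(sp[, "680"] ~ chl_tot))[2]
  k <- spectral_links()$chlorophyll
  expect_lt(abs(-slope - k) / k, 0.05)
})

test_that("the end-to-end trial is deterministic in the seed", {
  a <- simulate_trial(n_rows = 6, n_cols = 6, n_clones = 10,
                      ramets_per_clone = 3, seed = 99)
  b <- simulate_trial(n_rows = 6, n_cols = 6, n_clones = 10,
                      ramets_per_clone = 3, seed = 99)
  expect_identical(a$traits, b$traits)
  expect_identical(unclass(a$spectra), unclass(b$spectra))
})

test_that("layout and trait CSV round-trips preserve the tables", {
  lay <- simulate_layout(5, 5, 5, 4, seed = 13)
  f <- tempfile(fileext = ".csv")
  write_layout(lay, f)
  expect_equal(read_layout(f), lay)
  unlink(f)
})
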