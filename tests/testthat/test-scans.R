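# Wavelength-wise scans, group comparisons, region extraction.

make_spectra_pair <- function(n = 20, shift_at = NULL, shift = 0, seed = 1) {
  set.seed(seed)
  wl <- 500:549
  ids <- sprintf("t%02d", 1:n)
  base <- matrix(0.3 + rnorm(n * 50, sd = 0.01), n, 50,
                 dimnames = list(ids, wl))
  m2 <- base + matrix(rnorm(n * 50, sd = 0.01), n, 50)
  if (!is.null(shift_at)) {
    m2[, as.character(shift_at)] <- m2[, as.character(shift_at)] + shift
  }
  list(a = as_spectra(base), b = as_spectra(m2))
}

test_that("paired t-scan flags identical samplings degenerate", {
  sp <- make_spectra_pair()
  r <- paired_t_scan(sp$a, sp$a)
  expect_true(all(r$degenerate))
  expect_true(all(r$p == 1))
})

test_that("paired t-scan detects a designed shift and is order invariant", {
  sd_diff <- sqrt(2) * 0.01
  sp <- make_spectra_pair(n = 20, shift_at = 520, shift = 5 * sd_diff,
                          seed = 3)
  r <- paired_t_scan(sp$a, sp$b)
  expect_lt(r$p[r$wavelength == 520], 1e-6)
  # closed-form paired t at one wavelength
  d <- sp$a[, "520"] - sp$b[, "520"]
  t_hand <- mean(d) / (sd(d) / sqrt(20))
  expect_equal(r$t[r$wavelength == 520], t_hand, tolerance = 1e-12)
  expect_equal(r$p[r$wavelength == 520], 2 * pt(-abs(t_hand), 19),
               tolerance = 1e-12)
  # permuting tree order identically leaves the scan bit-identical
  perm <- sample(rownames(sp$a))
  r2 <- paired_t_scan(sp$a[perm, ], sp$b[perm, ])
  expect_identical(r, r2)
})

test_that("paired t-scan drops unmatched trees and enforces n >= 3", {
  sp <- make_spectra_pair(n = 5, seed = 4)
  b2 <- sp$b[1:4, ]
  expect_message(r <- paired_t_scan(sp$a, b2), "unmatched")
  expect_true(all(r$df == 3))
  expect_error(suppressMessages(paired_t_scan(sp$a[1:2, ], sp$b[1:2, ])),
               "at least 3")
})

test_that("Fisher's LSD matches the textbook pooled-variance formula", {
  vals <- c(1.1, 1.3, 1.2, 2.1, 2.0, 2.2, 1.6, 1.5, 1.8)
  grp <- rep(c("low", "medium", "high"), each = 3)
  r <- lsd_compare(vals, grp)
  expect_equal(nrow(r), 3)
  # hand computation for one pair
  means <- tapply(vals, grp, mean)
  mse <- sum(tapply(vals, grp, function(v) sum((v - mean(v))^2))) / (9 - 3)
  se <- sqrt(mse * (1 / 3 + 1 / 3))
  i <- which(r$group1 == "high" & r$group2 == "low" |
               r$group1 == "low" & r$group2 == "high")
  expect_equal(abs(r$diff[i]), abs(means[["high"]] - means[["low"]]),
               tolerance = 1e-10)
  expect_equal(r$se[i], se, tolerance = 1e-10)
  expect_equal(abs(r$t[i]), abs(means[["high"]] - means[["low"]]) / se,
               tolerance = 1e-10)
  expect_equal(r$p[i], 2 * pt(-abs(r$t[i]), 6), tolerance = 1e-12)
})

test_that("LSD identities: identical groups, zero MSE, antisymmetry", {
  vals <- c(1, 2, 3, 1, 2, 3)
  grp <- rep(c("a", "b"), each = 3)
  r <- lsd_compare(vals, grp)
  expect_equal(r$diff, 0)
  expect_equal(r$p, 1)
  # zero pooled variance flags degenerate
  r0 <- lsd_compare(c(0, 0, 0, 1, 1, 1, .5, .5, .5),
                    rep(c("a", "b", "c"), each = 3))
  expect_true(all(r0$degenerate))
  expect_true(all(is.na(r0$p)))
  expect_equal(r0$diff[r0$group1 == "a" & r0$group2 == "b"], -1)
  # group with n < 2 errors
  expect_error(lsd_compare(c(1, 2, 3), c("a", "a", "b")), "n >= 2")
})

test_that("Pearson scan reproduces r, SE and p formulas", {
  set.seed(9)
  n <- 87
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("w", 1:4)))
  trait <- X[, 1]  # identical column -> r = 1
  r <- pearson_scan(X, trait)
  expect_equal(r$r[1], 1)
  expect_equal(r$se[1], 0)
  j <- 2
  rr <- cor(X[, j], trait)
  expect_equal(r$r[j], rr, tolerance = 1e-12)
  expect_equal(r$se[j], sqrt((1 - rr^2) / (n - 2)), tolerance = 1e-12)
  tt <- rr * sqrt((n - 2) / (1 - rr^2))
  expect_equal(r$p[j], 2 * pt(-abs(tt), n - 2), tolerance = 1e-12)
  # SE magnitude at r = 0 and n = 87
  expect_equal(sqrt(1 / 85), 0.1085, tolerance = 1e-3)
  # constant column flagged undefined
  X[, 3] <- 1
  r2 <- pearson_scan(X, trait)
  expect_true(r2$undefined[3])
  expect_true(is.na(r2$r[3]))
})

test_that("heritability scan recovers designed H2 and survives failures", {
  lay <- simulate_layout(10, 10, 30, 3, seed = 171)
  y1 <- sim_response(lay, 0.45, 0.55, 0, 0, seed = 172)  # H2 = 0.45
  X <- cbind(h = y1, flat = rep(1, 90))
  r <- heritability_scan(X, lay, structure = "iid")
  expect_equal(nrow(r), 2)
  expect_true(is.finite(r$H2[1]))
  expect_true(abs(r$H2[1] - 0.45) < 0.25)  # single replicate, wide MC band
  expect_true(!is.na(r$error[2]))          # constant column fails gracefully
})

test_that("gcorr scan records boundary and failure columns", {
  lay <- simulate_layout(6, 6, 10, 3, seed = 181)
  y <- sim_response(lay, 0.5, 0.5, 0, 0, seed = 182)
  X <- cbind(dup = y, flat = rep(1, 30))
  r <- suppressWarnings(gcorr_scan(X, y, lay, structure = "iid"))
  expect_identical(r$flag[1], "B")
  expect_equal(abs(r$r_g[1]), 0.999)
  expect_true(!is.na(r$error[2]))
})

test_that("significant regions are maximal runs that invert the mask", {
  grid <- 350:449
  p <- rep(1, 100)
  expect_equal(nrow(significant_regions(p, grid)), 0)
  p[grid %in% 400:410] <- 0.01
  p[grid == 440] <- 0.01
  r <- significant_regions(p, grid)
  expect_equal(r$start_nm, c(400, 440))
  expect_equal(r$end_nm, c(410, 440))
  # idempotence / exact invertibility on random vectors
  set.seed(12)
  for (k in 1:25) {
    pv <- runif(100)
    reg <- significant_regions(pv, grid, alpha = 0.3)
    covered <- unlist(Map(seq, reg$start_nm, reg$end_nm))
    expect_identical(sort(covered), sort(grid[pv < 0.3]))
    if (nrow(reg) > 1) {
      expect_true(all(reg$start_nm[-1] > reg$end_nm[-nrow(reg)] + 1))
    }
  }
})
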