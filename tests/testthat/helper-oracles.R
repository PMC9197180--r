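# Independent oracles used across test files. These deliberately avoid the
# package's likelihood code paths: the restricted log-likelihood is evaluated
# as the Gaussian log-density of error contrasts K'y with K an explicit
# orthonormal basis of the orthogonal complement of the fixed-effect design.

oracle_restricted_ll <- function(y, X, V) {
  n <- length(y)
  p <- ncol(X)
  K <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE]
  Ky <- crossprod(K, y)
  KVK <- crossprod(K, V %*% K)
  ch <- chol(KVK)
  -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, Ky, transpose = TRUE)^2))
}

# Dense covariance implied by a univariate fit, built elementwise by loops.
oracle_V_univariate <- function(fit) {
  lay <- fit$layout
  n <- nrow(lay)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      v <- fit$sigma2 *
        fit$rho_row^abs(lay$row[i] - lay$row[j]) *
        fit$rho_col^abs(lay$col[i] - lay$col[j])
      if (fit$structure == "iid") v <- if (i == j) fit$sigma2 else 0
      if (fit$include_clone && lay$clone_id[i] == lay$clone_id[j]) {
        v <- v + fit$sigma2_c
      }
      V[i, j] <- v
    }
  }
  V
}

# Dense covariance implied by a bivariate fit, built elementwise from the
# stacked records.
oracle_V_bivariate <- function(fit) {
  d <- fit$stacked$data
  N <- nrow(d)
  V <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      ti <- as.integer(d$trait[i]); tj <- as.integer(d$trait[j])
      v <- 0
      if (d$clone_id[i] == d$clone_id[j]) v <- v + fit$G[ti, tj]
      if (d$tree_id[i] == d$tree_id[j]) {
        v <- v + fit$sigma2_u
      }
      if (ti == tj) {
        rr <- fit$resid$rho_row[ti]; rc <- fit$resid$rho_col[ti]
        if (fit$structure == "iid") { rr <- 0; rc <- 0 }
        v <- v + fit$resid$sigma2[ti] *
          rr^abs(d$row[i] - d$row[j]) * rc^abs(d$col[i] - d$col[j])
      }
      V[i, j] <- v
    }
  }
  V
}

# Simulate one univariate trial response at given truth on a fixed layout.
sim_response <- function(layout, sigma2_c, sigma2, rho_row, rho_col, mu = 10,
                         seed = NULL) {
  gv <- simulate_genetic_values(unique(layout$clone_id),
                                matrix(sigma2_c, 1, 1,
                                       dimnames = list("y", "y")),
                                seed = seed)
  surf <- simulate_spatial_surface(layout, rho_row, rho_col, sigma2,
                                   seed = if (is.null(seed)) NULL else seed + 1)
  mu + gv[layout$clone_id, "y"] + surf
}
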