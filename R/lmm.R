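# Univariate spatial linear mixed model:
#   y = X beta + Z c + e,  c ~ N(0, sigma2_c I),  e ~ N(0, sigma2 C)
# with C either the identity (iid) or the observed-tree submatrix of the
# separable AR1(rho_col) x AR1(rho_row) correlation. Variance components are
# estimated by REML with fixed effects and the residual scale profiled out.

#' Orthogonal polynomial basis for field indices
#'
#' Orthonormal polynomial basis (via [stats::poly()]) in an index vector,
#' used as the fixed-effect spatial trend of the mixed models: columns are
#' mutually orthogonal with unit norm, and the first column spans the linear
#' trend of the centered indices.
#'
#' @param indices numeric vector (e.g. row or column numbers).
#' @param degree polynomial degree (default 2).
#' @return matrix with `degree` columns.
#' @export
orthogonal_polynomial_basis <- function(indices, degree = 2L) {
  if (length(unique(indices)) <= degree) {
    stop("need more than ", degree, " distinct index values for a degree-",
         degree, " basis", call. = FALSE)
  }
  B <- stats::poly(indices, degree = degree)
  # poly() columns are orthogonal with unit norm already
  unname(matrix(as.numeric(B), nrow = length(indices)))
}

#' AR1 correlation matrix
#'
#' First-order autoregressive correlation over integer indices: entry (i, j)
#' is `rho^|index_i - index_j|`.
#'
#' @param rho autocorrelation, `|rho| < 1`.
#' @param indices integer positions.
#' @return symmetric positive-definite correlation matrix.
#' @export
ar1_correlation <- function(rho, indices) {
  check_rho(rho)
  rho^abs(outer(indices, indices, "-"))
}

#' Residual covariance of observed trees
#'
#' For the `"ar1xar1"` structure the covariance between trees at positions
#' \eqn{(r_1,c_1)} and \eqn{(r_2,c_2)} is
#' \eqn{\sigma^2\,\rho_{col}^{|c_1-c_2|}\,\rho_{row}^{|r_1-r_2|}} — the
#' observed-tree submatrix of the full Kronecker product
#' \eqn{\sigma^2\,[AR1(\rho_{col}) \otimes AR1(\rho_{row})]}; `"iid"` gives
#' \eqn{\sigma^2 I}.
#'
#' @param layout trial layout with `row` and `col` columns (observed trees).
#' @param sigma2 residual variance.
#' @param rho_row,rho_col autoregressive correlations (ignored for `"iid"`).
#' @param structure `"iid"` or `"ar1xar1"`.
#' @return covariance matrix over the trees in `layout` order.
#' @export
residual_covariance <- function(layout, sigma2 = 1, rho_row = 0, rho_col = 0,
                                structure = c("ar1xar1", "iid")) {
  structure <- match.arg(structure)
  n <- nrow(layout)
  if (structure == "iid") return(sigma2 * diag(n))
  check_rho(rho_row, "rho_row"); check_rho(rho_col, "rho_col")
  sigma2 * ar1xar1_correlation(layout$row, layout$col, rho_row, rho_col)
}

# ---- internal likelihood machinery -----------------------------------------

# Shared data bundle for the likelihood evaluators.
uni_data <- function(y, layout, structure, include_clone,
                     poly_row, poly_col, degree) {
  keep <- is.finite(y)
  y <- y[keep]
  layout <- layout[keep, , drop = FALSE]
  n <- length(y)
  X <- matrix(1, n, 1)
  terms <- list(intercept = 1L)
  if (poly_row) {
    B <- orthogonal_polynomial_basis(layout$row, degree)
    terms$poly_row <- ncol(X) + seq_len(ncol(B))
    X <- cbind(X, B)
  }
  if (poly_col) {
    B <- orthogonal_polynomial_basis(layout$col, degree)
    terms$poly_col <- ncol(X) + seq_len(ncol(B))
    X <- cbind(X, B)
  }
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design is rank deficient",
                           call. = FALSE)
  ZZt <- NULL
  if (include_clone) {
    cl <- factor(layout$clone_id)
    Z <- stats::model.matrix(~ 0 + cl)
    ZZt <- tcrossprod(Z)
  }
  Cfun <- if (structure == "iid") {
    function(rr, rc) diag(n)
  } else {
    function(rr, rc) ar1xar1_correlation(layout$row, layout$col, rr, rc)
  }
  list(y = y, X = X, n = n, p = p, ZZt = ZZt, Cfun = Cfun, terms = terms,
       layout = layout, ldXtX = as.numeric(determinant(crossprod(X))$modulus),
       structure = structure, include_clone = include_clone)
}

# Profiled REML log-likelihood at (gamma = sigma2_c/sigma2, rho_row, rho_col):
# the restricted log-density of contrasts K'y with K an orthonormal basis of
# the orthogonal complement of col(X), with beta and sigma2 at their
# maximizers. Returns -Inf outside the feasible region.
uni_profiled_ll <- function(gamma, rho_row, rho_col, dat, value_only = TRUE) {
  W <- dat$Cfun(rho_row, rho_col)
  if (!is.null(dat$ZZt) && gamma > 0) W <- W + gamma * dat$ZZt
  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(ch)) return(if (value_only) -Inf else NULL)
  ldW <- 2 * sum(log(diag(ch)))
  Wi_y <- backsolve(ch, backsolve(ch, dat$y, transpose = TRUE))
  Wi_X <- backsolve(ch, backsolve(ch, dat$X, transpose = TRUE))
  XtWiX <- crossprod(dat$X, Wi_X)
  chX <- tryCatch(chol(XtWiX), error = function(e) NULL)
  if (is.null(chX)) return(if (value_only) -Inf else NULL)
  ldX <- 2 * sum(log(diag(chX)))
  Xty <- crossprod(dat$X, Wi_y)
  beta <- backsolve(chX, backsolve(chX, Xty, transpose = TRUE))
  ypy <- sum(dat$y * Wi_y) - sum(Xty * beta)
  nm <- dat$n - dat$p
  if (ypy <= 0) return(if (value_only) -Inf else NULL)
  s2 <- ypy / nm
  ll <- -0.5 * (nm * log(2 * pi) + nm * log(s2) + nm + ldW + ldX - dat$ldXtX)
  if (value_only) return(ll)
  XtWiX_inv <- chol2inv(chX)
  list(ll = ll, sigma2 = s2, beta = drop(beta),
       beta_vcov = s2 * XtWiX_inv)
}

# Unprofiled restricted log-likelihood at natural-scale variance parameters;
# used for the numeric Hessian and as the reporting convention (identical to
# the profiled value at the optimum).
uni_ll <- function(sigma2_c, sigma2, rho_row, rho_col, dat) {
  if (sigma2 <= 0) return(-Inf)
  V <- sigma2 * dat$Cfun(rho_row, rho_col)
  if (!is.null(dat$ZZt) && sigma2_c != 0) V <- V + sigma2_c * dat$ZZt
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  ldV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, backsolve(ch, dat$y, transpose = TRUE))
  Vi_X <- backsolve(ch, backsolve(ch, dat$X, transpose = TRUE))
  XtViX <- crossprod(dat$X, Vi_X)
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(-Inf)
  ldX <- 2 * sum(log(diag(chX)))
  Xty <- crossprod(dat$X, Vi_y)
  beta <- backsolve(chX, backsolve(chX, Xty, transpose = TRUE))
  ypy <- sum(dat$y * Vi_y) - sum(Xty * beta)
  -0.5 * ((dat$n - dat$p) * log(2 * pi) + ldV + ldX - dat$ldXtX + ypy)
}

rho_bound <- 0.99
to_rho <- function(z) rho_bound * tanh(z)
from_rho <- function(r) atanh(pmin(pmax(r / rho_bound, -0.999999), 0.999999))

#' Fit the univariate spatial mixed model by REML
#'
#' Maximizes the restricted likelihood over the clone-to-residual variance
#' ratio and (for `structure = "ar1xar1"`) the row/column autocorrelations,
#' with fixed effects and the residual variance profiled out analytically.
#' The search probes a small start grid (variance ratio 0.1/1/3 crossed with
#' autocorrelations 0/0.5/-0.5), refines the best probe by Nelder-Mead on
#' transformed coordinates (log ratio, scaled atanh of rho), and compares the
#' result against an explicit fit on the `sigma2_c = 0` boundary. The
#' variance-parameter covariance matrix is the negative inverse of a
#' central-difference Hessian of the restricted log-likelihood at the
#' optimum.
#'
#' @param y response vector, aligned with `layout` rows; non-finite entries
#'   are dropped listwise (the layout of retained trees keeps its original
#'   coordinates, so spatial lags are preserved).
#' @param layout trial layout (`row`, `col`, `clone_id`, `tree_id`).
#' @param structure residual structure: `"ar1xar1"` (default) or `"iid"`.
#' @param include_clone fit the clone variance component (set `FALSE` for the
#'   null model of the clone-variance likelihood-ratio test).
#' @param poly_row,poly_col include second-order orthogonal polynomial trends
#'   in the row / column index.
#' @param degree polynomial degree for the spatial trend.
#' @param compute_vcov compute the variance-parameter covariance matrix
#'   (numeric Hessian; skip for speed in simulation loops).
#' @param control list: `maxit` (Nelder-Mead iterations, default 500),
#'   `reltol` (default 1e-10).
#' @return object of class `"spatial_lmm"` with components `sigma2_c`,
#'   `sigma2`, `rho_row`, `rho_col`, `beta`, `beta_vcov`, `loglik`, `vcov`
#'   (variance parameters), `converged`, `n`, `n_varpar`, `terms`, and the
#'   model frame needed by downstream tests.
#' @examples
#' trial <- simulate_trial(seed = 7)
#' fit <- reml_fit(trial$traits$chl_a, trial$layout, compute_vcov = FALSE)
#' fit$sigma2_c / (fit$sigma2_c + fit$sigma2)
#' @export
reml_fit <- function(y, layout, structure = c("ar1xar1", "iid"),
                     include_clone = TRUE, poly_row = TRUE, poly_col = TRUE,
                     degree = 2L, compute_vcov = TRUE, control = list()) {
  structure <- match.arg(structure)
  check_layout(layout)
  if (length(y) != nrow(layout)) {
    stop("'y' and 'layout' lengths disagree", call. = FALSE)
  }
  maxit <- control$maxit %||% 500L
  reltol <- control$reltol %||% 1e-10
  dat <- uni_data(y, layout, structure, include_clone, poly_row, poly_col,
                  degree)
  if (stats::var(dat$y) == 0) {
    stop("response is constant; variance components are undefined",
         call. = FALSE)
  }

  ar1 <- structure == "ar1xar1"
  converged <- TRUE

  if (!include_clone && !ar1) {
    gamma <- 0; rho <- c(0, 0)
  } else if (include_clone && !ar1) {
    # 1-D search in log gamma, plus the gamma = 0 boundary
    f <- function(lg) -uni_profiled_ll(exp(lg), 0, 0, dat)
    opt <- stats::optimize(f, c(log(1e-8), log(1e5)), tol = 1e-10)
    ll0 <- uni_profiled_ll(0, 0, 0, dat)
    if (ll0 >= -opt$objective) {
      gamma <- 0
    } else {
      gamma <- exp(opt$minimum)
    }
    rho <- c(0, 0)
  } else {
    # probe the start grid, refine by Nelder-Mead
    gammas <- if (include_clone) c(0.1, 1, 3) else NA_real_
    rhos <- c(0, 0.5, -0.5)
    probes <- expand.grid(g = gammas, r = rhos)
    probe_ll <- mapply(function(g, r) {
      uni_profiled_ll(if (is.na(g)) 0 else g, r, r, dat)
    }, probes$g, probes$r)
    best <- probes[which.max(probe_ll), ]
    if (include_clone) {
      par0 <- c(log(best$g), from_rho(best$r), from_rho(best$r))
      fn <- function(p) -uni_profiled_ll(exp(p[1]), to_rho(p[2]),
                                         to_rho(p[3]), dat)
    } else {
      par0 <- c(from_rho(best$r), from_rho(best$r))
      fn <- function(p) -uni_profiled_ll(0, to_rho(p[1]), to_rho(p[2]), dat)
    }
    opt <- stats::optim(par0, fn, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    # one polish restart from the optimum (standard Nelder-Mead practice)
    opt2 <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = reltol))
    if (opt2$value < opt$value) opt <- opt2
    converged <- opt$convergence == 0
    if (include_clone) {
      gamma <- exp(opt$par[1]); rho <- to_rho(opt$par[2:3])
      # boundary comparison: best fit with sigma2_c pinned at 0
      fb <- function(p) -uni_profiled_ll(0, to_rho(p[1]), to_rho(p[2]), dat)
      optb <- stats::optim(from_rho(rho), fb, method = "Nelder-Mead",
                           control = list(maxit = maxit, reltol = reltol))
      if (-optb$value >= -opt$value) {
        gamma <- 0; rho <- to_rho(optb$par)
        converged <- optb$convergence == 0
      }
    } else {
      gamma <- 0; rho <- to_rho(opt$par)
    }
  }

  fin <- uni_profiled_ll(gamma, rho[1], rho[2], dat, value_only = FALSE)
  if (is.null(fin)) {
    stop("REML fit failed: profiled likelihood undefined at the optimum",
         call. = FALSE)
  }
  sigma2 <- fin$sigma2
  sigma2_c <- gamma * sigma2

  # named variance parameters in natural units
  par_names <- c(if (include_clone) "sigma2_c", "sigma2",
                 if (ar1) c("rho_row", "rho_col"))
  theta <- c(if (include_clone) sigma2_c, sigma2, if (ar1) rho)
  names(theta) <- par_names

  vcov <- matrix(NA_real_, length(theta), length(theta),
                 dimnames = list(par_names, par_names))
  if (compute_vcov) {
    llfun <- function(th) {
      names(th) <- par_names
      uni_ll(if (include_clone) th[["sigma2_c"]] else 0, th[["sigma2"]],
             if (ar1) th[["rho_row"]] else 0,
             if (ar1) th[["rho_col"]] else 0, dat)
    }
    H <- num_hessian(llfun, theta)
    vcov <- vcov_from_hessian(H, par_names)
  }

  beta_names <- c("intercept",
                  if (poly_row) paste0("poly_row", seq_len(degree)),
                  if (poly_col) paste0("poly_col", seq_len(degree)))
  beta <- stats::setNames(fin$beta, beta_names)

  out <- list(
    sigma2_c = if (include_clone) sigma2_c else 0,
    sigma2 = sigma2, gamma = gamma,
    rho_row = if (ar1) rho[1] else 0, rho_col = if (ar1) rho[2] else 0,
    beta = beta, beta_vcov = fin$beta_vcov,
    loglik = fin$ll, vcov = vcov, converged = converged,
    n = dat$n, p = dat$p,
    n_varpar = length(theta),
    structure = structure, include_clone = include_clone,
    terms = dat$terms, X = dat$X, y = dat$y, layout = dat$layout,
    call = match.call()
  )
  class(out) <- "spatial_lmm"
  out
}

#' @export
print.spatial_lmm <- function(x, ...) {
  cat("Spatial linear mixed model (REML)\n")
  cat("  residual structure:", x$structure, "\n")
  cat(sprintf("  sigma2_c = %.4g, sigma2 = %.4g", x$sigma2_c, x$sigma2))
  if (x$structure == "ar1xar1") {
    cat(sprintf(", rho_row = %.3f, rho_col = %.3f", x$rho_row, x$rho_col))
  }
  cat(sprintf("\n  REML log-likelihood = %.4f (n = %d)\n", x$loglik, x$n))
  invisible(x)
}

#' @export
logLik.spatial_lmm <- function(object, ...) {
  structure(object$loglik, df = object$n_varpar, class = "logLik")
}

#' Likelihood-ratio test between nested REML fits
#'
#' Compares two REML fits with identical fixed parts. The statistic is
#' `2 * (logLik(full) - logLik(reduced))`, floored at zero. When the null
#' pins a variance at its boundary (clone variance = 0) the reference
#' distribution is the equal mixture `0.5*chisq(0) + 0.5*chisq(1)`; for
#' interior nulls (autocorrelations) a plain chi-square with df equal to the
#' parameter-count difference is used. The boundary case is auto-detected
#' (full model has the clone term, reduced does not, same residual structure)
#' and can be overridden.
#'
#' @param full,reduced `"spatial_lmm"` fits; `reduced` nested in `full`.
#' @param boundary `"auto"`, `"variance"` (mixture) or `"none"` (plain
#'   chi-square).
#' @return list with `statistic`, `df`, `p_value`, `boundary`.
#' @export
likelihood_ratio_test <- function(full, reduced,
                                  boundary = c("auto", "variance", "none")) {
  boundary <- match.arg(boundary)
  if (!identical(dim(full$X), dim(reduced$X)) ||
      max(abs(full$X - reduced$X)) > 1e-10) {
    stop("fits have different fixed parts; REML log-likelihoods are not ",
         "comparable", call. = FALSE)
  }
  df <- full$n_varpar - reduced$n_varpar
  if (df < 0) stop("'reduced' has more parameters than 'full'", call. = FALSE)
  if (boundary == "auto") {
    boundary <- if (full$include_clone && !reduced$include_clone &&
                    full$structure == reduced$structure) "variance" else "none"
  }
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (boundary == "variance" && df == 1L) {
    if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)
  } else {
    if (stat <= 0 || df == 0L) 1 else
      stats::pchisq(stat, df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p_value = p, boundary = boundary)
}

#' Approximate Wald F-test of a fixed-effect term
#'
#' Wald F-statistic for a named fixed-effect term using the fitted
#' fixed-effect covariance; the denominator degrees of freedom are the
#' containment-style simplification `n - rank(X)` (labelled in the output).
#'
#' @param fit a `"spatial_lmm"` fit.
#' @param term one of the term labels in `fit$terms` (e.g. `"poly_row"`).
#' @return list with `F`, `df1`, `df2`, `p_value`, `ddf_method`.
#' @export
wald_f_test <- function(fit, term) {
  if (!term %in% names(fit$terms)) {
    stop("term '", term, "' not in the fixed part; available: ",
         paste(names(fit$terms), collapse = ", "), call. = FALSE)
  }
  idx <- fit$terms[[term]]
  b <- fit$beta[idx]
  Vb <- fit$beta_vcov[idx, idx, drop = FALSE]
  ch <- tryCatch(chol(Vb), error = function(e) {
    stop("coefficient covariance for term '", term,
         "' is singular (rank problem)", call. = FALSE)
  })
  q <- length(b)
  Fstat <- sum(backsolve(ch, b, transpose = TRUE)^2) / q
  df2 <- fit$n - fit$p
  list(F = Fstat, df1 = q, df2 = df2,
       p_value = stats::pf(Fstat, q, df2, lower.tail = FALSE),
       ddf_method = "containment (n - rank(X))")
}

#' Delta-method standard error of broad-sense heritability
#'
#' First-order propagation of the covariance of
#' \eqn{(\sigma^2_c, \sigma^2)} through
#' \eqn{H^2 = \sigma^2_c/(\sigma^2_c+\sigma^2)}; the gradient is
#' \eqn{(\sigma^2, -\sigma^2_c)/(\sigma^2_c+\sigma^2)^2}.
#'
#' @param sigma2_c,sigma2 clone and residual variance estimates.
#' @param vcov2 2x2 covariance of `(sigma2_c, sigma2)` in that order.
#' @return the standard error (NA when the quadratic form is not finite).
#' @examples
#' h2_delta_se(1, 1, diag(0.1, 2))  # about 0.1118
#' @export
h2_delta_se <- function(sigma2_c, sigma2, vcov2) {
  tot <- sigma2_c + sigma2
  g <- c(sigma2, -sigma2_c) / tot^2
  v <- drop(t(g) %*% vcov2 %*% g)
  if (!is.finite(v) || v < 0) return(NA_real_)
  sqrt(v)
}

#' Broad-sense heritability from a REML fit
#'
#' Computes \eqn{H^2 = \sigma^2_c / (\sigma^2_c + \sigma^2)} with a
#' delta-method standard error propagated from the fit's variance-parameter
#' covariance, and (when a reduced fit without the clone term is supplied)
#' the boundary-corrected likelihood-ratio p-value for \eqn{\sigma^2_c = 0}.
#'
#' @param fit a `"spatial_lmm"` fit with the clone term.
#' @param reduced optional matching fit with `include_clone = FALSE`.
#' @return object of class `"heritability"`: list with `H2`, `SE`,
#'   `p_value` (`NA` without `reduced`), `sigma2_c`, `sigma2`.
#' @examples
#' # H2 = 0.5 when both components are equal
#' @export
heritability <- function(fit, reduced = NULL) {
  if (!fit$include_clone) {
    stop("fit has no clone variance component", call. = FALSE)
  }
  tot <- fit$sigma2_c + fit$sigma2
  if (tot <= 0) stop("total variance is zero; heritability undefined",
                     call. = FALSE)
  H2 <- fit$sigma2_c / tot
  se <- NA_real_
  if (all(c("sigma2_c", "sigma2") %in% rownames(fit$vcov)) &&
      !anyNA(fit$vcov[c("sigma2_c", "sigma2"), c("sigma2_c", "sigma2")])) {
    se <- h2_delta_se(fit$sigma2_c, fit$sigma2,
                      fit$vcov[c("sigma2_c", "sigma2"),
                               c("sigma2_c", "sigma2")])
  }
  p <- NA_real_
  if (!is.null(reduced)) {
    p <- likelihood_ratio_test(fit, reduced, boundary = "variance")$p_value
  }
  out <- list(H2 = H2, SE = se, p_value = p,
              sigma2_c = fit$sigma2_c, sigma2 = fit$sigma2)
  class(out) <- "heritability"
  out
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("H2 = %.3f (SE %.3f)", x$H2, x$SE))
  if (!is.na(x$p_value)) cat(sprintf(", LRT p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}
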