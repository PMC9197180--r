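# Stacked bivariate mixed model for genetic correlations:
#   y = X1 t + X1 t:beta_x + X2 t:beta_y + Z1 tc + Z2 u + e
# tc ~ N(0, Gc x Ic) with Gc unstructured 2x2, u ~ N(0, sigma2_u I_trees)
# shared across traits, e trait-block-diagonal (iid or AR1xAR1 per trait).

# Generic restricted Gaussian log-likelihood machinery over a covariance
# matrix M (profiled scale optional); shared by the bivariate evaluators.
restricted_ll <- function(M, y, X, ldXtX, profile = TRUE,
                          value_only = TRUE) {
  n <- length(y); p <- ncol(X)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(if (value_only) -Inf else NULL)
  ldM <- 2 * sum(log(diag(ch)))
  Mi_y <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  Mi_X <- backsolve(ch, backsolve(ch, X, transpose = TRUE))
  XtMiX <- crossprod(X, Mi_X)
  chX <- tryCatch(chol(XtMiX), error = function(e) NULL)
  if (is.null(chX)) return(if (value_only) -Inf else NULL)
  ldX <- 2 * sum(log(diag(chX)))
  Xty <- crossprod(X, Mi_y)
  beta <- backsolve(chX, backsolve(chX, Xty, transpose = TRUE))
  ypy <- sum(y * Mi_y) - sum(Xty * beta)
  nm <- n - p
  if (profile) {
    if (ypy <= 0) return(if (value_only) -Inf else NULL)
    s2 <- ypy / nm
    ll <- -0.5 * (nm * log(2 * pi) + nm * log(s2) + nm + ldM + ldX - ldXtX)
    if (value_only) return(ll)
    return(list(ll = ll, sigma2 = s2, beta = drop(beta),
                beta_vcov = s2 * chol2inv(chX)))
  }
  ll <- -0.5 * (nm * log(2 * pi) + ldM + ldX - ldXtX + ypy)
  if (value_only) return(ll)
  list(ll = ll, beta = drop(beta), beta_vcov = chol2inv(chX))
}

#' Stack two traits for the bivariate model
#'
#' Builds the stacked response (one record per tree and trait) and the
#' trait-nested fixed-effect design: a trait main effect plus second-order
#' orthogonal polynomials in row and column index nested within trait. Only
#' trees with both traits observed enter; unmatched trees are dropped with a
#' message. Traits are ordered internally by name so that the fit is
#' invariant to the order in which the two traits are supplied.
#'
#' @param y1,y2 response vectors aligned with `layout` rows (`NA` = missing).
#' @param layout trial layout.
#' @param trait_names labels for the two traits.
#' @param degree polynomial degree of the trait-nested spatial trend.
#' @return object of class `"stacked_traits"`: list with `data` (stacked
#'   records: `tree_id`, `trait`, `value`, `row`, `col`, `clone_id`), the
#'   design matrix `X`, `m` (trees per trait), `trait_names` (canonical
#'   order) and `n_dropped`.
#' @export
stack_bivariate <- function(y1, y2, layout,
                            trait_names = c("trait1", "trait2"),
                            degree = 2L) {
  check_layout(layout)
  if (length(y1) != nrow(layout) || length(y2) != nrow(layout)) {
    stop("'y1'/'y2' must align with 'layout' rows", call. = FALSE)
  }
  if (anyDuplicated(trait_names)) {
    trait_names <- make.unique(trait_names)
  }
  keep <- is.finite(y1) & is.finite(y2)
  if (!any(keep)) {
    stop("no tree has both traits observed (disjoint tree sets)",
         call. = FALSE)
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " trees without both traits dropped from the stack")
  }
  lay <- layout[keep, , drop = FALSE]
  ys <- list(y1[keep], y2[keep])
  names(ys) <- trait_names
  ord <- order(trait_names)
  trait_names <- trait_names[ord]
  ys <- ys[ord]
  m <- nrow(lay)

  dat <- data.frame(
    tree_id = rep(lay$tree_id, 2),
    trait = factor(rep(trait_names, each = m), levels = trait_names),
    value = c(ys[[1]], ys[[2]]),
    row = rep(lay$row, 2), col = rep(lay$col, 2),
    clone_id = rep(lay$clone_id, 2),
    stringsAsFactors = FALSE
  )

  Brow <- orthogonal_polynomial_basis(lay$row, degree)
  Bcol <- orthogonal_polynomial_basis(lay$col, degree)
  Buni <- cbind(Brow, Bcol)
  zero <- matrix(0, m, ncol(Buni))
  X <- cbind(
    c(rep(1, m), rep(0, m)), c(rep(0, m), rep(1, m)),
    rbind(Buni, zero), rbind(zero, Buni)
  )
  colnames(X) <- c(paste0("mu_", trait_names),
                   paste0(trait_names[1], ":",
                          c(paste0("poly_row", seq_len(degree)),
                            paste0("poly_col", seq_len(degree)))),
                   paste0(trait_names[2], ":",
                          c(paste0("poly_row", seq_len(degree)),
                            paste0("poly_col", seq_len(degree)))))

  out <- list(data = dat, X = X, m = m, layout = lay,
              trait_names = trait_names, n_dropped = n_dropped)
  class(out) <- "stacked_traits"
  out
}

# Data bundle for the bivariate likelihood evaluators.
biv_data <- function(stacked, structure) {
  lay <- stacked$layout
  m <- stacked$m
  cl <- factor(lay$clone_id)
  if (max(table(cl)) < 2) {
    stop("no clone has 2 or more ramets; clonal covariance is inestimable",
         call. = FALSE)
  }
  Z <- stats::model.matrix(~ 0 + cl)
  Cfun <- if (structure == "iid") {
    function(rr, rc) diag(m)
  } else {
    function(rr, rc) ar1xar1_correlation(lay$row, lay$col, rr, rc)
  }
  X <- stacked$X
  list(y = stacked$data$value, X = X, m = m, n = 2 * m, p = ncol(X),
       ZZt = tcrossprod(Z), Im = diag(m), Cfun = Cfun,
       ldXtX = as.numeric(determinant(crossprod(X))$modulus),
       structure = structure, trait_names = stacked$trait_names)
}

# Stacked covariance (or its scale-relative version) from natural-scale
# parameters. th: list(G11, G12, G22, su, s1, s2, rho1 = c(rr, rc), rho2).
biv_V <- function(th, dat) {
  m <- dat$m
  i1 <- seq_len(m); i2 <- m + i1
  V <- matrix(0, 2 * m, 2 * m)
  V[i1, i1] <- th$G11 * dat$ZZt + th$su * dat$Im +
    th$s1 * dat$Cfun(th$rho1[1], th$rho1[2])
  V[i2, i2] <- th$G22 * dat$ZZt + th$su * dat$Im +
    th$s2 * dat$Cfun(th$rho2[1], th$rho2[2])
  V[i1, i2] <- th$G12 * dat$ZZt + th$su * dat$Im
  V[i2, i1] <- t(V[i1, i2])
  V
}

# Unprofiled restricted log-likelihood at natural-scale parameters
# (theta named: G11, G12, G22, sigma2_u, sigma2_1, [rho_row_1, rho_col_1],
# sigma2_2, [rho_row_2, rho_col_2]).
biv_ll <- function(theta, dat) {
  ar1 <- dat$structure == "ar1xar1"
  th <- list(G11 = theta[["G11"]], G12 = theta[["G12"]],
             G22 = theta[["G22"]], su = theta[["sigma2_u"]],
             s1 = theta[["sigma2_1"]], s2 = theta[["sigma2_2"]],
             rho1 = if (ar1) c(theta[["rho_row_1"]], theta[["rho_col_1"]])
                    else c(0, 0),
             rho2 = if (ar1) c(theta[["rho_row_2"]], theta[["rho_col_2"]])
                    else c(0, 0))
  if (th$s1 <= 0 || th$s2 <= 0 || th$su < 0) return(-Inf)
  if (any(abs(c(th$rho1, th$rho2)) >= 1)) return(-Inf)
  restricted_ll(biv_V(th, dat), dat$y, dat$X, dat$ldXtX, profile = FALSE)
}

# Map the unconstrained optimizer vector to relative (profiled-scale)
# parameters. Cholesky parameterization of the relative G keeps it PSD.
biv_par_to_theta <- function(par, ar1, diagonal_G) {
  i <- 1
  L11 <- exp(min(max(par[i], -23), 23)); i <- i + 1
  L21 <- if (diagonal_G) 0 else { v <- par[i]; i <- i + 1; v }
  L22 <- exp(min(max(par[i], -23), 23)); i <- i + 1
  lu <- exp(min(max(par[i], -23), 23)); i <- i + 1
  l2 <- exp(min(max(par[i], -23), 23)); i <- i + 1
  rho1 <- c(0, 0); rho2 <- c(0, 0)
  if (ar1) {
    rho1 <- to_rho(par[i:(i + 1)]); i <- i + 2
    rho2 <- to_rho(par[i:(i + 1)])
  }
  list(G11 = L11^2, G12 = L11 * L21, G22 = L21^2 + L22^2,
       su = lu, l2 = l2, rho1 = rho1, rho2 = rho2)
}

biv_profiled_ll <- function(par, dat, ar1, diagonal_G, value_only = TRUE) {
  th <- biv_par_to_theta(par, ar1, diagonal_G)
  W <- biv_V(list(G11 = th$G11, G12 = th$G12, G22 = th$G22, su = th$su,
                  s1 = 1, s2 = th$l2, rho1 = th$rho1, rho2 = th$rho2), dat)
  restricted_ll(W, dat$y, dat$X, dat$ldXtX, profile = TRUE,
                value_only = value_only)
}

#' Fit the stacked bivariate mixed model by REML
#'
#' Maximizes the restricted likelihood over the unstructured 2x2 clonal
#' covariance (parameterized through its Cholesky factor, which enforces
#' positive semi-definiteness), the shared tree-level variance, and one
#' residual block per trait (variance plus, for `"ar1xar1"`, row/column
#' autocorrelations). Cross-trait dependence enters only through the clonal
#' covariance and the tree effect; residual blocks are trait-diagonal. The
#' overall scale is profiled out analytically; the optimizer probes starting
#' clonal correlations 0 and +/-0.6 and refines the best probe by
#' Nelder-Mead.
#'
#' @param stacked a `"stacked_traits"` object from [stack_bivariate()].
#' @param structure residual structure per trait block: `"iid"` or
#'   `"ar1xar1"`.
#' @param diagonal_G constrain the clonal covariance (the G off-diagonal) to
#'   zero — the null model of the genetic-correlation test.
#' @param compute_vcov compute the variance-parameter covariance matrix
#'   (numeric Hessian at the optimum).
#' @param control list: `maxit` (default 1500), `reltol` (default 1e-9).
#' @return object of class `"bivariate_lmm"`: `G` (2x2 clonal covariance,
#'   trait-named), `sigma2_u`, `resid` (per-trait residual parameters),
#'   `beta`, `loglik`, `vcov`, `converged`, `n_varpar`, plus the model
#'   internals.
#' @export
reml_fit_bivariate <- function(stacked, structure = c("ar1xar1", "iid"),
                               diagonal_G = FALSE, compute_vcov = TRUE,
                               control = list()) {
  structure <- match.arg(structure)
  if (!inherits(stacked, "stacked_traits")) {
    stop("'stacked' must come from stack_bivariate()", call. = FALSE)
  }
  maxit <- control$maxit %||% 1500L
  reltol <- control$reltol %||% 1e-9
  dat <- biv_data(stacked, structure)
  ar1 <- structure == "ar1xar1"
  m <- dat$m

  # common rescaling of both traits (model-preserving) for conditioning
  k <- stats::sd(dat$y)
  if (!is.finite(k) || k <= 0) k <- 1
  dat_s <- dat; dat_s$y <- dat$y / k

  # moment-based starting values on the scaled data
  y1 <- dat_s$y[seq_len(m)]; y2 <- dat_s$y[m + seq_len(m)]
  cl <- dat$ZZt %*% rep(1, m)  # ramet count per tree's clone
  start_comp <- function(yv) {
    cm <- tapply(yv, stacked$layout$clone_id, mean)
    wv <- stats::var(yv - cm[stacked$layout$clone_id])
    bv <- stats::var(cm)
    v <- stats::var(yv)
    g0 <- min(max(bv - wv / mean(table(stacked$layout$clone_id)), 0.05 * v),
              2 * v)
    c(g = g0, w = max(wv, 0.05 * v))
  }
  s1c <- start_comp(y1); s2c <- start_comp(y2)
  s0 <- s1c[["w"]]
  G10 <- s1c[["g"]] / s0; G20 <- s2c[["g"]] / s0
  l20 <- s2c[["w"]] / s0
  lu0 <- 0.1

  r0s <- if (diagonal_G) 0 else c(0, 0.6, -0.6)
  make_start <- function(r0) {
    L11 <- sqrt(G10)
    L21 <- r0 * sqrt(G20)
    L22 <- sqrt(max(G20 * (1 - r0^2), 1e-6))
    c(log(L11), if (!diagonal_G) L21, log(L22), log(lu0), log(l20),
      if (ar1) rep(0, 4))
  }
  starts <- lapply(r0s, make_start)
  probe <- vapply(starts, function(p) {
    biv_profiled_ll(p, dat_s, ar1, diagonal_G)
  }, numeric(1))
  par0 <- starts[[which.max(probe)]]

  fn <- function(p) -biv_profiled_ll(p, dat_s, ar1, diagonal_G)
  opt <- stats::optim(par0, fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  opt2 <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = reltol))
  if (opt2$value < opt$value) opt <- opt2
  converged <- opt$convergence == 0

  fin <- biv_profiled_ll(opt$par, dat_s, ar1, diagonal_G, value_only = FALSE)
  if (is.null(fin)) {
    stop("bivariate REML fit failed: likelihood undefined at the optimum",
         call. = FALSE)
  }
  th <- biv_par_to_theta(opt$par, ar1, diagonal_G)
  s <- fin$sigma2                     # profiled scale on scaled data
  scale2 <- k^2 * s                   # back to original units

  G <- matrix(scale2 * c(th$G11, th$G12, th$G12, th$G22), 2, 2,
              dimnames = list(dat$trait_names, dat$trait_names))
  sigma2_u <- scale2 * th$su
  resid <- data.frame(
    trait = dat$trait_names,
    sigma2 = c(scale2, scale2 * th$l2),
    rho_row = c(th$rho1[1], th$rho2[1]),
    rho_col = c(th$rho1[2], th$rho2[2]),
    stringsAsFactors = FALSE
  )

  par_names <- c("G11", if (!diagonal_G) "G12", "G22", "sigma2_u",
                 "sigma2_1", if (ar1) c("rho_row_1", "rho_col_1"),
                 "sigma2_2", if (ar1) c("rho_row_2", "rho_col_2"))
  theta_full <- c(G11 = G[1, 1], G12 = G[1, 2], G22 = G[2, 2],
                  sigma2_u = sigma2_u,
                  sigma2_1 = resid$sigma2[1],
                  rho_row_1 = resid$rho_row[1], rho_col_1 = resid$rho_col[1],
                  sigma2_2 = resid$sigma2[2],
                  rho_row_2 = resid$rho_row[2], rho_col_2 = resid$rho_col[2])

  # report the restricted log-likelihood on the original data scale
  loglik <- biv_ll(theta_full, dat)

  vcov <- matrix(NA_real_, length(par_names), length(par_names),
                 dimnames = list(par_names, par_names))
  if (compute_vcov) {
    llfun <- function(v) {
      th2 <- theta_full
      th2[par_names] <- v
      if (diagonal_G) th2[["G12"]] <- 0
      biv_ll(th2, dat)
    }
    H <- num_hessian(llfun, theta_full[par_names],
                     floor = 0.01 * max(scale2, 1e-8))
    vcov <- vcov_from_hessian(H, par_names)
  }

  beta <- stats::setNames(k * fin$beta, colnames(stacked$X))

  out <- list(G = G, sigma2_u = sigma2_u, resid = resid,
              beta = beta, loglik = loglik, vcov = vcov,
              converged = converged, structure = structure,
              diagonal_G = diagonal_G,
              n = dat$n, m = m, p = dat$p,
              n_varpar = length(par_names),
              trait_names = dat$trait_names,
              stacked = stacked, call = match.call())
  class(out) <- "bivariate_lmm"
  out
}

#' @export
print.bivariate_lmm <- function(x, ...) {
  cat("Stacked bivariate mixed model (REML)\n")
  cat("  traits:", paste(x$trait_names, collapse = " / "),
      " residual structure:", x$structure, "\n")
  cat("  clonal covariance G:\n")
  print(round(x$G, 5))
  cat(sprintf("  sigma2_u = %.4g, REML log-likelihood = %.4f\n",
              x$sigma2_u, x$loglik))
  invisible(x)
}

#' @export
logLik.bivariate_lmm <- function(object, ...) {
  structure(object$loglik, df = object$n_varpar, class = "logLik")
}

#' Delta-method standard error of a genetic correlation
#'
#' First-order propagation of the covariance of the clonal (co)variance
#' estimates `(G11, G12, G22)` through
#' \eqn{r_g = G_{12}/\sqrt{G_{11} G_{22}}}: the gradient is
#' \eqn{(-r_g/2G_{11},\; 1/\sqrt{G_{11}G_{22}},\; -r_g/2G_{22})}.
#'
#' @param G 2x2 clonal covariance matrix.
#' @param vcov3 3x3 covariance of `(G11, G12, G22)` in that order.
#' @return the standard error (NA when the quadratic form is not finite).
#' @examples
#' rg_delta_se(diag(2), diag(0.01, 3))  # 0.1
#' @export
rg_delta_se <- function(G, vcov3) {
  G11 <- G[1, 1]; G12 <- G[1, 2]; G22 <- G[2, 2]
  r <- G12 / sqrt(G11 * G22)
  g <- c(-r / (2 * G11), 1 / sqrt(G11 * G22), -r / (2 * G22))
  v <- drop(t(g) %*% vcov3 %*% g)
  if (!is.finite(v) || v < 0) return(NA_real_)
  sqrt(v)
}

#' Genetic correlation from a bivariate fit
#'
#' Computes \eqn{r_g = G_{12}/\sqrt{G_{11} G_{22}}} with a delta-method SE
#' from the fit's variance-parameter covariance. Estimates with
#' \eqn{|r_g| > 0.999} are clamped to \eqn{\pm 0.999} and flagged `"B"`
#' (parameter at the boundary; no SE is reported there, following the
#' reporting convention of clonal-trial studies). Significance is a 1-df
#' likelihood-ratio test against the fit with the G off-diagonal fixed at
#' zero (an interior null).
#'
#' @param fit a `"bivariate_lmm"` fit with unconstrained G.
#' @param reduced optional matching fit with `diagonal_G = TRUE`; when
#'   `test = TRUE` and `reduced` is missing it is fitted internally.
#' @param test compute the likelihood-ratio p-value for `r_g = 0`.
#' @return object of class `"genetic_correlation"`: list with `r_g`, `SE`,
#'   `flag` (`"B"` or `""`), `p_value`, `G`.
#' @export
genetic_correlation <- function(fit, reduced = NULL, test = !is.null(reduced)) {
  if (fit$diagonal_G) {
    stop("fit has a diagonal G; refit with diagonal_G = FALSE", call. = FALSE)
  }
  G11 <- fit$G[1, 1]; G22 <- fit$G[2, 2]; G12 <- fit$G[1, 2]
  tol <- 1e-8 * (G11 + G22 + sum(fit$resid$sigma2))
  if (G11 <= tol || G22 <= tol) {
    stop("zero clonal variance in at least one trait; genetic correlation ",
         "is undefined", call. = FALSE)
  }
  r <- G12 / sqrt(G11 * G22)
  flag <- ""
  se <- NA_real_
  if (abs(r) > 0.999) {
    r <- sign(r) * 0.999
    flag <- "B"
  } else {
    gn <- c("G11", "G12", "G22")
    if (all(gn %in% rownames(fit$vcov)) && !anyNA(fit$vcov[gn, gn])) {
      se <- rg_delta_se(fit$G, fit$vcov[gn, gn])
    }
  }
  p <- NA_real_
  if (test) {
    if (is.null(reduced)) {
      reduced <- reml_fit_bivariate(fit$stacked, structure = fit$structure,
                                    diagonal_G = TRUE, compute_vcov = FALSE)
    }
    stat <- max(0, 2 * (fit$loglik - reduced$loglik))
    p <- if (stat <= 0) 1 else stats::pchisq(stat, 1, lower.tail = FALSE)
  }
  out <- list(r_g = r, SE = se, flag = flag, p_value = p, G = fit$G,
              trait_names = fit$trait_names)
  class(out) <- "genetic_correlation"
  out
}

#' @export
print.genetic_correlation <- function(x, ...) {
  cat(sprintf("r_g(%s, %s) = %.3f", x$trait_names[1], x$trait_names[2],
              x$r_g))
  if (x$flag == "B") cat(" [B: boundary]")
  else if (!is.na(x$SE)) cat(sprintf(" (SE %.3f)", x$SE))
  if (!is.na(x$p_value)) cat(sprintf(", LRT p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}
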