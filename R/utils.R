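# Internal helpers shared across modules.

# Run code with a temporary RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards so simulation functions are
# deterministic without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Symmetric PSD check with tolerance relative to the largest eigenvalue.
check_covariance <- function(G, name = "G") {
  if (!is.matrix(G) || nrow(G) != ncol(G)) {
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  }
  if (max(abs(G - t(G))) > 1e-8 * max(1, max(abs(G)))) {
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  }
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev)))) {
    stop(sprintf("'%s' must be positive semi-definite", name), call. = FALSE)
  }
  invisible(TRUE)
}

# Matrix square root of a PSD matrix (eigen-based so semi-definite G,
# including the zero matrix, is handled).
psd_sqrt <- function(G) {
  e <- eigen(G, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

check_rho <- function(rho, name = "rho") {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || abs(rho) >= 1) {
    stop(sprintf("'%s' must satisfy |%s| < 1", name, name), call. = FALSE)
  }
  invisible(TRUE)
}

check_layout <- function(layout) {
  need <- c("row", "col", "tree_id", "clone_id")
  miss <- setdiff(need, names(layout))
  if (length(miss)) {
    stop("layout is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(layout[, c("row", "col")])) {
    stop("layout has duplicated (row, col) positions", call. = FALSE)
  }
  if (anyDuplicated(layout$tree_id)) {
    stop("layout has duplicated tree ids", call. = FALSE)
  }
  invisible(TRUE)
}

# Central-difference Hessian; steps are 1e-4 * max(|x|, floor) per coordinate.
# `f` must be finite at the evaluation points or NA is propagated.
num_hessian <- function(f, x, floor = 0.01, rel = 1e-4) {
  k <- length(x)
  h <- rel * pmax(abs(x), floor)
  H <- matrix(NA_real_, k, k)
  fx <- function(z) {
    v <- tryCatch(f(z), error = function(e) NA_real_)
    if (!is.finite(v)) NA_real_ else v
  }
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    for (j in i:k) {
      ej <- replace(numeric(k), j, h[j])
      if (i == j) {
        H[i, i] <- (fx(x + ei) - 2 * fx(x) + fx(x - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (fx(x + ei + ej) - fx(x + ei - ej) -
             fx(x - ei + ej) + fx(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

# Variance-covariance of variance parameters from the negative inverse
# Hessian of the REML log-likelihood; NA matrix when inversion fails.
vcov_from_hessian <- function(H, names) {
  k <- nrow(H)
  V <- matrix(NA_real_, k, k, dimnames = list(names, names))
  if (!anyNA(H)) {
    Vi <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(Vi)) {
      Vi <- (Vi + t(Vi)) / 2
      dimnames(Vi) <- list(names, names)
      V <- Vi
    }
  }
  V
}

`%||%` <- function(a, b) if (is.null(a)) b else a
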