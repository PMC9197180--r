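# Wavelength-wise and index-wise analyses: seasonal paired t-scans, Fisher's
# LSD group comparisons, Pearson correlation scans, heritability and
# genetic-correlation scans, and contiguous significant-region extraction.

#' Paired t-test scan across wavelengths
#'
#' Per wavelength, a paired t-test on the within-tree differences between two
#' samplings (e.g. May vs August spectra of the same trees). Trees present in
#' only one sampling are dropped with a message. Zero-variance differences
#' give p = 1 with a degenerate flag rather than an error.
#'
#' @param spectra1,spectra2 spectra matrices on a common grid, rownames =
#'   tree ids.
#' @return `data.frame` per wavelength: `wavelength`, `mean_diff`
#'   (sampling 1 minus sampling 2), `t`, `df`, `p`, `degenerate`.
#' @export
paired_t_scan <- function(spectra1, spectra2) {
  common <- intersect(rownames(spectra1), rownames(spectra2))
  dropped <- length(union(rownames(spectra1), rownames(spectra2))) -
    length(common)
  if (dropped > 0) message(dropped, " unmatched trees dropped")
  if (length(common) < 3) {
    stop("need at least 3 matched trees for the paired t-scan", call. = FALSE)
  }
  if (!identical(colnames(spectra1), colnames(spectra2))) {
    stop("spectra are not on a common wavelength grid", call. = FALSE)
  }
  d <- spectra1[common, , drop = FALSE] - spectra2[common, , drop = FALSE]
  n <- length(common)
  md <- colMeans(d)
  sdd <- apply(d, 2, stats::sd)
  degenerate <- sdd == 0
  tt <- ifelse(degenerate, 0, md / (sdd / sqrt(n)))
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(tt), df = n - 1))
  data.frame(wavelength = as.numeric(colnames(d)), mean_diff = unname(md),
             t = unname(tt), df = n - 1, p = unname(p),
             degenerate = unname(degenerate), row.names = NULL)
}

#' Fisher's LSD pairwise comparisons
#'
#' One-way pooled-variance pairwise t-tests (least significant difference;
#' p-values unadjusted). The pooled mean square error comes from the one-way
#' within-group sum of squares with `N - k` degrees of freedom. A zero pooled
#' MSE flags all comparisons degenerate (difference reported, p = NA).
#'
#' @param values numeric trait values.
#' @param groups group labels (e.g. ecotypes), aligned with `values`.
#' @return `data.frame`, one row per unordered group pair: `group1`,
#'   `group2`, `diff` (mean of group1 minus group2), `se`, `t`, `df`, `p`,
#'   `degenerate`.
#' @export
lsd_compare <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(as.character(groups[keep]))
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("every group needs n >= 2 (got ",
         paste(names(sizes)[sizes < 2], collapse = ", "), ")", call. = FALSE)
  }
  k <- length(sizes); N <- length(values)
  means <- tapply(values, groups, mean)
  ss_within <- sum(tapply(values, groups,
                          function(v) sum((v - mean(v))^2)))
  df <- N - k
  mse <- ss_within / df
  pairs <- utils::combn(names(sizes), 2)
  out <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ], stringsAsFactors = FALSE
  )
  out$diff <- means[out$group1] - means[out$group2]
  out$se <- sqrt(mse * (1 / sizes[out$group1] + 1 / sizes[out$group2]))
  degenerate <- mse == 0
  out$t <- if (degenerate) NA_real_ else out$diff / out$se
  out$df <- df
  out$p <- if (degenerate) NA_real_ else 2 * stats::pt(-abs(out$t), df)
  out$degenerate <- degenerate
  rownames(out) <- NULL
  out
}

#' Pearson correlation scan
#'
#' Pearson correlation of a trait against every column of a matrix
#' (wavelengths of a spectra matrix, or vegetation-index columns), with the
#' large-sample standard error `sqrt((1 - r^2)/(n - 2))` and the two-sided
#' p-value from `t = r * sqrt((n - 2)/(1 - r^2))`. Constant columns are
#' flagged undefined (`NA`), not fatal.
#'
#' @param x numeric matrix or data.frame of columns to scan (non-numeric
#'   columns such as `tree_id` are ignored).
#' @param trait numeric trait vector aligned with the rows of `x`.
#' @return `data.frame` per column: `column`, `r`, `se`, `t`, `p`, `n`,
#'   `undefined`.
#' @export
pearson_scan <- function(x, trait) {
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    x <- as.matrix(x[, num, drop = FALSE])
  }
  if (nrow(x) != length(trait)) {
    stop("'trait' must align with the rows of 'x'", call. = FALSE)
  }
  cols <- colnames(x) %||% as.character(seq_len(ncol(x)))
  res <- lapply(seq_len(ncol(x)), function(j) {
    ok <- is.finite(x[, j]) & is.finite(trait)
    n <- sum(ok)
    if (n < 3) {
      return(data.frame(column = cols[j], r = NA_real_, se = NA_real_,
                        t = NA_real_, p = NA_real_, n = n, undefined = TRUE))
    }
    xv <- x[ok, j]; tv <- trait[ok]
    if (stats::sd(xv) == 0 || stats::sd(tv) == 0) {
      return(data.frame(column = cols[j], r = NA_real_, se = NA_real_,
                        t = NA_real_, p = NA_real_, n = n, undefined = TRUE))
    }
    r <- stats::cor(xv, tv)
    se <- sqrt((1 - r^2) / (n - 2))
    tt <- if (abs(r) >= 1) Inf * sign(r) else r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    data.frame(column = cols[j], r = r, se = se, t = tt, p = p, n = n,
               undefined = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Heritability scan over columns
#'
#' Runs the univariate spatial REML fit and [heritability()] on every column
#' (wavelength or vegetation index), flagging columns whose clone-variance
#' likelihood-ratio p-value falls below `alpha` as heritable (the
#' pre-selection rule for the downstream genetic-correlation analysis).
#' Per-column failures are recorded, not fatal.
#'
#' @param x numeric matrix/data.frame of responses (columns scanned).
#' @param layout trial layout aligned with the rows of `x`.
#' @param structure residual structure passed to [reml_fit()].
#' @param alpha selection level for the heritable flag.
#' @param ... further arguments to [reml_fit()].
#' @return `data.frame` per column: `column`, `H2`, `SE`, `p_value`,
#'   `sigma2_c`, `sigma2`, `heritable`, `error` (message or `NA`).
#' @export
heritability_scan <- function(x, layout, structure = "ar1xar1", alpha = 0.05,
                              ...) {
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    x <- as.matrix(x[, num, drop = FALSE])
  }
  cols <- colnames(x) %||% as.character(seq_len(ncol(x)))
  res <- lapply(seq_len(ncol(x)), function(j) {
    est <- tryCatch({
      full <- reml_fit(x[, j], layout, structure = structure, ...)
      red <- reml_fit(x[, j], layout, structure = structure,
                      include_clone = FALSE, compute_vcov = FALSE, ...)
      h <- heritability(full, reduced = red)
      data.frame(column = cols[j], H2 = h$H2, SE = h$SE,
                 p_value = h$p_value, sigma2_c = h$sigma2_c,
                 sigma2 = h$sigma2, heritable = h$p_value < alpha,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(column = cols[j], H2 = NA_real_, SE = NA_real_,
                 p_value = NA_real_, sigma2_c = NA_real_, sigma2 = NA_real_,
                 heritable = NA, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    est
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Genetic-correlation scan over columns
#'
#' Runs the stacked bivariate REML fit and [genetic_correlation()] of a trait
#' against every column (wavelength or index). Per-column failures (e.g.
#' zero clonal variance) are recorded, not fatal.
#'
#' @param x numeric matrix/data.frame of columns to scan.
#' @param trait numeric trait vector aligned with the rows of `x`.
#' @param layout trial layout aligned with the rows of `x`.
#' @param structure residual structure passed to [reml_fit_bivariate()].
#' @param test compute the 1-df likelihood-ratio p-value per column (doubles
#'   the fitting cost).
#' @param ... further arguments to [reml_fit_bivariate()].
#' @return `data.frame` per column: `column`, `r_g`, `SE`, `flag`,
#'   `p_value`, `error`.
#' @export
gcorr_scan <- function(x, trait, layout, structure = "ar1xar1", test = FALSE,
                       ...) {
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    x <- as.matrix(x[, num, drop = FALSE])
  }
  cols <- colnames(x) %||% as.character(seq_len(ncol(x)))
  res <- lapply(seq_len(ncol(x)), function(j) {
    tryCatch({
      st <- stack_bivariate(trait, x[, j], layout,
                            trait_names = c("trait", "column"))
      fit <- reml_fit_bivariate(st, structure = structure, ...)
      gc <- genetic_correlation(fit, test = test)
      data.frame(column = cols[j], r_g = gc$r_g, SE = gc$SE, flag = gc$flag,
                 p_value = gc$p_value, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(column = cols[j], r_g = NA_real_, SE = NA_real_,
                 flag = NA_character_, p_value = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Contiguous significant wavelength regions
#'
#' Extracts the maximal runs of consecutive grid wavelengths with `p < alpha`
#' as inclusive intervals; the union of the intervals reproduces exactly the
#' set of significant wavelengths.
#'
#' @param pvalues numeric p-values aligned with `grid`.
#' @param grid wavelength grid (nm), strictly increasing and contiguous at
#'   the grid step.
#' @param alpha significance level.
#' @return `data.frame` with columns `alpha`, `start_nm`, `end_nm`, sorted
#'   and disjoint (zero rows when nothing is significant).
#' @examples
#' p <- rep(1, 10)
#' p[3:5] <- 0.01
#' significant_regions(p, 350:359)
#' @export
significant_regions <- function(pvalues, grid, alpha = 0.05) {
  if (length(pvalues) != length(grid)) {
    stop("'pvalues' and 'grid' lengths disagree", call. = FALSE)
  }
  sig <- !is.na(pvalues) & pvalues < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(alpha = rep(alpha, sum(keep)),
             start_nm = grid[starts[keep]],
             end_nm = grid[ends[keep]],
             row.names = NULL)
}
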