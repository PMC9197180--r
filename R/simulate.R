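# Synthetic clonal-trial generator: genetic values, spatial surfaces,
# trait tables, and trait-linked reflectance spectra with known truth.

#' Simulate clone genetic values
#'
#' Draws one multivariate-normal vector of genetic effects per clone,
#' independent across clones, with trait covariance `G` (the generative
#' counterpart of the clonal (co)variance the mixed models estimate).
#'
#' @param clone_ids character vector of clone identifiers.
#' @param G trait-by-trait genetic covariance matrix (symmetric PSD; the
#'   zero matrix is allowed and yields all-zero effects).
#' @param seed RNG seed.
#' @return matrix of genetic values, `length(clone_ids)` rows (named by
#'   clone) by `ncol(G)` trait columns.
#' @examples
#' g <- simulate_genetic_values(c("C1", "C2"), diag(2) * 0.4, seed = 1)
#' @export
simulate_genetic_values <- function(clone_ids, G, seed = NULL) {
  if (is.null(dim(G))) G <- matrix(G, 1, 1)
  check_covariance(G, "G")
  q <- length(clone_ids); k <- ncol(G)
  with_seed(seed, {
    Zstd <- matrix(stats::rnorm(q * k), q, k)
    vals <- Zstd %*% psd_sqrt(G)
    dimnames(vals) <- list(clone_ids, colnames(G))
    vals
  })
}

# AR1xAR1 correlation between observed positions: entry (i, j) is
# rho_row^|r_i - r_j| * rho_col^|c_i - c_j| — the observed-tree submatrix of
# the full Kronecker correlation, built directly from coordinates.
ar1xar1_correlation <- function(rows, cols, rho_row, rho_col) {
  dr <- abs(outer(rows, rows, "-"))
  dc <- abs(outer(cols, cols, "-"))
  (rho_row^dr) * (rho_col^dc)
}

#' Simulate a spatial surface over trial positions
#'
#' Generates, for each occupied position, a smooth second-order polynomial
#' trend in the (centered) row and column indices plus zero-mean Gaussian
#' microsite noise whose covariance between positions \eqn{(r_1,c_1)} and
#' \eqn{(r_2,c_2)} is
#' \eqn{\sigma^2 \rho_{row}^{|r_1-r_2|} \rho_{col}^{|c_1-c_2|}} (separable
#' AR1xAR1).
#'
#' @param layout trial layout (see [simulate_layout()]).
#' @param rho_row,rho_col autoregressive correlations in rows/columns,
#'   `|rho| < 1`.
#' @param sigma2 marginal noise variance (> 0, or 0 for a noiseless trend).
#' @param trend named numeric vector of polynomial coefficients
#'   `c(row, row2, col, col2)` applied to centered indices; missing names
#'   default to 0.
#' @param seed RNG seed.
#' @return numeric vector of surface values aligned with `layout` rows.
#' @export
simulate_spatial_surface <- function(layout, rho_row = 0, rho_col = 0,
                                     sigma2 = 1,
                                     trend = c(row = 0, row2 = 0,
                                               col = 0, col2 = 0),
                                     seed = NULL) {
  check_layout(layout)
  check_rho(rho_row, "rho_row"); check_rho(rho_col, "rho_col")
  if (sigma2 < 0) stop("'sigma2' must be >= 0", call. = FALSE)
  tr <- c(row = 0, row2 = 0, col = 0, col2 = 0)
  tr[names(trend)] <- trend
  r <- layout$row - mean(layout$row)
  cc <- layout$col - mean(layout$col)
  mu <- tr["row"] * r + tr["row2"] * r^2 + tr["col"] * cc + tr["col2"] * cc^2
  n <- nrow(layout)
  with_seed(seed, {
    noise <- numeric(n)
    if (sigma2 > 0) {
      C <- ar1xar1_correlation(layout$row, layout$col, rho_row, rho_col)
      U <- chol(C)
      noise <- sqrt(sigma2) * drop(crossprod(U, stats::rnorm(n)))
    }
    unname(mu + noise)
  })
}

#' Assemble a per-tree trait table
#'
#' Each tree's value for a trait is `mean + clone genetic value + spatial
#' surface (trend + microsite noise)`, i.e. the generative counterpart of the
#' mixed model `y = 1*mu + X*beta + Z*c + e`. Optional ecotype effects add a
#' clone-level mean shift per trait.
#'
#' @param layout trial layout.
#' @param genetic_values clone-by-trait matrix (rownames = clone ids), as from
#'   [simulate_genetic_values()].
#' @param surfaces matrix of spatial surface values, one row per tree in
#'   layout order and one column per trait (a vector is accepted for a single
#'   trait).
#' @param means named numeric vector of trait means (names define the trait
#'   registry and must match `colnames(genetic_values)`).
#' @param ecotype_effects optional ecotype-by-trait matrix of mean shifts
#'   (rownames = ecotype labels).
#' @param month sampling-month tag stamped on the table.
#' @return `data.frame` with tree metadata columns (`tree_id`, `clone_id`,
#'   `ecotype`, `row`, `col`, `month`) followed by one column per trait.
#' @export
simulate_traits <- function(layout, genetic_values, surfaces, means,
                            ecotype_effects = NULL, month = "august") {
  check_layout(layout)
  if (is.null(dim(surfaces))) surfaces <- matrix(surfaces, ncol = 1)
  traits <- names(means)
  if (is.null(traits)) stop("'means' must be named by trait", call. = FALSE)
  if (!identical(sort(colnames(genetic_values)), sort(traits))) {
    stop("trait names of 'genetic_values' and 'means' disagree", call. = FALSE)
  }
  if (nrow(surfaces) != nrow(layout) || ncol(surfaces) != length(traits)) {
    stop("'surfaces' must be n_trees x n_traits", call. = FALSE)
  }
  if (is.null(colnames(surfaces))) colnames(surfaces) <- traits
  miss <- setdiff(layout$clone_id, rownames(genetic_values))
  if (length(miss)) {
    stop("genetic values missing for clones: ",
         paste(utils::head(miss), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    tree_id = layout$tree_id, clone_id = layout$clone_id,
    ecotype = layout$ecotype, row = layout$row, col = layout$col,
    month = month, stringsAsFactors = FALSE
  )
  for (tr in traits) {
    val <- means[[tr]] + genetic_values[layout$clone_id, tr] + surfaces[, tr]
    if (!is.null(ecotype_effects) && tr %in% colnames(ecotype_effects)) {
      val <- val + ecotype_effects[layout$ecotype, tr]
    }
    out[[tr]] <- unname(val)
  }
  out
}

#' Default spectral link coefficients
#'
#' Depths (reflectance units) of the Gaussian absorption features per unit of
#' the linked variable: `chlorophyll` scales dips at 680 and 550 nm per
#' mg g^-1 total chlorophyll; `water` scales dips at 970/1,200/1,450/1,930 nm
#' per unit latent water; `structure` raises the 760--1,300 nm NIR plateau
#' per unit latent structure.
#'
#' @return named list of link coefficients.
#' @export
spectral_links <- function() {
  list(chlorophyll = 0.008, water = 0.12, structure = 0.05)
}

# Vegetation-like baseline reflectance: low VIS with a green bump, logistic
# red-edge rise to a NIR plateau, smooth SWIR decay.
baseline_reflectance <- function(wl) {
  0.05 +
    0.03 * exp(-((wl - 550)^2) / (2 * 30^2)) +
    0.40 * stats::plogis((wl - 715) / 15) -
    0.18 * stats::plogis((wl - 1450) / 220)
}

#' Simulate reflectance spectra from a trait table
#'
#' Builds each tree's spectrum as a shared vegetation-like baseline minus
#' Gaussian absorption features whose depths increase in the tree's trait
#' values: chlorophyll absorption at 680 nm (and a weaker green-region dip at
#' 550 nm) driven by total chlorophyll (`chl_a + chl_b`, or a `chl` column),
#' water absorption at 970, 1,200, 1,450 and 1,930 nm driven by a latent
#' `water` column, and the 760--1,300 nm NIR plateau raised by a latent
#' `structure` column. Values are clipped to [0, 1].
#'
#' @param traits trait table (see [simulate_traits()]); `water`/`structure`
#'   columns default to 0 when absent.
#' @param links named list of link coefficients (see [spectral_links()]).
#' @param noise_sd standard deviation of additive iid measurement noise.
#' @param wavelengths integer wavelength grid in nm.
#' @param seed RNG seed.
#' @return spectra matrix (class `"spectra"`): one row per tree (rownames =
#'   tree ids), one column per wavelength.
#' @export
simulate_spectra <- function(traits, links = spectral_links(), noise_sd = 0,
                             wavelengths = 350:2500, seed = NULL) {
  chl <- if (all(c("chl_a", "chl_b") %in% names(traits))) {
    traits$chl_a + traits$chl_b
  } else if ("chl" %in% names(traits)) {
    traits$chl
  } else {
    stop("trait table must contain 'chl_a' + 'chl_b' (or 'chl') columns",
         call. = FALSE)
  }
  water <- traits$water %||% rep(0, nrow(traits))
  structure <- traits$structure %||% rep(0, nrow(traits))
  wl <- as.numeric(wavelengths)
  n <- nrow(traits)

  base <- baseline_reflectance(wl)
  dip680 <- exp(-((wl - 680)^2) / (2 * 30^2))
  dip550 <- 0.6 * exp(-((wl - 550)^2) / (2 * 25^2))
  water_dip <- 0.30 * exp(-((wl - 970)^2)  / (2 * 40^2)) +
               0.40 * exp(-((wl - 1200)^2) / (2 * 45^2)) +
               1.00 * exp(-((wl - 1450)^2) / (2 * 60^2)) +
               1.00 * exp(-((wl - 1930)^2) / (2 * 70^2))
  nir_win <- stats::plogis((wl - 755) / 10) * (1 - stats::plogis((wl - 1305) / 40))

  spec <- matrix(rep(base, each = n), n, length(wl)) -
    links$chlorophyll * outer(chl, dip680 + dip550) -
    links$water * outer(water, water_dip) +
    links$structure * outer(structure, nir_win)

  with_seed(seed, {
    if (noise_sd > 0) {
      spec <- spec + matrix(stats::rnorm(length(spec), sd = noise_sd),
                            nrow = n)
    }
    spec[spec < 0] <- 0
    spec[spec > 1] <- 1
    dimnames(spec) <- list(traits$tree_id, as.character(wavelengths))
    class(spec) <- c("spectra", "matrix")
    spec
  })
}

#' Default trait registry for the trial generator
#'
#' Trait means and variance components emulate a mature Norway-spruce clone
#' bank: growth traits (`dbh` cm, `height` m, crown height `hc` m, crown
#' length `lc` m), pigments (`chl_a`, `chl_b`, `car` in mg g^-1 dry mass) and
#' latent `water`/`structure` drivers of the spectra. Broad-sense heritability
#' is `sigma2_c / (sigma2_c + sigma2)` per trait (0.4 by default).
#'
#' @return `data.frame` with columns `trait`, `mean`, `sigma2_c`, `sigma2`.
#' @export
default_trait_registry <- function() {
  data.frame(
    trait    = c("dbh", "height", "hc", "lc", "chl_a", "chl_b", "car",
                 "water", "structure"),
    mean     = c(33.1, 20.6, 8.6, 11.0, 3.1, 1.1, 0.57, 1.0, 1.0),
    sigma2_c = c(24.0, 3.5, 1.6, 2.4, 0.26, 0.040, 0.0090, 0.016, 0.016),
    sigma2   = c(36.0, 5.2, 2.4, 3.6, 0.39, 0.060, 0.0135, 0.024, 0.024),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete clonal trial with known truth
#'
#' End-to-end wrapper: layout, clone genetic values (with a common genetic
#' correlation among traits), per-trait spatial surfaces sharing the trial's
#' AR1xAR1 microsite field parameters, the trait table, and reflectance
#' spectra linked to the simulated pigments and latent water/structure.
#'
#' @param n_rows,n_cols,n_clones,ramets_per_clone,arrangement layout
#'   parameters (see [simulate_layout()]).
#' @param registry trait registry (see [default_trait_registry()]).
#' @param genetic_cor common genetic correlation between every trait pair
#'   (defaults to 0.5, a moderately pleiotropic architecture).
#' @param rho_row,rho_col spatial autocorrelations of the microsite noise.
#' @param trend second-order spatial trend coefficients (see
#'   [simulate_spatial_surface()]); the same relative trend is applied to each
#'   trait scaled by its residual SD.
#' @param ecotype_effects optional ecotype-by-trait mean-shift matrix.
#' @param noise_sd spectral measurement noise SD.
#' @param seed RNG seed (drives every stage).
#' @return list with elements `layout`, `genetic_values`, `traits`, `spectra`
#'   and `truth` (the generating parameters).
#' @examples
#' trial <- simulate_trial(seed = 42)
#' str(trial$traits)
#' @export
simulate_trial <- function(n_rows = 10, n_cols = 10, n_clones = 30,
                           ramets_per_clone = 3,
                           arrangement = "random",
                           registry = default_trait_registry(),
                           genetic_cor = 0.5,
                           rho_row = 0.5, rho_col = 0.5,
                           trend = c(row = 0.1, row2 = -0.02,
                                     col = 0.05, col2 = 0),
                           ecotype_effects = NULL,
                           noise_sd = 0.002,
                           seed = NULL) {
  k <- nrow(registry)
  R <- matrix(genetic_cor, k, k); diag(R) <- 1
  sdg <- sqrt(registry$sigma2_c)
  G <- diag(sdg, k) %*% R %*% diag(sdg, k)
  dimnames(G) <- list(registry$trait, registry$trait)

  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, 3 + k)
    layout <- simulate_layout(n_rows, n_cols, n_clones, ramets_per_clone,
                              arrangement = arrangement, seed = seeds[1])
    gv <- simulate_genetic_values(unique(layout$clone_id), G, seed = seeds[2])
    surfaces <- sapply(seq_len(k), function(j) {
      simulate_spatial_surface(
        layout, rho_row, rho_col, sigma2 = registry$sigma2[j],
        trend = trend * sqrt(registry$sigma2[j]),
        seed = seeds[3 + j])
    })
    colnames(surfaces) <- registry$trait
    means <- stats::setNames(registry$mean, registry$trait)
    traits <- simulate_traits(layout, gv, surfaces, means,
                              ecotype_effects = ecotype_effects)
    spectra <- simulate_spectra(traits, noise_sd = noise_sd, seed = seeds[3])
    list(layout = layout, genetic_values = gv, traits = traits,
         spectra = spectra,
         truth = list(G = G, registry = registry, rho_row = rho_row,
                      rho_col = rho_col, trend = trend,
                      genetic_cor = genetic_cor, seed = seed))
  })
}

#' Read or write a trait table CSV
#'
#' @param file path to a CSV file.
#' @param traits trait table as from [simulate_traits()].
#' @return `read_traits()` returns the trait `data.frame`; `write_traits()`
#'   returns `file` invisibly.
#' @export
read_traits <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' @rdname read_traits
#' @export
write_traits <- function(traits, file) {
  utils::write.csv(traits, file, row.names = FALSE)
  invisible(file)
}
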