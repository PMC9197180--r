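# Spectral data model, scan aggregation, vegetation indices.

#' Coerce to a spectra matrix
#'
#' A spectra matrix holds one bidirectional reflectance factor (BRF) spectrum
#' per row: rownames are tree (sample) ids and column names are integer
#' wavelengths in nm on a strictly increasing grid. Reflectance stored in
#' percent (detected when the maximum exceeds 1.5) is divided by 100 with a
#' warning; values outside [0, 1.1] after that raise a warning.
#'
#' @param x numeric matrix or data.frame; if the first column is non-numeric
#'   it is taken as the tree id.
#' @return a matrix of class `"spectra"`.
#' @export
as_spectra <- function(x) {
  if (is.data.frame(x)) {
    if (!is.numeric(x[[1]])) {
      ids <- as.character(x[[1]])
      x <- as.matrix(x[, -1, drop = FALSE])
      rownames(x) <- ids
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.numeric(x)) stop("spectra must be numeric", call. = FALSE)
  wl <- suppressWarnings(as.numeric(colnames(x)))
  if (anyNA(wl)) stop("column names must be numeric wavelengths (nm)",
                      call. = FALSE)
  if (any(diff(wl) <= 0)) stop("wavelength grid must be strictly increasing",
                               call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("spectra contain non-finite values", call. = FALSE)
  }
  if (max(x) > 1.5) {
    warning("spectra look like percent reflectance; dividing by 100")
    x <- x / 100
  }
  if (min(x) < 0 || max(x) > 1.1) {
    warning("reflectance values outside [0, 1.1]")
  }
  class(x) <- c("spectra", "matrix")
  x
}

#' Wavelengths of a spectra matrix
#' @param spectra a spectra matrix.
#' @return numeric vector of wavelengths (nm).
#' @export
wavelengths <- function(spectra) as.numeric(colnames(spectra))

#' Median spectrum over repeated scans
#'
#' Aggregates repeated scans of one sample into a single spectrum by taking
#' the per-wavelength median (the midpoint of the two central order statistics
#' for even scan counts).
#'
#' @param scans matrix of scans (rows) by wavelengths, or a list of equal-grid
#'   numeric vectors.
#' @return named numeric vector: the median spectrum on the common grid.
#' @export
median_spectrum <- function(scans) {
  if (is.list(scans) && !is.data.frame(scans)) {
    grids <- lapply(scans, names)
    if (length(unique(vapply(grids, paste, "", collapse = ","))) != 1L) {
      stop("scans are not on a common wavelength grid", call. = FALSE)
    }
    scans <- do.call(rbind, scans)
  }
  scans <- as.matrix(scans)
  if (nrow(scans) < 1L) stop("need at least one scan", call. = FALSE)
  out <- apply(scans, 2, stats::median)
  names(out) <- colnames(scans)
  out
}

# Index registry. The "paper" dialect holds the formulas exactly as printed
# in the source study's index table; "canonical" swaps in the literature
# definition where it differs (CRI2 as a reciprocal-reflectance difference).
index_registry <- function(dialect = c("paper", "canonical")) {
  dialect <- match.arg(dialect)
  reg <- list(
    CRI2   = list(wl = c(760, 700),
                  fun = function(R) R[["760"]] / R[["700"]] - 1),
    DWSI4  = list(wl = c(550, 680),
                  fun = function(R) R[["550"]] / R[["680"]]),
    GI     = list(wl = c(554, 677),
                  fun = function(R) R[["554"]] / R[["677"]]),
    SR3    = list(wl = c(750, 550),
                  fun = function(R) R[["750"]] / R[["550"]]),
    SR4    = list(wl = c(700, 670),
                  fun = function(R) R[["700"]] / R[["670"]]),
    SR5    = list(wl = c(675, 700),
                  fun = function(R) R[["675"]] / R[["700"]]),
    TCARI2 = list(wl = c(750, 705, 550),
                  fun = function(R) {
                    3 * ((R[["750"]] - R[["705"]]) -
                           0.2 * (R[["750"]] - R[["550"]]) *
                           (R[["750"]] / R[["705"]]))
                  })
  )
  if (dialect == "canonical") {
    reg$CRI2 <- list(wl = c(510, 700),
                     fun = function(R) 1 / R[["510"]] - 1 / R[["700"]])
  }
  reg
}

#' Available vegetation indices
#'
#' @param dialect `"paper"` uses the formulas as printed in the study's index
#'   table (the default and the authoritative set here); `"canonical"` swaps
#'   in the literature definition where the two differ (CRI2 becomes
#'   `1/R510 - 1/R700`).
#' @return character vector of index names.
#' @export
vegetation_indices <- function(dialect = c("paper", "canonical")) {
  names(index_registry(match.arg(dialect)))
}

# Resolve requested wavelengths on the grid: exact integer match, else the
# nearest grid point within 1 nm, else an error.
resolve_wavelengths <- function(grid, wanted) {
  idx <- vapply(wanted, function(w) {
    d <- abs(grid - w)
    i <- which.min(d)
    if (d[i] > 1) {
      stop("wavelength ", w, " nm not on grid (nearest is ", grid[i], " nm)",
           call. = FALSE)
    }
    i
  }, integer(1))
  stats::setNames(idx, as.character(wanted))
}

#' Compute a vegetation index
#'
#' Evaluates a registered index for every spectrum (row) of a spectra matrix.
#' Wavelength lookup is exact on the integer grid, falling back to the nearest
#' grid point within 1 nm. A zero denominator yields `NA` for that tree (with
#' a warning), never an error.
#'
#' @param spectra spectra matrix (see [as_spectra()]) or a single named
#'   spectrum vector.
#' @param index index name (see [vegetation_indices()]).
#' @param dialect formula dialect, `"paper"` (default) or `"canonical"`.
#' @return named numeric vector of index values, one per tree.
#' @examples
#' flat <- as_spectra(matrix(0.3, 1, 2151,
#'   dimnames = list("t1", 350:2500)))
#' compute_index(flat, "GI")      # 1
#' compute_index(flat, "TCARI2")  # 0
#' @export
compute_index <- function(spectra, index,
                          dialect = c("paper", "canonical")) {
  reg <- index_registry(match.arg(dialect))
  if (!index %in% names(reg)) {
    stop("unknown index '", index, "'; see vegetation_indices()",
         call. = FALSE)
  }
  if (is.null(dim(spectra))) {
    spectra <- matrix(spectra, 1, dimnames = list("spectrum", names(spectra)))
  }
  def <- reg[[index]]
  grid <- as.numeric(colnames(spectra))
  idx <- resolve_wavelengths(grid, def$wl)
  R <- lapply(idx, function(i) spectra[, i])
  names(R) <- names(idx)
  old <- options(warn = -1); on.exit(options(old))
  val <- def$fun(R)
  options(old); on.exit()
  bad <- !is.finite(val)
  if (any(bad)) {
    warning(sum(bad), " spectra gave a non-finite ", index,
            " (zero denominator); set to NA")
    val[bad] <- NA_real_
  }
  stats::setNames(as.numeric(val), rownames(spectra))
}

#' Compute several vegetation indices
#'
#' @inheritParams compute_index
#' @param indices character vector of index names (default: all registered).
#' @return `data.frame` with `tree_id` and one column per index.
#' @export
compute_indices <- function(spectra, indices = vegetation_indices(dialect),
                            dialect = c("paper", "canonical")) {
  dialect <- match.arg(dialect)
  vals <- lapply(indices, function(ix) compute_index(spectra, ix, dialect))
  out <- data.frame(tree_id = rownames(spectra), stringsAsFactors = FALSE)
  for (i in seq_along(indices)) out[[indices[i]]] <- unname(vals[[i]])
  out
}

#' Read or write a wide spectra CSV
#'
#' Wide format: first column `tree_id`, remaining columns named by wavelength
#' (`"350"` ... `"2500"`).
#'
#' @param file path to a CSV file.
#' @param spectra spectra matrix.
#' @return `read_spectra()` returns a spectra matrix; `write_spectra()`
#'   returns `file` invisibly.
#' @export
read_spectra <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  as_spectra(df)
}

#' @rdname read_spectra
#' @export
write_spectra <- function(spectra, file) {
  df <- data.frame(tree_id = rownames(spectra), as.data.frame(unclass(spectra)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
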