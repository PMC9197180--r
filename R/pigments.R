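# Pigment quantification: extract absorbances -> content per needle dry mass.

#' Pigment equation coefficient sets
#'
#' Coefficients for converting 80%-acetone extract absorbances at 663, 646
#' and 470 nm into chlorophyll a, chlorophyll b and total carotenoid
#' concentrations (ug ml^-1):
#' \describe{
#'   \item{lichtenthaler}{Ca = 12.25 A663 - 2.79 A646;
#'     Cb = 21.50 A646 - 5.10 A663;
#'     Car = (1000 A470 - 1.82 Ca - 85.02 Cb) / 198. The default.}
#'   \item{wellburn}{Ca = 12.21 A663 - 2.81 A646;
#'     Cb = 20.13 A646 - 5.03 A663;
#'     Car = (1000 A470 - 3.27 Ca - 104 Cb) / 229.}
#' }
#' The two sets differ by a few percent, so every result is stamped with the
#' set used.
#'
#' @return named list of coefficient functions.
#' @export
pigment_coefficients <- function() {
  list(
    lichtenthaler = function(A663, A646, A470) {
      Ca <- 12.25 * A663 - 2.79 * A646
      Cb <- 21.50 * A646 - 5.10 * A663
      Car <- (1000 * A470 - 1.82 * Ca - 85.02 * Cb) / 198
      list(Ca = Ca, Cb = Cb, Car = Car)
    },
    wellburn = function(A663, A646, A470) {
      Ca <- 12.21 * A663 - 2.81 * A646
      Cb <- 20.13 * A646 - 5.03 * A663
      Car <- (1000 * A470 - 3.27 * Ca - 104 * Cb) / 229
      list(Ca = Ca, Cb = Cb, Car = Car)
    }
  )
}

#' Pigment content per needle dry mass
#'
#' Converts 80%-acetone extract absorbances to pigment content. Extract
#' concentrations (ug ml^-1) come from the selected coefficient set; content
#' is `concentration * extract volume (ml) / dry mass (mg)`, i.e. ug mg^-1,
#' numerically equal to mg g^-1 dry mass. Negative computed pigments are
#' reported as-is and flagged, not truncated, so downstream statistics remain
#' unbiased.
#'
#' @param A663,A646,A470 absorbances (unitless, >= 0); vectors are recycled to
#'   a common length.
#' @param volume_ml extract volume in ml (default 10).
#' @param dry_mass_mg needle dry mass in mg (default 25).
#' @param coefficients coefficient set, `"lichtenthaler"` (default) or
#'   `"wellburn"`.
#' @param tree_id optional sample identifiers.
#' @return `data.frame` with columns `tree_id` (when given), `chl_a`,
#'   `chl_b`, `car` (mg g^-1 dry mass), `coefficient_set` and `flag`
#'   (`TRUE` when any pigment is negative).
#' @examples
#' pigment_content(0.50, 0.20, 0.30)  # chl_a about 2.227 mg/g
#' @export
pigment_content <- function(A663, A646, A470, volume_ml = 10,
                            dry_mass_mg = 25,
                            coefficients = c("lichtenthaler", "wellburn"),
                            tree_id = NULL) {
  coefficients <- match.arg(coefficients)
  n <- max(length(A663), length(A646), length(A470))
  A663 <- rep_len(A663, n); A646 <- rep_len(A646, n); A470 <- rep_len(A470, n)
  volume_ml <- rep_len(volume_ml, n); dry_mass_mg <- rep_len(dry_mass_mg, n)
  if (any(c(A663, A646, A470) < 0)) {
    stop("absorbances must be >= 0", call. = FALSE)
  }
  if (any(volume_ml <= 0) || any(dry_mass_mg <= 0)) {
    stop("extract volume and dry mass must be > 0", call. = FALSE)
  }
  conc <- pigment_coefficients()[[coefficients]](A663, A646, A470)
  scale <- volume_ml / dry_mass_mg  # ug/ml * ml / mg = ug/mg = mg/g
  out <- data.frame(
    chl_a = conc$Ca * scale,
    chl_b = conc$Cb * scale,
    car = conc$Car * scale,
    coefficient_set = coefficients,
    stringsAsFactors = FALSE
  )
  out$flag <- out$chl_a < 0 | out$chl_b < 0 | out$car < 0
  if (!is.null(tree_id)) out <- cbind(tree_id = tree_id, out)
  out
}

#' Pigment content from an assay table
#'
#' Convenience wrapper applying [pigment_content()] to a CSV-style assay
#' table with columns `tree_id, A663, A646, A470` and optional `volume_ml`,
#' `dry_mass_mg`.
#'
#' @param assays `data.frame` of assays.
#' @param ... passed to [pigment_content()].
#' @return see [pigment_content()].
#' @export
pigment_content_table <- function(assays, ...) {
  pigment_content(assays$A663, assays$A646, assays$A470,
                  volume_ml = assays$volume_ml %||% 10,
                  dry_mass_mg = assays$dry_mass_mg %||% 25,
                  tree_id = assays$tree_id, ...)
}
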