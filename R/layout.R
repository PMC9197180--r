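#' Simulate a clonal field-trial layout
#'
#' Places `n_clones * ramets_per_clone` trees on a rectangular row-by-column
#' grid and assigns each clone an ecotype label. Positions not receiving a
#' tree are left empty (the layout only lists occupied positions), emulating
#' trials in which a subset of a larger planting is sampled.
#'
#' @param n_rows,n_cols grid dimensions (1-based integer row/column indices).
#' @param n_clones number of distinct clones.
#' @param ramets_per_clone number of ramets (trees) per clone.
#' @param ecotype_fractions named numeric vector of clone fractions per
#'   ecotype; must sum to 1. Default is equal thirds of
#'   `c("low", "medium", "high")` elevation ecotypes.
#' @param arrangement `"random"` scatters trees over the grid; `"clonal_rows"`
#'   plants the ramets of each clone contiguously in row-major order,
#'   mirroring trials planted as clonal rows.
#' @param seed RNG seed; identical seeds give bit-identical layouts.
#'
#' @return A `data.frame` with columns `row`, `col`, `tree_id`, `clone_id`,
#'   `ecotype` — one record per occupied position.
#' @examples
#' lay <- simulate_layout(10, 10, n_clones = 30, ramets_per_clone = 3, seed = 1)
#' table(table(lay$clone_id))  # every clone has exactly 3 ramets
#' @export
simulate_layout <- function(n_rows, n_cols, n_clones, ramets_per_clone,
                            ecotype_fractions = c(low = 1/3, medium = 1/3,
                                                  high = 1/3),
                            arrangement = c("random", "clonal_rows"),
                            seed = NULL) {
  arrangement <- match.arg(arrangement)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n_clones <- as.integer(n_clones)
  ramets_per_clone <- as.integer(ramets_per_clone)
  n_trees <- n_clones * ramets_per_clone
  if (n_trees > n_rows * n_cols) {
    stop("grid capacity exceeded: ", n_trees, " trees requested but only ",
         n_rows * n_cols, " positions available", call. = FALSE)
  }
  if (abs(sum(ecotype_fractions) - 1) > 1e-8) {
    stop("'ecotype_fractions' must sum to 1", call. = FALSE)
  }

  with_seed(seed, {
    grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols),
                        KEEP.OUT.ATTRS = FALSE)
    # row-major order (columns vary fastest within a row)
    grid <- grid[order(grid$row, grid$col), , drop = FALSE]

    clone_id <- sprintf("C%03d", seq_len(n_clones))
    clone_of_tree <- rep(clone_id, each = ramets_per_clone)

    if (arrangement == "clonal_rows") {
      # contiguous ramets, clones in randomized order, filling row-major
      ord <- sample.int(n_clones)
      clone_of_tree <- rep(clone_id[ord], each = ramets_per_clone)
      pos <- grid[seq_len(n_trees), , drop = FALSE]
    } else {
      pos <- grid[sample.int(nrow(grid), n_trees), , drop = FALSE]
      clone_of_tree <- sample(clone_of_tree)
    }

    # largest-remainder apportionment of clones to ecotypes
    target <- ecotype_fractions * n_clones
    base <- floor(target)
    rem <- n_clones - sum(base)
    if (rem > 0) {
      extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    eco_of_clone <- rep(names(ecotype_fractions), times = base)
    eco_of_clone <- sample(eco_of_clone)
    names(eco_of_clone) <- clone_id

    out <- data.frame(
      row = pos$row,
      col = pos$col,
      tree_id = sprintf("T%04d", seq_len(n_trees)),
      clone_id = clone_of_tree,
      ecotype = unname(eco_of_clone[clone_of_tree]),
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  })
}

#' Read or write a trial layout CSV
#'
#' Layout files have columns `row,col,tree_id,clone_id,ecotype`.
#'
#' @param file path to a CSV file.
#' @param layout a layout `data.frame` as produced by [simulate_layout()].
#' @return `read_layout()` returns the layout `data.frame`;
#'   `write_layout()` returns `file` invisibly.
#' @export
read_layout <- function(file) {
  lay <- utils::read.csv(file, stringsAsFactors = FALSE)
  check_layout(lay)
  lay
}

#' @rdname read_layout
#' @export
write_layout <- function(layout, file) {
  check_layout(layout)
  utils::write.csv(layout, file, row.names = FALSE)
  invisible(file)
}
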