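#' Default grids for the training-ratio experiment
#'
#' The study design sweeps 17 inactive:active (IN/A) training ratios from
#' 0.5 to 100 against 8 screening-library sizes from 5,000 to 400,000
#' compounds, with 10 random trials per grid cell.
#'
#' @name design_defaults
NULL

#' @rdname design_defaults
#' @export
default_ratio_grid <- function() {
  c(0.5, 1, 2, 4, 7, 10, 15, 20, 25, 30, 40, 50, 60, 70, 80, 90, 100)
}

#' @rdname design_defaults
#' @export
default_library_sizes <- function() {
  c(5000L, 10000L, 25000L, 50000L, 75000L, 100000L, 200000L, 400000L)
}

#' Define a ratio-by-library-size experiment design
#'
#' @param ratio_grid strictly increasing positive IN/A training ratios.
#' @param library_sizes strictly increasing screening-library sizes.
#' @param n_trials random trials per grid cell.
#' @param train_fraction fraction of the active pool reserved for training
#'   (the remainder are the fixed test positives merged into every
#'   screening library).
#' @param base_seed master seed; every cell derives its own seed from it.
#' @return an `experiment_design` object.
#' @examples
#' design <- experiment_design()
#' length(design$ratio_grid)    # 17
#' length(design$library_sizes) # 8
#' @export
experiment_design <- function(ratio_grid = default_ratio_grid(),
                              library_sizes = default_library_sizes(),
                              n_trials = 10, train_fraction = 0.18,
                              base_seed = 1) {
  stopifnot(length(ratio_grid) >= 1, all(ratio_grid > 0),
            length(library_sizes) >= 1, all(library_sizes > 0),
            length(n_trials) == 1, n_trials >= 1,
            length(train_fraction) == 1,
            length(base_seed) == 1, is.finite(base_seed))
  if (is.unsorted(ratio_grid, strictly = TRUE)) {
    stop("`ratio_grid` must be strictly increasing.", call. = FALSE)
  }
  if (is.unsorted(library_sizes, strictly = TRUE)) {
    stop("`library_sizes` must be strictly increasing.", call. = FALSE)
  }
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("`train_fraction` must lie strictly between 0 and 1.", call. = FALSE)
  }
  structure(
    list(ratio_grid = as.numeric(ratio_grid),
         library_sizes = as.integer(library_sizes),
         n_trials = as.integer(n_trials),
         train_fraction = train_fraction,
         base_seed = as.integer(base_seed)),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design> ", length(x$ratio_grid), " ratios (",
      min(x$ratio_grid), "-", max(x$ratio_grid), ") x ",
      length(x$library_sizes), " library sizes (",
      min(x$library_sizes), "-", max(x$library_sizes), ") x ",
      x$n_trials, " trials; train fraction ", x$train_fraction,
      ", base seed ", x$base_seed, "\n", sep = "")
  invisible(x)
}

#' Split the active pool into fixed training and test positives
#'
#' Draws `round(train_fraction * n)` actives uniformly without replacement
#' as the positive training set; the remainder become the test positives
#' merged into every screening library. The split is made once per
#' experiment: training positives never vary across grid cells.
#'
#' @param active_ids character vector of active compound ids (>= 2).
#' @param train_fraction fraction reserved for training, in (0, 1).
#' @param seed integer seed.
#' @return list with `train_pos_ids` and `test_pos_ids`.
#' @examples
#' split <- split_actives(sprintf("a%04d", 1:1101), 0.18, seed = 7)
#' lengths(split) # 198 train, 903 test
#' @export
split_actives <- function(active_ids, train_fraction = 0.18, seed = 1) {
  n <- length(active_ids)
  stopifnot(n >= 2, train_fraction > 0, train_fraction < 1)
  if (anyDuplicated(active_ids)) {
    stop("`active_ids` contains duplicates.", call. = FALSE)
  }
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n_train >= n) {
    stop("`train_fraction` = ", train_fraction, " leaves ", n_train,
         " of ", n, " actives for training; need at least 1 on each side.",
         call. = FALSE)
  }
  with_seed(seed, {
    idx <- sample.int(n, n_train)
    list(train_pos_ids = active_ids[sort(idx)],
         test_pos_ids = active_ids[-sort(idx)])
  })
}

#' Assemble one train/test realization for a grid cell
#'
#' Training negatives are `round(ratio * n_train_pos)` decoys sampled
#' without replacement from the pool; the screening library (test set) is
#' the fixed test positives merged with `library_size - n_test_pos` decoys
#' sampled from the *remaining* pool, so no decoy appears in both training
#' and test. The test order is shuffled under the seed. Fresh decoys are
#' drawn for every trial; only the positive sets are fixed.
#'
#' @param train_pos_ids,test_pos_ids fixed positive sets from
#'   [split_actives()].
#' @param decoy_pool_ids pool of decoy ids to draw from.
#' @param ratio IN/A training ratio.
#' @param library_size total size of the screening library.
#' @param seed integer seed for this cell's draws.
#' @param trial trial index recorded in the cell tag.
#' @return a `trial_assembly`: list with `train_pos_ids`, `train_neg_ids`,
#'   `test_ids`, `test_labels` (1 = active) and `cell`.
#' @export
assemble_trial <- function(train_pos_ids, test_pos_ids, decoy_pool_ids,
                           ratio, library_size, seed = 1, trial = 1L) {
  stopifnot(length(train_pos_ids) >= 1, length(test_pos_ids) >= 1,
            ratio > 0, library_size > 0)
  n_neg <- round(ratio * length(train_pos_ids))
  n_test_decoys <- library_size - length(test_pos_ids)
  if (n_test_decoys < 0) {
    stop("`library_size` (", library_size, ") is smaller than the number of ",
         "test positives (", length(test_pos_ids), ").", call. = FALSE)
  }
  required <- n_neg + n_test_decoys
  if (length(decoy_pool_ids) < required) {
    stop("Decoy pool too small: ", required, " decoys required (",
         n_neg, " training + ", n_test_decoys, " test) but only ",
         length(decoy_pool_ids), " available.", call. = FALSE)
  }
  with_seed(seed, {
    pick <- sample.int(length(decoy_pool_ids), required)
    train_neg_ids <- decoy_pool_ids[pick[seq_len(n_neg)]]
    test_decoy_ids <- decoy_pool_ids[pick[n_neg + seq_len(n_test_decoys)]]
    test_ids <- c(test_pos_ids, test_decoy_ids)
    test_labels <- c(rep(1L, length(test_pos_ids)),
                     rep(0L, length(test_decoy_ids)))
    perm <- sample.int(length(test_ids))
    structure(
      list(train_pos_ids = train_pos_ids,
           train_neg_ids = train_neg_ids,
           test_ids = test_ids[perm],
           test_labels = test_labels[perm],
           cell = list(ratio = ratio, library_size = as.integer(library_size),
                       trial = as.integer(trial))),
      class = "trial_assembly"
    )
  })
}

#' @export
print.trial_assembly <- function(x, ...) {
  cat("<trial_assembly> ratio ", x$cell$ratio, ", library ",
      x$cell$library_size, ", trial ", x$cell$trial, ": ",
      length(x$train_pos_ids), "+/", length(x$train_neg_ids), "- train, ",
      length(x$test_ids), " test (", sum(x$test_labels), " positives)\n",
      sep = "")
  invisible(x)
}

# deterministic 31-bit seed for one grid cell, mixing the base seed with a
# stable hash of the (ratio, size, trial) triple
cell_seed <- function(base_seed, ratio, library_size, trial) {
  h <- (round(ratio * 2) * 1000003 + as.numeric(library_size) * 97 +
          as.numeric(trial) * 131071) %% 2^31
  as.integer(bitwXor(as.integer(base_seed %% 2^31), as.integer(h)) %% 2^31)
}

#' Enumerate all grid cells of a design
#'
#' Cartesian product of library sizes, ratios and trials in a deterministic
#' order (library-size major, then ratio, then trial), each with its own
#' derived seed.
#'
#' @param design an [experiment_design()].
#' @return tibble with columns `library_size`, `ratio`, `trial`, `seed`.
#' @examples
#' nrow(enumerate_cells(experiment_design())) # 17 * 8 * 10 = 1360
#' @export
enumerate_cells <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  cells <- tidyr::expand_grid(
    library_size = design$library_sizes,
    ratio = design$ratio_grid,
    trial = seq_len(design$n_trials)
  )
  cells$seed <- purrr::pmap_int(
    cells,
    function(library_size, ratio, trial) {
      cell_seed(design$base_seed, ratio, library_size, trial)
    }
  )
  cells
}
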