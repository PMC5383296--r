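#' Run the full training-ratio experiment
#'
#' The end-to-end driver: split the active pool once into fixed training
#' and test positives, then for every grid cell (library size x training
#' ratio x trial) assemble a fresh screening library and training-negative
#' draw, fit every classifier, score the hard predictions, aggregate trial
#' means and derive cost-effectiveness recommendations. Identical inputs
#' and `base_seed` reproduce every table bit-exactly.
#'
#' @param actives `fingerprint_matrix` of active compounds.
#' @param decoys `fingerprint_matrix` of the decoy pool; must be large
#'   enough to cover the largest cell (training negatives plus test
#'   decoys). The error message of an undersized pool states the required
#'   and available counts.
#' @param design an [experiment_design()].
#' @param classifiers list of [classifier_spec()] objects (default: the
#'   native nb and knn1 pair).
#' @param threshold cost-effectiveness threshold for the recommendations
#'   table; default 0.03.
#' @param fingerprint_kind label recorded in the results (defaults to the
#'   actives' kind tag).
#' @param target label for the compound collection (optional bookkeeping).
#' @param progress print a line per library size as the grid proceeds?
#' @return a `vs_experiment` object: list with `results` (one row per cell
#'   x classifier), `cell_means`, `recommendations`, `design`, `split` and
#'   `manifest`.
#' @export
run_experiment <- function(actives, decoys, design = experiment_design(),
                           classifiers = list(classifier_spec("nb"),
                                              classifier_spec("knn1")),
                           threshold = 0.03,
                           fingerprint_kind = actives$kind,
                           target = "synthetic", progress = FALSE) {
  stopifnot(inherits(actives, "fingerprint_matrix"),
            inherits(decoys, "fingerprint_matrix"),
            inherits(design, "experiment_design"))
  if (ncol(actives$bits) != ncol(decoys$bits)) {
    stop("Active and decoy fingerprints have different widths.", call. = FALSE)
  }
  if (!is.list(classifiers) ||
      !all(vapply(classifiers, inherits, logical(1), "classifier_spec"))) {
    stop("`classifiers` must be a list of classifier_spec objects.",
         call. = FALSE)
  }
  if (any(duplicated(vapply(classifiers, function(s) s$algorithm, character(1))))) {
    stop("Duplicate classifier algorithms in `classifiers`.", call. = FALSE)
  }
  if (length(intersect(actives$ids, decoys$ids)) > 0) {
    stop("Active and decoy id sets overlap.", call. = FALSE)
  }

  # fixed positive split for the whole experiment
  split <- split_actives(actives$ids, design$train_fraction,
                         seed = stream_seed(design$base_seed, "split"))
  n_train_pos <- length(split$train_pos_ids)
  n_test_pos <- length(split$test_pos_ids)

  # capacity check up front so failures name the worst cell, not a trial
  worst_required <- round(max(design$ratio_grid) * n_train_pos) +
    (max(design$library_sizes) - n_test_pos)
  if (length(decoys$ids) < worst_required) {
    stop("Decoy pool too small for the largest grid cell: ", worst_required,
         " decoys required but only ", length(decoys$ids), " available.",
         call. = FALSE)
  }
  if (min(design$library_sizes) <= n_test_pos) {
    stop("Smallest library size (", min(design$library_sizes),
         ") does not exceed the number of test positives (", n_test_pos, ").",
         call. = FALSE)
  }

  train_pos_bits <- actives$bits[match(split$train_pos_ids, actives$ids), ,
                                 drop = FALSE]
  test_pos_bits <- actives$bits[match(split$test_pos_ids, actives$ids), ,
                                drop = FALSE]
  decoy_index <- stats::setNames(seq_along(decoys$ids), decoys$ids)

  cells <- enumerate_cells(design)
  algo_names <- vapply(classifiers, function(s) s$algorithm, character(1))
  rows <- vector("list", nrow(cells) * length(classifiers))
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    if (progress && (i == 1 ||
                     cell$library_size != cells$library_size[[i - 1]])) {
      message("library size ", cell$library_size, " ...")
    }
    asm <- assemble_trial(split$train_pos_ids, split$test_pos_ids,
                          decoys$ids, cell$ratio, cell$library_size,
                          seed = cell$seed, trial = cell$trial)
    train_bits <- rbind(train_pos_bits,
                        decoys$bits[decoy_index[asm$train_neg_ids], ,
                                    drop = FALSE])
    train_labels <- c(rep(1L, n_train_pos), rep(0L, length(asm$train_neg_ids)))
    is_pos <- asm$test_labels == 1L
    test_bits <- matrix(0L, length(asm$test_ids), ncol(actives$bits))
    test_bits[is_pos, ] <- test_pos_bits[match(asm$test_ids[is_pos],
                                               split$test_pos_ids), ,
                                         drop = FALSE]
    test_bits[!is_pos, ] <- decoys$bits[decoy_index[asm$test_ids[!is_pos]], ,
                                        drop = FALSE]
    for (j in seq_along(classifiers)) {
      fit <- fit_classifier(classifiers[[j]], train_bits, train_labels,
                            seed = stream_seed(cell$seed, "classifier"))
      scored <- score_predictions(predict(fit, test_bits), asm$test_labels)
      k <- k + 1L
      rows[[k]] <- dplyr::bind_cols(
        tibble::tibble(target = target, classifier = algo_names[[j]],
                       fingerprint = fingerprint_kind,
                       ratio = cell$ratio, library_size = cell$library_size,
                       trial = cell$trial),
        scored
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  cell_means <- aggregate_trials(results)
  recommendations <- recommend_ratios(cell_means, threshold)

  manifest <- list(
    package_version = as.character(utils::packageVersion("vsratio")),
    target = target,
    fingerprint_kind = fingerprint_kind,
    n_actives = length(actives$ids),
    n_decoys = length(decoys$ids),
    n_train_pos = n_train_pos,
    n_test_pos = n_test_pos,
    classifiers = algo_names,
    threshold = threshold,
    design = design[c("ratio_grid", "library_sizes", "n_trials",
                      "train_fraction", "base_seed")],
    config_hash = config_hash(design, algo_names, threshold,
                              length(actives$ids), length(decoys$ids))
  )
  structure(
    list(results = results, cell_means = cell_means,
         recommendations = recommendations, design = design, split = split,
         manifest = manifest),
    class = "vs_experiment"
  )
}

# cheap deterministic configuration digest for the manifest (not
# cryptographic; changes whenever any run-defining input changes)
config_hash <- function(design, algos, threshold, n_act, n_dcy) {
  s <- paste(c(design$ratio_grid, design$library_sizes, design$n_trials,
               design$train_fraction, design$base_seed, algos, threshold,
               n_act, n_dcy), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' @export
print.vs_experiment <- function(x, ...) {
  cat("<vs_experiment> ", x$manifest$target, ": ",
      length(x$design$ratio_grid), " ratios x ",
      length(x$design$library_sizes), " sizes x ", x$design$n_trials,
      " trials, classifiers: ",
      paste(x$manifest$classifiers, collapse = ", "), "\n", sep = "")
  cat("  ", nrow(x$results), " result rows; recommendations at threshold ",
      x$manifest$threshold, ":\n", sep = "")
  print(x$recommendations)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-cell means of an experiment
#'
#' @param x a `vs_experiment`.
#' @param ... unused.
#' @return the per-cell trial means as a tibble.
#' @export
tidy.vs_experiment <- function(x, ...) {
  x$cell_means
}

#' One-row experiment summary
#'
#' @param x a `vs_experiment`.
#' @param ... unused.
#' @return one-row tibble: grid dimensions, best MCC over all cells, and
#'   the range of recommended ratios.
#' @export
glance.vs_experiment <- function(x, ...) {
  tibble::tibble(
    n_ratios = length(x$design$ratio_grid),
    n_library_sizes = length(x$design$library_sizes),
    n_trials = x$design$n_trials,
    n_classifiers = length(x$manifest$classifiers),
    n_cells = nrow(x$cell_means),
    best_mcc = max(x$cell_means$mcc),
    min_optimal_ratio = min(x$recommendations$optimal_ratio),
    max_optimal_ratio = max(x$recommendations$optimal_ratio)
  )
}

#' Performance panels: recall, precision and MCC against the training ratio
#'
#' One panel per (classifier, measure) with a curve per library size --
#' the standard view of how the training ratio and the screening-library
#' size jointly move screening performance.
#'
#' @param x a `vs_experiment` (or its `cell_means` tibble).
#' @return a ggplot object.
#' @export
plot_performance <- function(x) {
  cm <- if (inherits(x, "vs_experiment")) x$cell_means else x
  long <- cm |>
    tidyr::pivot_longer(cols = c("recall", "precision", "mcc"),
                        names_to = "measure", values_to = "value") |>
    dplyr::mutate(measure = factor(.data$measure,
                                   levels = c("recall", "precision", "mcc")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ratio, y = .data$value,
                                     colour = factor(.data$library_size),
                                     group = factor(.data$library_size))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(measure ~ classifier) +
    ggplot2::labs(x = "IN/A training ratio", y = NULL,
                  colour = "library size") +
    ggplot2::theme_minimal()
}

#' Precision-recall trajectories across training ratios
#'
#' @param x a `vs_experiment` (or its `cell_means` tibble).
#' @return a ggplot object: one path per (classifier, library size),
#'   traced with increasing training ratio.
#' @export
plot_pr_trajectory <- function(x) {
  cm <- if (inherits(x, "vs_experiment")) x$cell_means else x
  cm <- dplyr::arrange(cm, .data$ratio)
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   colour = factor(.data$library_size),
                                   group = factor(.data$library_size))) +
    ggplot2::geom_path(arrow = grid::arrow(length = grid::unit(2, "mm"))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 3) +
    ggplot2::facet_wrap(~classifier) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision", colour = "library size") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness curves
#'
#' MCC loss relative to the best ratio, per library size and classifier.
#'
#' @param x a `vs_experiment` (or its `cell_means` tibble).
#' @return a ggplot object.
#' @export
plot_cost_effectiveness <- function(x) {
  cm <- if (inherits(x, "vs_experiment")) x$cell_means else x
  context_cols <- intersect(c("target", "classifier", "fingerprint",
                              "library_size"), names(cm))
  curves <- cm |>
    dplyr::group_by(dplyr::across(dplyr::all_of(context_cols))) |>
    dplyr::mutate(delta = max(.data$mcc) - .data$mcc) |>
    dplyr::ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$ratio, y = .data$delta,
                                       colour = factor(.data$library_size),
                                       group = factor(.data$library_size))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~classifier) +
    ggplot2::labs(x = "IN/A training ratio", y = "MCC loss vs best",
                  colour = "library size") +
    ggplot2::theme_minimal()
}

#' @rdname plot_performance
#' @param object a `vs_experiment`.
#' @param ... unused.
#' @export
autoplot.vs_experiment <- function(object, ...) {
  plot_performance(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write experiment outputs to a directory
#'
#' Emits the per-trial results table, the per-cell means, the
#' recommendations table (all CSV), a JSON manifest recording the
#' configuration, seeds and package version, and the three standard figure
#' panels as PNG files.
#'
#' @param experiment a `vs_experiment`.
#' @param dir output directory (created if missing).
#' @param figures write the PNG panels as well?
#' @return named character vector of written paths, invisibly.
#' @export
report_experiment <- function(experiment, dir, figures = TRUE) {
  stopifnot(inherits(experiment, "vs_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    results = file.path(dir, "results.csv"),
    cell_means = file.path(dir, "cell_means.csv"),
    recommendations = file.path(dir, "recommendations.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  readr::write_csv(experiment$results, paths[["results"]], progress = FALSE)
  readr::write_csv(experiment$cell_means, paths[["cell_means"]],
                   progress = FALSE)
  readr::write_csv(experiment$recommendations, paths[["recommendations"]],
                   progress = FALSE)
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("Writing the manifest needs the jsonlite package.", call. = FALSE)
  }
  jsonlite::write_json(experiment$manifest, paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (figures) {
    figs <- c(performance = plot_performance,
              pr_trajectory = plot_pr_trajectory,
              cost_effectiveness = plot_cost_effectiveness)
    for (nm in names(figs)) {
      p <- file.path(dir, paste0(nm, ".png"))
      ggplot2::ggsave(p, figs[[nm]](experiment), width = 8, height = 6,
                      dpi = 120)
      paths[[nm]] <- p
    }
  }
  invisible(paths)
}
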