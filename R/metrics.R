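#' Confusion counts for hard binary predictions
#'
#' Tallies true/false positives and negatives for 0/1 predictions against
#' 0/1 truth (1 = active). The four counts always partition the test set.
#'
#' @param pred,truth 0/1 vectors of equal length.
#' @return one-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` have different lengths (", length(pred), " vs ",
         length(truth), ").", call. = FALSE)
  }
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  if (!all(pred %in% c(0L, 1L)) || !all(truth %in% c(0L, 1L))) {
    stop("`pred` and `truth` must be 0/1 vectors.", call. = FALSE)
  }
  tibble::tibble(
    tp = sum(pred == 1L & truth == 1L),
    fp = sum(pred == 1L & truth == 0L),
    tn = sum(pred == 0L & truth == 0L),
    fn = sum(pred == 0L & truth == 1L)
  )
}

counts_from <- function(cc) {
  if (is.data.frame(cc)) {
    need <- c("tp", "fp", "tn", "fn")
    missing_cols <- setdiff(need, names(cc))
    if (length(missing_cols) > 0) {
      stop("Confusion counts are missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    cc[need]
  } else if (is.numeric(cc) && all(c("tp", "fp", "tn", "fn") %in% names(cc))) {
    as.data.frame(as.list(cc[c("tp", "fp", "tn", "fn")]))
  } else {
    stop("Expected a confusion-counts data frame or named vector.",
         call. = FALSE)
  }
}

#' Recall (sensitivity)
#'
#' `TP / (TP + FN)`: the fraction of test actives that the model recovers.
#' If a cell has no test positives at all (degenerate and outside the
#' intended use, where test positives are fixed and nonzero), the value is
#' 0 with a warning.
#'
#' @param cc confusion counts: the tibble from [confusion()] (any number of
#'   rows) or a named vector with `tp`, `fp`, `tn`, `fn`.
#' @return numeric vector of recalls in `[0, 1]`.
#' @export
recall <- function(cc) {
  cc <- counts_from(cc)
  denom <- cc$tp + cc$fn
  if (any(denom == 0)) {
    warning("recall undefined without test positives; returning 0.",
            call. = FALSE)
  }
  ifelse(denom == 0, 0, cc$tp / denom)
}

#' Precision (positive predictive value)
#'
#' `TP / (TP + FP)`: the fraction of predicted actives that are truly
#' active -- in screening terms, the hit rate among the compounds the model
#' selects. When the model selects nothing (`TP + FP = 0`) the value is 0
#' by the no-skill convention; [score_predictions()] flags such cells.
#'
#' @inheritParams recall
#' @return numeric vector of precisions in `[0, 1]`.
#' @export
precision <- function(cc) {
  cc <- counts_from(cc)
  denom <- cc$tp + cc$fp
  ifelse(denom == 0, 0, cc$tp / denom)
}

#' Matthews correlation coefficient
#'
#' `(TP * TN - FP * FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the balanced
#' effectiveness measure for binary classification: -1 is total
#' disagreement, 0 chance-level, 1 perfect. Any zero factor in the
#' denominator yields 0 by convention (the no-skill value, which keeps
#' trial averages defined); counts up to 1e7 are handled without overflow
#' by evaluating in double precision.
#'
#' @inheritParams recall
#' @return numeric vector of MCC values in `[-1, 1]`.
#' @examples
#' mcc(c(tp = 7, fp = 0, tn = 13, fn = 0)) # 1
#' @export
mcc <- function(cc) {
  cc <- counts_from(cc)
  tp <- as.numeric(cc$tp); fp <- as.numeric(cc$fp)
  tn <- as.numeric(cc$tn); fn <- as.numeric(cc$fn)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  ifelse(denom == 0, 0, (tp * tn - fp * fn) / denom)
}

#' Score hard predictions against truth
#'
#' Convenience wrapper: confusion counts plus recall, precision and MCC in
#' one row, with a `degenerate` flag raised when precision or MCC fell back
#' to the 0 convention (no positive predictions, or a zero MCC denominator).
#'
#' @inheritParams confusion
#' @return one-row tibble: `tp`, `fp`, `tn`, `fn`, `recall`, `precision`,
#'   `mcc`, `degenerate`.
#' @export
score_predictions <- function(pred, truth) {
  cc <- confusion(pred, truth)
  tp <- as.numeric(cc$tp); fp <- as.numeric(cc$fp)
  tn <- as.numeric(cc$tn); fn <- as.numeric(cc$fn)
  degenerate <- (tp + fp) == 0 ||
    any(c(tp + fp, tp + fn, tn + fp, tn + fn) == 0)
  dplyr::mutate(cc, recall = recall(cc), precision = precision(cc),
                mcc = mcc(cc), degenerate = degenerate)
}

#' Average per-trial metrics within each grid cell
#'
#' Collapses a per-trial results table to per-cell means: the arithmetic
#' mean of each measure across trials (the mean of per-trial metrics, not
#' the metric of pooled counts -- the two differ), with the trial count and
#' standard deviation retained. Grouping is by every identifying column
#' present among `classifier`, `fingerprint`, `target`, `ratio`,
#' `library_size`.
#'
#' @param records tibble with one row per trial: identifying columns plus
#'   `trial` and the measures `recall`, `precision`, `mcc`.
#' @return tibble of cell means with columns `recall`, `precision`, `mcc`,
#'   `sd_recall`, `sd_precision`, `sd_mcc`, `n_trials`.
#' @export
aggregate_trials <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("ratio", "library_size", "trial", "recall", "precision", "mcc")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    stop("`records` is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  group_cols <- intersect(
    c("target", "classifier", "fingerprint", "ratio", "library_size"),
    names(records)
  )
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      sd_recall = stats::sd(.data$recall),
      sd_precision = stats::sd(.data$precision),
      sd_mcc = stats::sd(.data$mcc),
      recall = mean(.data$recall),
      precision = mean(.data$precision),
      mcc = mean(.data$mcc),
      .groups = "drop"
    ) |>
    dplyr::relocate(dplyr::all_of(group_cols), "recall", "precision", "mcc")
  if (length(unique(out$n_trials)) > 1) {
    bad <- out[out$n_trials < max(out$n_trials), group_cols, drop = FALSE]
    stop("Incomplete cells (fewer trials than the rest):\n",
         paste(utils::capture.output(print(as.data.frame(bad))), collapse = "\n"),
         call. = FALSE)
  }
  out
}

#' Precision-recall trajectory across training ratios
#'
#' For one (classifier, fingerprint, library size) context, orders the
#' per-cell mean (recall, precision) points by increasing training ratio --
#' the parametric PR path traced as the negative training set grows -- and
#' labels each point with its PR quadrant. Quadrants split at recall 0.5
#' and precision 0.5: quarter I is the good corner (both at or above 0.5),
#' IV is high recall / low precision (where under-trained screening models
#' start), III is low recall / high precision, and II is low on both.
#'
#' @param cell_means tibble of per-cell means for a single context, with
#'   columns `ratio`, `recall`, `precision` (one row per ratio).
#' @return tibble ordered by `ratio` with an added `quadrant` column.
#' @export
pr_trajectory <- function(cell_means) {
  stopifnot(is.data.frame(cell_means))
  need <- c("ratio", "recall", "precision")
  missing_cols <- setdiff(need, names(cell_means))
  if (length(missing_cols) > 0) {
    stop("`cell_means` is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(cell_means) < 2) {
    stop("A trajectory needs at least 2 ratios.", call. = FALSE)
  }
  if (anyDuplicated(cell_means$ratio)) {
    stop("`cell_means` must hold a single context: one row per ratio.",
         call. = FALSE)
  }
  cell_means |>
    dplyr::arrange(.data$ratio) |>
    dplyr::mutate(quadrant = dplyr::case_when(
      .data$recall >= 0.5 & .data$precision >= 0.5 ~ "I",
      .data$recall < 0.5 & .data$precision >= 0.5 ~ "III",
      .data$recall >= 0.5 & .data$precision < 0.5 ~ "IV",
      TRUE ~ "II"
    ))
}
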