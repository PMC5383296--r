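#' Cost-effectiveness curve of the training ratio
#'
#' For one (classifier, fingerprint, library size) context, expresses each
#' training ratio's trial-mean MCC as a loss `delta` relative to the best
#' mean MCC found anywhere on the ratio grid for that library:
#' `delta(ratio) = best_mcc - mcc(ratio)`. The curve is the raw material
#' for choosing a cheaper training ratio at a tolerated MCC loss.
#'
#' @param cell_means tibble for a single context with columns `ratio` and
#'   `mcc` (one row per ratio, trial means).
#' @return a `ce_curve`: the input ordered by ratio with a `delta` column
#'   and the best MCC in `attr(, "best_mcc")`.
#' @examples
#' curve <- cost_effectiveness(
#'   tibble::tibble(ratio = c(0.5, 2, 10, 100), mcc = c(0.2, 0.5, 0.6, 0.58))
#' )
#' curve$delta # 0.4 0.1 0.0 0.02
#' @export
cost_effectiveness <- function(cell_means) {
  stopifnot(is.data.frame(cell_means))
  missing_cols <- setdiff(c("ratio", "mcc"), names(cell_means))
  if (length(missing_cols) > 0) {
    stop("`cell_means` is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(cell_means) < 1) {
    stop("At least one ratio is required.", call. = FALSE)
  }
  if (anyDuplicated(cell_means$ratio)) {
    stop("`cell_means` must hold a single context: one row per ratio.",
         call. = FALSE)
  }
  if (all(!is.finite(cell_means$mcc))) {
    stop("All MCC values are degenerate; no curve can be formed.",
         call. = FALSE)
  }
  best <- max(cell_means$mcc, na.rm = TRUE)
  out <- cell_means |>
    dplyr::arrange(.data$ratio) |>
    dplyr::mutate(delta = best - .data$mcc)
  attr(out, "best_mcc") <- best
  class(out) <- c("ce_curve", class(out))
  out
}

#' Minimal cost-effective training ratio
#'
#' The smallest ratio on the grid whose MCC loss `delta` is within the
#' cost-effectiveness threshold. At threshold 0 this is the best ratio
#' itself (ties resolve to the smaller, cheaper ratio).
#'
#' @param curve a [cost_effectiveness()] curve.
#' @param threshold maximum tolerated MCC loss (>= 0); default 0.03.
#' @return one-row tibble: `threshold`, `optimal_ratio`, `best_mcc`,
#'   `mcc_at_optimal`, plus any context columns carried on the curve.
#' @examples
#' curve <- cost_effectiveness(
#'   tibble::tibble(ratio = c(0.5, 2, 10, 100), mcc = c(0.2, 0.5, 0.6, 0.58))
#' )
#' minimize_ratio(curve, 0.03)$optimal_ratio # 10
#' minimize_ratio(curve, 0.12)$optimal_ratio # 2
#' @export
minimize_ratio <- function(curve, threshold = 0.03) {
  stopifnot(inherits(curve, "ce_curve"), length(threshold) == 1,
            threshold >= 0)
  ok <- which(curve$delta <= threshold)
  # threshold 0 is always satisfiable: delta is 0 at the argmax
  pick <- ok[[1]]
  context_cols <- intersect(c("target", "classifier", "fingerprint",
                              "library_size"), names(curve))
  out <- tibble::tibble(
    threshold = threshold,
    optimal_ratio = curve$ratio[[pick]],
    best_mcc = attr(curve, "best_mcc"),
    mcc_at_optimal = curve$mcc[[pick]]
  )
  if (length(context_cols) > 0) {
    out <- dplyr::bind_cols(
      tibble::as_tibble(curve)[pick, context_cols, drop = FALSE], out
    )
  }
  out
}

#' Optimal ratio across a range of thresholds
#'
#' Applies [minimize_ratio()] over a list of thresholds. Because any ratio
#' admissible at a threshold stays admissible at every larger threshold,
#' the profile is monotone: larger thresholds never yield larger optimal
#' ratios.
#'
#' @param curve a [cost_effectiveness()] curve.
#' @param thresholds numeric vector of thresholds (>= 0).
#' @return tibble with one row per threshold.
#' @export
threshold_profile <- function(curve, thresholds) {
  stopifnot(length(thresholds) >= 1, all(thresholds >= 0))
  purrr::map_dfr(thresholds, function(t) minimize_ratio(curve, t))
}

#' Cost-effectiveness recommendations for a whole results table
#'
#' Splits a per-cell means table by context (target / classifier /
#' fingerprint / library size, whichever are present), builds each context's
#' cost-effectiveness curve and extracts the minimal ratio at the given
#' threshold -- the tabular summary of how the recommended training ratio
#' scales with the screening library.
#'
#' @param cell_means per-cell means from [aggregate_trials()].
#' @param threshold tolerated MCC loss; default 0.03.
#' @return tibble with one recommendation row per context.
#' @export
recommend_ratios <- function(cell_means, threshold = 0.03) {
  stopifnot(is.data.frame(cell_means))
  context_cols <- intersect(c("target", "classifier", "fingerprint",
                              "library_size"), names(cell_means))
  cell_means |>
    dplyr::group_by(dplyr::across(dplyr::all_of(context_cols))) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(g) minimize_ratio(cost_effectiveness(g), threshold))
}
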