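#' Standardize a potency measurement to Ki in nM
#'
#' Converts heterogeneous binding / inhibition measurements onto a common
#' Ki scale in nanomolar. \code{Ki} values pass through unchanged, \code{pKi}
#' (= -log10 of Ki in molar) maps to \code{10^(9 - pKi)} nM, and \code{IC50}
#' is divided by 2 (the Cheng-Prusoff-motivated conversion factor of
#' Kalliokoski and colleagues for heterogeneous assay data).
#'
#' @param measurement_type character vector, each one of `"Ki"`, `"pKi"`,
#'   `"IC50"` (case-insensitive).
#' @param value numeric vector of measured values; nM for Ki and IC50,
#'   dimensionless for pKi. Must be strictly positive for Ki and IC50.
#' @return numeric vector of Ki values in nM.
#' @examples
#' standardize_activity("IC50", 200) # 100
#' standardize_activity("pKi", 7)    # 100
#' standardize_activity("Ki", 50)    # 50
#' @export
standardize_activity <- function(measurement_type, value) {
  type <- tolower(as.character(measurement_type))
  if (length(type) == 1 && length(value) > 1) {
    type <- rep(type, length(value))
  }
  if (length(type) != length(value)) {
    stop("`measurement_type` and `value` must have the same length.", call. = FALSE)
  }
  known <- c("ki", "pki", "ic50")
  bad <- setdiff(unique(type), known)
  if (length(bad) > 0) {
    stop("Unknown measurement type(s): ", paste(bad, collapse = ", "),
         ". Expected Ki, pKi or IC50.", call. = FALSE)
  }
  needs_pos <- type %in% c("ki", "ic50")
  if (any(needs_pos & (!is.finite(value) | value <= 0))) {
    stop("Ki and IC50 values must be strictly positive.", call. = FALSE)
  }
  out <- value
  out[type == "pki"] <- 10^(9 - value[type == "pki"])
  out[type == "ic50"] <- value[type == "ic50"] / 2
  out
}

#' Aggregate repeated measurements of one compound
#'
#' When a compound carries several activity records, its consensus Ki is the
#' median of the standardized values: robust to the occasional discordant
#' assay and equal to the single value when only one record exists.
#'
#' @param measurement_type,value vectors of measurements for one compound,
#'   as in [standardize_activity()].
#' @return a single Ki in nM.
#' @examples
#' aggregate_measurements(c("Ki", "Ki", "Ki"), c(10, 90, 20)) # 20
#' aggregate_measurements(c("IC50", "pKi"), c(40, 8))         # 15
#' @export
aggregate_measurements <- function(measurement_type, value) {
  if (length(value) == 0) {
    stop("At least one measurement is required.", call. = FALSE)
  }
  stats::median(standardize_activity(measurement_type, value))
}

#' Label a compound active or inactive from its Ki
#'
#' A compound is active when its Ki is strictly below the threshold
#' (default 100 nM); a Ki exactly at the threshold is inactive.
#'
#' @param ki_nM positive numeric vector of Ki values in nM.
#' @param threshold_nM positive scalar activity cutoff in nM.
#' @return character vector, `"active"` or `"inactive"`.
#' @examples
#' label_activity(c(99, 100, 0.1))
#' @export
label_activity <- function(ki_nM, threshold_nM = 100) {
  stopifnot(is.numeric(ki_nM), length(threshold_nM) == 1, threshold_nM > 0)
  if (any(!is.finite(ki_nM) | ki_nM <= 0)) {
    stop("`ki_nM` must be strictly positive.", call. = FALSE)
  }
  ifelse(ki_nM < threshold_nM, "active", "inactive")
}

#' Filter compounds by molecular weight
#'
#' Retains compounds whose molecular weight lies strictly inside
#' (`lo_Da`, `hi_Da`); the default window 200-700 Da excludes fragments and
#' oversized molecules. Both bounds are strict, so a compound of exactly
#' 200 Da is removed. Row order is preserved.
#'
#' @param compounds data frame with an `mw` column (Daltons).
#' @param lo_Da,hi_Da strict bounds in Daltons.
#' @param keep_missing_mw if `TRUE`, rows with `NA` molecular weight pass
#'   through; if `FALSE` (default) they are an error.
#' @return the filtered tibble.
#' @export
filter_by_mw <- function(compounds, lo_Da = 200, hi_Da = 700,
                         keep_missing_mw = FALSE) {
  stopifnot(is.data.frame(compounds), lo_Da < hi_Da)
  if (!"mw" %in% names(compounds)) {
    stop("`compounds` must have an `mw` column.", call. = FALSE)
  }
  mw <- compounds$mw
  if (any(is.na(mw)) && !keep_missing_mw) {
    stop("Missing molecular weights; set `keep_missing_mw = TRUE` to pass them through.",
         call. = FALSE)
  }
  keep <- (!is.na(mw) & mw > lo_Da & mw < hi_Da) | (is.na(mw) & keep_missing_mw)
  tibble::as_tibble(compounds[keep, , drop = FALSE])
}

#' Remove duplicate compounds
#'
#' One row is kept per distinct structure key: the canonical structure
#' string where present, otherwise the compound id. The first occurrence
#' wins and row order is preserved, so the result is deterministic.
#'
#' @param compounds data frame with a `compound_id` column and optionally a
#'   `structure` column.
#' @return deduplicated tibble.
#' @export
deduplicate <- function(compounds) {
  stopifnot(is.data.frame(compounds))
  if (nrow(compounds) == 0) {
    return(tibble::as_tibble(compounds))
  }
  if (!"compound_id" %in% names(compounds)) {
    stop("`compounds` must have a `compound_id` column.", call. = FALSE)
  }
  key <- as.character(compounds$compound_id)
  if ("structure" %in% names(compounds)) {
    s <- as.character(compounds$structure)
    use <- !is.na(s) & nzchar(s)
    key[use] <- s[use]
  }
  tibble::as_tibble(compounds[!duplicated(key), , drop = FALSE])
}

#' Curate an activity-record table to labeled compounds
#'
#' The full curation pipeline for a table of activity records (one row per
#' measurement): standardize every measurement to Ki (nM), aggregate
#' repeated measurements per compound by the median, label activity at the
#' Ki cutoff, deduplicate by structure and (optionally) filter by molecular
#' weight.
#'
#' @param records data frame with columns `compound_id`,
#'   `measurement_type`, `value`, and optionally `structure`, `mw`,
#'   `target_id`.
#' @param threshold_nM activity cutoff in nM; active means Ki strictly
#'   below it.
#' @param mw_filter apply the molecular-weight window? Requires an `mw`
#'   column when `TRUE`.
#' @param lo_Da,hi_Da strict molecular-weight bounds (Daltons).
#' @return tibble with one row per curated compound: `compound_id`,
#'   `ki_nM`, `label`, and `mw` / `structure` when supplied.
#' @examples
#' records <- tibble::tibble(
#'   compound_id = c("a", "a", "b", "c"),
#'   measurement_type = c("Ki", "IC50", "pKi", "Ki"),
#'   value = c(40, 120, 7.5, 500),
#'   mw = c(320, 320, 410, 250)
#' )
#' curate_activities(records)
#' @export
curate_activities <- function(records, threshold_nM = 100, mw_filter = TRUE,
                              lo_Da = 200, hi_Da = 700) {
  stopifnot(is.data.frame(records))
  need <- c("compound_id", "measurement_type", "value")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    stop("`records` is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) {
    stop("`records` has no rows.", call. = FALSE)
  }
  if (any(is.na(records$compound_id) | !nzchar(as.character(records$compound_id)))) {
    stop("Every record needs a non-empty `compound_id`.", call. = FALSE)
  }
  # validate all measurements up front so errors name the input, not a group
  standardize_activity(records$measurement_type, records$value)

  keep_first <- function(x) x[[1]]
  curated <- records |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(
      ki_nM = aggregate_measurements(.data$measurement_type, .data$value),
      dplyr::across(dplyr::any_of(c("structure", "mw", "target_id")), keep_first),
      .groups = "drop"
    ) |>
    dplyr::mutate(label = label_activity(.data$ki_nM, threshold_nM)) |>
    dplyr::relocate(dplyr::any_of(c("compound_id", "ki_nM", "label", "mw",
                                    "structure", "target_id")))
  curated <- deduplicate(curated)
  if (mw_filter) {
    curated <- filter_by_mw(curated, lo_Da, hi_Da)
  }
  curated
}

#' Read an activity-record table from delimited text
#'
#' Expects a header row with at least `compound_id`, `measurement_type` and
#' `value`; `structure`, `mw` and `target_id` are optional. Comma and tab
#' delimiters are auto-detected.
#'
#' @param path file path.
#' @return tibble of activity records.
#' @export
read_activity_table <- function(path) {
  if (!file.exists(path)) {
    stop("File not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  need <- c("compound_id", "measurement_type", "value")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("Activity table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Write a curated compound table
#'
#' @param compounds curated tibble from [curate_activities()].
#' @param path output file path; format is comma-delimited with a header.
#' @return `path`, invisibly.
#' @export
write_curated_table <- function(compounds, path) {
  readr::write_csv(compounds, path, progress = FALSE)
  invisible(path)
}
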