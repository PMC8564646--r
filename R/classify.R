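#' Relative change in ctDNA level between two timepoints
#'
#' @param c0 Baseline copies per mL plasma, strictly positive.
#' @param c1 Follow-up copies per mL plasma, non-negative.
#' @return Signed fraction `(c1 - c0) / c0`; -1 corresponds to complete
#'   clearance. Vectorised.
#' @examples
#' relative_change(100, 70)
#' relative_change(50, 0)
#' @export
relative_change <- function(c0, c1) {
  if (any(c0 <= 0)) {
    stop("baseline level must be strictly positive to compute a relative change",
         call. = FALSE)
  }
  if (any(c1 < 0)) stop("follow-up level must be non-negative", call. = FALSE)
  (c1 - c0) / c0
}

#' Classify two-timepoint ctDNA dynamics
#'
#' Classifies each patient's change in mutant ctDNA between baseline (t0)
#' and the 4-6-week follow-up (t1) into four categories at a relative-change
#' threshold derived from the assay's ~30% technical coefficient of
#' variation — only larger changes are treated as real:
#'
#' * `decreasing` — more than `threshold` fewer copies at t1 (or a positive
#'   t0 followed by a valid negative t1, change -1),
#' * `increasing` — more than `threshold` more copies at t1 (including new
#'   detection after a negative baseline, by convention),
#' * `stable` — absolute change at or below the threshold (the boundary is
#'   stable),
#' * `negative` — the tissue-confirmed mutation undetected in plasma at both
#'   timepoints.
#'
#' Patients with an `invalid` measurement at either timepoint are excluded
#' (returned with `NA` category and an `excluded_reason`), mirroring the
#' exclusion of patients without evaluable samples.
#'
#' @param quant Quantification table as returned by [quantify_wells()]
#'   (columns `patient_id`, `timepoint`, `copies_per_ml`, `status`),
#'   containing the two timepoints of interest.
#' @param threshold Relative-change threshold as a fraction in (0, 1).
#' @param t0,t1 Timepoint labels identifying baseline and follow-up rows.
#' @param negative_baseline How to treat patients negative at t0 but
#'   positive at t1: `"increasing"` (default) classifies them as new
#'   detections; `"exclude"` drops them.
#' @return A tibble with one row per patient: `copies_t0`, `copies_t1`,
#'   `status_t0`, `status_t1`, `relative_change` (defined only when t0 is
#'   positive), `category`, `threshold`, `excluded_reason`.
#' @examples
#' quant <- tibble::tibble(
#'   patient_id = rep(c("P1", "P2"), each = 2),
#'   timepoint = rep(c("t0", "t1"), 2),
#'   copies_per_ml = c(100, 65, 100, 70),
#'   status = "positive"
#' )
#' classify_dynamics(quant)
#' @export
classify_dynamics <- function(quant, threshold = 0.30, t0 = "t0", t1 = "t1",
                              negative_baseline = c("increasing", "exclude")) {
  negative_baseline <- match.arg(negative_baseline)
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single fraction in (0, 1)", call. = FALSE)
  }
  quant <- tibble::as_tibble(quant)
  required <- c("patient_id", "timepoint", "copies_per_ml", "status")
  missing_cols <- setdiff(required, names(quant))
  if (length(missing_cols) > 0L) {
    stop("quantification table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  wide <- quant |>
    dplyr::filter(.data$timepoint %in% c(t0, t1)) |>
    dplyr::mutate(.tp = dplyr::if_else(.data$timepoint == t0, "t0", "t1")) |>
    dplyr::select("patient_id", ".tp", "copies_per_ml", "status") |>
    tidyr::pivot_wider(names_from = ".tp",
                       values_from = c("copies_per_ml", "status"),
                       names_glue = "{.value}_{.tp}") |>
    dplyr::rename(copies_t0 = "copies_per_ml_t0", copies_t1 = "copies_per_ml_t1")

  for (col in c("copies_t0", "copies_t1")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  for (col in c("status_t0", "status_t1")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_character_
  }

  wide |>
    dplyr::mutate(
      excluded_reason = dplyr::case_when(
        is.na(.data$status_t0) | is.na(.data$status_t1) ~ "missing timepoint",
        .data$status_t0 == "invalid" | .data$status_t1 == "invalid" ~
          "invalid measurement",
        .data$status_t0 == "negative" & .data$status_t1 == "positive" &
          negative_baseline == "exclude" ~ "negative baseline",
        .default = NA_character_
      ),
      relative_change = dplyr::case_when(
        !is.na(.data$excluded_reason) ~ NA_real_,
        .data$status_t0 != "positive" ~ NA_real_,
        .data$status_t1 == "negative" ~ -1,
        .default = (.data$copies_t1 - .data$copies_t0) / .data$copies_t0
      ),
      category = dplyr::case_when(
        !is.na(.data$excluded_reason) ~ NA_character_,
        .data$status_t0 == "negative" & .data$status_t1 == "negative" ~ "negative",
        .data$status_t0 == "negative" & .data$status_t1 == "positive" ~ "increasing",
        .data$relative_change < -threshold ~ "decreasing",
        .data$relative_change > threshold ~ "increasing",
        .default = "stable"
      ),
      threshold = threshold
    ) |>
    dplyr::select("patient_id", "copies_t0", "copies_t1", "status_t0",
                  "status_t1", "relative_change", "category", "threshold",
                  "excluded_reason")
}

#' Collapse dynamics categories to the binary decrease / no-decrease grouping
#'
#' Two grouping conventions are used in the survival comparisons:
#' `exclude_negative` compares decrease vs no-decrease (increase + stable)
#' among patients with detectable ctDNA, leaving plasma-negative patients
#' out; `include_negative` folds the negative patients into the no-decrease
#' arm.
#'
#' @param calls Dynamics table from [classify_dynamics()].
#' @param convention `"exclude_negative"` or `"include_negative"`.
#' @return The input tibble with an added `group` column
#'   (`"decrease"` / `"no_decrease"`, `NA` when the patient is excluded
#'   under the convention) and an `excluded` logical column.
#' @examples
#' calls <- tibble::tibble(patient_id = 1:3,
#'                         category = c("decreasing", "stable", "negative"),
#'                         excluded_reason = NA_character_)
#' group_binary(calls, "exclude_negative")
#' @export
group_binary <- function(calls,
                         convention = c("exclude_negative", "include_negative")) {
  convention <- match.arg(convention)
  calls <- tibble::as_tibble(calls)
  if (!"category" %in% names(calls)) {
    stop("`calls` must contain a `category` column", call. = FALSE)
  }
  no_decrease <- if (convention == "exclude_negative") {
    c("increasing", "stable")
  } else {
    c("increasing", "stable", "negative")
  }
  calls |>
    dplyr::mutate(
      group = dplyr::case_when(
        .data$category == "decreasing" ~ "decrease",
        .data$category %in% no_decrease ~ "no_decrease",
        .default = NA_character_
      ),
      excluded = is.na(.data$group),
      convention = convention
    )
}

#' Classify dynamics under several change thresholds
#'
#' Repeats [classify_dynamics()] at each threshold (the assay-derived 30%
#' plus more stringent alternatives such as 40% and 50%). Because a larger
#' threshold is strictly harder to cross, the decreasing set at a larger
#' threshold is always a subset of that at a smaller one.
#'
#' @inheritParams classify_dynamics
#' @param thresholds Numeric vector of fractions in (0, 1).
#' @return A tibble: the [classify_dynamics()] output stacked over
#'   thresholds, distinguished by the `threshold` column.
#' @export
threshold_sweep <- function(quant, thresholds = c(0.30, 0.40, 0.50),
                            t0 = "t0", t1 = "t1",
                            negative_baseline = c("increasing", "exclude")) {
  negative_baseline <- match.arg(negative_baseline)
  if (any(thresholds <= 0) || any(thresholds >= 1)) {
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  purrr::map(thresholds, function(th) {
    classify_dynamics(quant, threshold = th, t0 = t0, t1 = t1,
                      negative_baseline = negative_baseline)
  }) |>
    purrr::list_rbind()
}
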