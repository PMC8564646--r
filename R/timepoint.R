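#' Detect the early on-treatment ctDNA spike
#'
#' Responding patients frequently show a transient rise in ctDNA within
#' the first ~2 weeks of treatment — tumor DNA released by early cell
#' death — before levels fall. A series is called `spike` when any
#' observation inside the window exceeds baseline by more than the change
#' threshold; `unevaluable` when the baseline is not positive or no sample
#' falls inside the window.
#'
#' @param series Long-format tibble for one or more patients: columns
#'   `patient_id`, `week`, `copies_per_ml`, `status`; a week-0 baseline row
#'   per patient is required.
#' @param spike_window_weeks Window after treatment start, weeks.
#' @param threshold Relative-increase threshold (fraction).
#' @return A tibble with one row per patient: `patient_id`, `spike_call`
#'   in `c("spike", "no_spike", "unevaluable")`.
#' @export
detect_spike <- function(series, spike_window_weeks = 2, threshold = 0.30) {
  series <- tibble::as_tibble(series)
  series |>
    dplyr::arrange(.data$patient_id, .data$week) |>
    dplyr::summarise(
      spike_call = {
        base_i <- which(.data$week == 0)
        if (length(base_i) != 1L || .data$status[base_i] != "positive") {
          "unevaluable"
        } else {
          inside <- .data$week > 0 & .data$week <= spike_window_weeks &
            !is.na(.data$copies_per_ml)
          if (!any(inside)) {
            "unevaluable"
          } else if (any(.data$copies_per_ml[inside] >
                           (1 + threshold) * .data$copies_per_ml[base_i])) {
            "spike"
          } else {
            "no_spike"
          }
        }
      },
      .by = "patient_id"
    )
}

#' Align an irregular series to a target week
#'
#' Returns the observation nearest to `target_week` within
#' `± max_gap_weeks`; ties are broken toward the earlier observation;
#' absent (`NA`) when no observation falls inside the gap.
#'
#' @param weeks Observation weeks (strictly increasing within a patient).
#' @param values Copies/mL at those weeks.
#' @param target_week Candidate follow-up week.
#' @param max_gap_weeks Maximum tolerated distance, weeks.
#' @return The aligned copies/mL value, or `NA_real_`.
#' @examples
#' interpolate_at_week(c(0, 1, 4, 6), c(100, 180, 40, 30), 5, 1)
#' @export
interpolate_at_week <- function(weeks, values, target_week, max_gap_weeks = 1) {
  if (length(weeks) == 0L) stop("empty series", call. = FALSE)
  gap <- abs(weeks - target_week)
  ok <- which(gap <= max_gap_weeks & !is.na(values))
  if (length(ok) == 0L) return(NA_real_)
  # order() is stable, so the earlier observation wins ties
  ok[order(gap[ok])][1] |> (\(i) values[i])()
}

#' Responder / non-responder separation by candidate follow-up week
#'
#' For each candidate week, classifies every evaluable patient's change
#' from baseline to that week (nearest observation within the alignment
#' gap) with the standard dynamics rule, then tabulates the fraction of
#' responders called decreasing and the fraction of non-responders called
#' non-decreasing. The recommended follow-up week maximises the sum of the
#' two fractions; it is only emitted when both groups are represented.
#'
#' @param series Long-format series as in [detect_spike()].
#' @param responses Tibble `patient_id`, `responder` (logical; typically
#'   durable clinical benefit, or RECIST CR/PR).
#' @param candidate_weeks Weeks to evaluate.
#' @param threshold Relative-change threshold (fraction).
#' @param max_gap_weeks Alignment tolerance, weeks.
#' @return A tibble with one row per candidate week: `week`,
#'   `n_responders`, `responder_decrease_frac`, `n_nonresponders`,
#'   `nonresponder_nondecrease_frac`, `separation` (the sum). The
#'   recommended week is attached as attribute `"recommended_week"`
#'   (`NA` when either group is empty at every week).
#' @export
separation_by_timepoint <- function(series, responses,
                                    candidate_weeks = c(1, 2, 4, 6),
                                    threshold = 0.30, max_gap_weeks = 1) {
  series <- tibble::as_tibble(series)
  responses <- tibble::as_tibble(responses)

  baselines <- series |>
    dplyr::filter(.data$week == 0) |>
    dplyr::select("patient_id", base_copies = "copies_per_ml",
                  base_status = "status")

  per_week <- purrr::map(candidate_weeks, function(w) {
    aligned <- series |>
      dplyr::filter(.data$week > 0) |>
      dplyr::summarise(
        value = interpolate_at_week(.data$week, .data$copies_per_ml, w,
                                    max_gap_weeks),
        status_w = {
          i <- which(abs(.data$week - w) <= max_gap_weeks &
                       !is.na(.data$copies_per_ml))
          if (length(i) == 0L) NA_character_
          else .data$status[i[order(abs(.data$week[i] - w))][1]]
        },
        .by = "patient_id"
      )
    quant <- dplyr::bind_rows(
      baselines |>
        dplyr::transmute(.data$patient_id, timepoint = "t0",
                         copies_per_ml = .data$base_copies,
                         status = .data$base_status),
      aligned |>
        dplyr::filter(!is.na(.data$status_w)) |>
        dplyr::transmute(.data$patient_id, timepoint = "t1",
                         copies_per_ml = .data$value, status = .data$status_w)
    )
    classify_dynamics(quant, threshold = threshold) |>
      dplyr::mutate(week = w)
  }) |> purrr::list_rbind()

  tab <- per_week |>
    dplyr::inner_join(responses, by = "patient_id") |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::summarise(
      n_responders = sum(.data$responder),
      responder_decrease_frac =
        ifelse(sum(.data$responder) > 0,
               mean(.data$category[.data$responder] == "decreasing"), NA_real_),
      n_nonresponders = sum(!.data$responder),
      nonresponder_nondecrease_frac =
        ifelse(sum(!.data$responder) > 0,
               mean(.data$category[!.data$responder] != "decreasing"), NA_real_),
      .by = "week"
    ) |>
    dplyr::mutate(separation = .data$responder_decrease_frac +
                    .data$nonresponder_nondecrease_frac)

  eligible <- tab |>
    dplyr::filter(.data$n_responders > 0, .data$n_nonresponders > 0,
                  !is.na(.data$separation))
  rec <- if (nrow(eligible) > 0L) {
    eligible$week[which.max(eligible$separation)]
  } else {
    NA_real_
  }
  attr(tab, "recommended_week") <- rec
  class(tab) <- c("ctdna_separation", class(tab))
  tab
}
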