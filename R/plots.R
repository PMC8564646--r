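#' Kaplan-Meier plot of a survival endpoint by group
#'
#' @param data Data frame with the time, event and group columns.
#' @param time,event,group Column names (strings).
#' @param xlab,ylab Axis labels.
#' @return A ggplot object with step survival curves per group.
#' @export
plot_km <- function(data, time = "pfs_weeks", event = "pfs_event",
                    group = "group", xlab = "Weeks since start of ICI",
                    ylab = "Survival probability") {
  data <- tibble::as_tibble(data)
  curves <- split(data, data[[group]]) |>
    purrr::imap(function(g, nm) {
      km <- km_curve(g[[time]], g[[event]])
      dplyr::bind_rows(
        tibble::tibble(time = 0, survival = 1),
        dplyr::select(km, "time", "survival")
      ) |> dplyr::mutate(group = nm)
    }) |>
    purrr::list_rbind()
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = xlab, y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Spider plot of percent change in ctDNA from baseline
#'
#' One line per patient tracking the percent change in mutant copies/mL
#' relative to the week-0 baseline; the dashed reference lines mark the
#' +30%/-30% dynamics thresholds. Patients without a positive baseline are
#' omitted.
#'
#' @param series Long-format series (`patient_id`, `week`,
#'   `copies_per_ml`, `status`).
#' @param threshold Reference threshold fraction to draw.
#' @return A ggplot object.
#' @export
plot_spider <- function(series, threshold = 0.30) {
  series <- tibble::as_tibble(series)
  traj <- series |>
    dplyr::mutate(
      baseline = .data$copies_per_ml[.data$week == 0][1],
      .by = "patient_id"
    ) |>
    dplyr::filter(!is.na(.data$baseline), .data$baseline > 0,
                  !is.na(.data$copies_per_ml)) |>
    dplyr::mutate(pct_change = 100 * (.data$copies_per_ml / .data$baseline - 1))
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$week, y = .data$pct_change,
                                     group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = c(-100 * threshold, 100 * threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Weeks since start of ICI",
                  y = "Change in mutant ctDNA from baseline (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a survival endpoint report
#'
#' @param object A `ctdna_endpoints` object.
#' @param endpoint `"pfs"` or `"os"`.
#' @param comparison `"four_level"` (dynamics categories) or `"binary"`
#'   (decrease vs no-decrease, plasma-negative excluded).
#' @param ... Unused.
#' @return A ggplot KM plot.
#' @method autoplot ctdna_endpoints
#' @export
autoplot.ctdna_endpoints <- function(object, endpoint = c("pfs", "os"),
                                     comparison = c("four_level", "binary"),
                                     ...) {
  endpoint <- match.arg(endpoint)
  comparison <- match.arg(comparison)
  d <- object$data
  d$group <- if (comparison == "four_level") {
    d$category
  } else {
    dplyr::case_when(
      d$category == "decreasing" ~ "decrease",
      d$category %in% c("increasing", "stable") ~ "no_decrease",
      .default = NA_character_
    )
  }
  d <- dplyr::filter(d, !is.na(.data$group))
  plot_km(d, time = paste0(endpoint, "_weeks"),
          event = paste0(endpoint, "_event"), group = "group",
          ylab = if (endpoint == "pfs") "Progression-free survival"
                 else "Overall survival")
}

#' Autoplot a timepoint-separation table
#'
#' @param object Output of [separation_by_timepoint()].
#' @param ... Unused.
#' @return A ggplot of the responder/non-responder separation fractions by
#'   candidate week.
#' @method autoplot ctdna_separation
#' @export
autoplot.ctdna_separation <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("responder_decrease_frac", "nonresponder_nondecrease_frac"),
    names_to = "metric", values_to = "fraction"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$week, y = .data$fraction,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Candidate follow-up week", y = "Fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
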