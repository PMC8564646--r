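#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survivor function, with the median taken
#' as the earliest time at which survival drops to 0.5 or below. When the
#' curve never crosses 0.5 the median is undefined ("not reached").
#'
#' @param time Event/censoring times in weeks, non-negative.
#' @param event Event indicator: 1 = event observed, 0 = censored.
#' @return A tibble of curve points (`time`, `n_risk`, `n_event`,
#'   `survival`) with the median (weeks, or `NA` if not reached) attached
#'   as attribute `"median"`; also retrievable via [km_median()].
#' @examples
#' km <- km_curve(c(1, 2, 3, 4, 5), rep(1, 5))
#' attr(km, "median")
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0L) stop("no survival records", call. = FALSE)
  if (any(time < 0)) stop("times must be non-negative", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    survival = fit$surv
  )
  med <- unname(summary(fit)$table["median"])
  attr(out, "median") <- if (is.na(med)) NA_real_ else med
  out
}

#' @rdname km_curve
#' @export
km_median <- function(time, event) {
  attr(km_curve(time, event), "median")
}

#' Mantel-Cox log-rank test
#'
#' Compares survival between two or more groups with the standard log-rank
#' (Mantel-Cox) statistic: at each distinct event time the observed events
#' per group are compared with their hypergeometric expectation.
#'
#' @param time,event As in [km_curve()].
#' @param group Group label per record (>= 2 levels present).
#' @return A one-row tibble: `statistic` (chi-square), `df`, `p_value`.
#' @examples
#' logrank_test(c(1, 2, 3, 10, 11, 12), rep(1, 6), rep(c("a", "b"), each = 3))
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) {
    stop("log-rank test needs at least two groups", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  tibble::tibble(
    statistic = sd$chisq,
    df = df,
    p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  )
}

#' Univariate Cox proportional-hazards model for a binary grouping
#'
#' Fits a single-covariate Cox model by partial-likelihood maximisation
#' with Breslow tie handling and reports the hazard ratio of the second
#' factor level relative to the first with a Wald 95% confidence interval.
#' Monotone likelihoods (complete separation of event times) are flagged
#' rather than raised.
#'
#' @param time,event As in [km_curve()].
#' @param group Two-level covariate; the first factor level is the
#'   reference.
#' @return A one-row tibble: `term`, `hr`, `ci_lower`, `ci_upper`,
#'   `p_value`, `converged`.
#' @examples
#' cox_hr(c(5, 6, 20, 22, 8, 30), c(1, 1, 1, 0, 1, 1),
#'        rep(c("no_decrease", "decrease"), each = 3))
#' @export
cox_hr <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) {
    stop("cox_hr() expects a two-level grouping", call. = FALSE)
  }
  ok <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ group, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w))) {
        ok <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  tibble::tibble(
    term = paste(levels(group)[2], "vs", levels(group)[1]),
    hr = exp(beta),
    ci_lower = exp(beta - 1.96 * se),
    ci_upper = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    converged = ok
  )
}

#' Durable clinical benefit from progression-free survival
#'
#' Durable clinical benefit (DCB) is at least stable disease lasting six
#' months, operationalised as remaining progression-free for at least 26
#' weeks from treatment start. Patients censored before the threshold are
#' indeterminate and are excluded from DCB-rate denominators.
#'
#' @param pfs_weeks Progression-free survival in weeks.
#' @param pfs_event 1 = progression/death observed, 0 = censored.
#' @param threshold_weeks DCB landmark, default 26 weeks.
#' @return Character vector in `c("true", "false", "indeterminate")`.
#' @examples
#' durable_clinical_benefit(c(30, 10, 12), c(1, 1, 0))
#' @export
durable_clinical_benefit <- function(pfs_weeks, pfs_event, threshold_weeks = 26) {
  if (any(pfs_weeks < 0)) stop("PFS times must be non-negative", call. = FALSE)
  dplyr::case_when(
    pfs_weeks >= threshold_weeks ~ "true",
    pfs_event == 1 ~ "false",
    .default = "indeterminate"
  )
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The p-value is exact (full
#' enumeration) for small tie-free samples (`n_a + n_b <= 16`) and uses the
#' normal approximation with tie and continuity correction otherwise.
#'
#' @param a,b Numeric samples.
#' @return A one-row tibble: `u` (the U statistic for `a` vs `b`),
#'   `p_value` (two-sided), `exact`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 16 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  tibble::tibble(u = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

group_section <- function(df, time_col, event_col) {
  groups <- split(df, as.character(df$group))
  medians <- purrr::imap(groups, function(g, nm) {
    tibble::tibble(group = nm, n = nrow(g),
                   n_events = sum(g[[event_col]]),
                   median_weeks = km_median(g[[time_col]], g[[event_col]]))
  }) |> purrr::list_rbind()
  lr <- if (length(groups) >= 2L && sum(df[[event_col]]) > 0) {
    logrank_test(df[[time_col]], df[[event_col]], df$group)
  } else {
    NULL
  }
  list(medians = medians, logrank = lr)
}

#' Stratified survival endpoint report
#'
#' Reproduces the full comparison structure of the monitoring analysis on
#' a clinical table joined to a dynamics table:
#'
#' * PFS and OS by the 4-level dynamics category
#'   (decreasing / stable / increasing / negative);
#' * PFS and OS for decrease vs no-decrease excluding plasma-negative
#'   patients, with log-rank tests, Cox hazard ratios and DCB rates (the
#'   DCB-rate difference assessed by a rank test on the benefit indicator);
#' * the same binary comparison within PD-L1 TPS strata (TPS >= 1% vs
#'   < 1%), with negative patients folded into the no-decrease arm.
#'
#' @param clinical Data frame with columns `patient_id`, `pfs_weeks`,
#'   `pfs_event`, `os_weeks`, `os_event` and optionally `tps_stratum`
#'   (levels `"<1%"`, `"1-49%"`, `">=50%"`, `"unavailable"`).
#' @param dynamics Dynamics table from [classify_dynamics()].
#' @param dcb_weeks Durable-clinical-benefit landmark in weeks.
#' @return An object of class `ctdna_endpoints`: a list with elements
#'   `four_level`, `binary` (exclude-negative convention) and `tps`
#'   (include-negative convention within TPS strata), each holding
#'   per-group KM medians and the associated tests, plus `dcb` rates, and
#'   the joined analysis table in `$data`. Has [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
endpoint_report <- function(clinical, dynamics, dcb_weeks = 26) {
  clinical <- tibble::as_tibble(clinical)
  required <- c("patient_id", "pfs_weeks", "pfs_event", "os_weeks", "os_event")
  missing_cols <- setdiff(required, names(clinical))
  if (length(missing_cols) > 0L) {
    stop("clinical table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"tps_stratum" %in% names(clinical)) {
    clinical$tps_stratum <- "unavailable"
  }
  joined <- dplyr::inner_join(
    clinical,
    dplyr::select(tibble::as_tibble(dynamics), "patient_id", "category"),
    by = "patient_id"
  ) |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::mutate(
      dcb = durable_clinical_benefit(.data$pfs_weeks, .data$pfs_event, dcb_weeks)
    )

  # 4-level comparison
  four <- joined |> dplyr::mutate(group = .data$category)
  four_level <- list(
    pfs = group_section(four, "pfs_weeks", "pfs_event"),
    os = group_section(four, "os_weeks", "os_event")
  )

  # binary, negatives excluded
  bin <- joined |>
    dplyr::mutate(group = dplyr::case_when(
      .data$category == "decreasing" ~ "decrease",
      .data$category %in% c("increasing", "stable") ~ "no_decrease",
      .default = NA_character_
    )) |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::mutate(group = factor(.data$group, c("no_decrease", "decrease")))
  binary <- list(
    pfs = group_section(bin, "pfs_weeks", "pfs_event"),
    os = group_section(bin, "os_weeks", "os_event"),
    hr_pfs = if (nlevels(droplevels(bin$group)) == 2L)
      cox_hr(bin$pfs_weeks, bin$pfs_event, bin$group) else NULL,
    hr_os = if (nlevels(droplevels(bin$group)) == 2L)
      cox_hr(bin$os_weeks, bin$os_event, bin$group) else NULL,
    dcb = dcb_rates(bin)
  )

  # TPS strata, negatives folded into no-decrease
  tps_data <- joined |>
    dplyr::mutate(
      group = dplyr::if_else(.data$category == "decreasing",
                             "decrease", "no_decrease"),
      group = factor(.data$group, c("no_decrease", "decrease")),
      tps_bin = dplyr::case_when(
        .data$tps_stratum %in% c("1-49%", ">=50%") ~ ">=1%",
        .data$tps_stratum == "<1%" ~ "<1%",
        .default = NA_character_
      )
    ) |>
    dplyr::filter(!is.na(.data$tps_bin))
  tps <- purrr::map(split(tps_data, tps_data$tps_bin), function(sub) {
    two <- nlevels(droplevels(sub$group)) == 2L
    list(
      pfs = group_section(sub, "pfs_weeks", "pfs_event"),
      os = group_section(sub, "os_weeks", "os_event"),
      hr_pfs = if (two) cox_hr(sub$pfs_weeks, sub$pfs_event, sub$group) else NULL,
      hr_os = if (two) cox_hr(sub$os_weeks, sub$os_event, sub$group) else NULL,
      dcb = dcb_rates(sub)
    )
  })

  structure(
    list(four_level = four_level, binary = binary, tps = tps,
         dcb_weeks = dcb_weeks, data = joined),
    class = "ctdna_endpoints"
  )
}

dcb_rates <- function(df) {
  evaluable <- dplyr::filter(df, .data$dcb != "indeterminate")
  rates <- evaluable |>
    dplyr::summarise(
      n = dplyr::n(),
      n_dcb = sum(.data$dcb == "true"),
      dcb_rate = mean(.data$dcb == "true"),
      .by = "group"
    )
  p <- NA_real_
  grp <- droplevels(as.factor(evaluable$group))
  if (nlevels(grp) == 2L) {
    ind <- as.numeric(evaluable$dcb == "true")
    split_ind <- split(ind, grp)
    if (stats::var(ind) > 0) {
      p <- mann_whitney_u(split_ind[[1]], split_ind[[2]])$p_value
    }
  }
  list(rates = rates, p_value = p)
}

#' @export
print.ctdna_endpoints <- function(x, ...) {
  cat("ctDNA dynamics survival endpoint report\n")
  cat("  patients analysed:", nrow(x$data), "\n")
  cat("  DCB landmark:", x$dcb_weeks, "weeks\n\n")
  cat("Decrease vs no-decrease (plasma-negative excluded):\n")
  print(x$binary$pfs$medians)
  if (!is.null(x$binary$pfs$logrank)) {
    cat(sprintf("  PFS log-rank p = %.3g\n", x$binary$pfs$logrank$p_value))
  }
  if (!is.null(x$binary$hr_pfs)) {
    with(x$binary$hr_pfs, cat(sprintf(
      "  PFS HR (%s) = %.2f [%.2f-%.2f]\n", term, hr, ci_lower, ci_upper)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-group endpoint summaries
#'
#' @param x A `ctdna_endpoints` object.
#' @param ... Unused.
#' @return A tibble with one row per comparison x endpoint x group:
#'   medians, event counts, and (for binary comparisons) hazard ratios.
#' @method tidy ctdna_endpoints
#' @export
tidy.ctdna_endpoints <- function(x, ...) {
  section_rows <- function(section, comparison) {
    purrr::imap(section[c("pfs", "os")], function(s, ep) {
      dplyr::mutate(s$medians, endpoint = ep, comparison = comparison,
                    logrank_p = if (is.null(s$logrank)) NA_real_ else s$logrank$p_value)
    }) |> purrr::list_rbind()
  }
  rows <- dplyr::bind_rows(
    section_rows(x$four_level, "four_level"),
    section_rows(x$binary, "binary_exclude_negative"),
    purrr::imap(x$tps, function(s, nm) {
      section_rows(s, paste0("tps_", nm))
    }) |> purrr::list_rbind()
  )
  hrs <- dplyr::bind_rows(
    if (!is.null(x$binary$hr_pfs))
      dplyr::mutate(x$binary$hr_pfs, endpoint = "pfs",
                    comparison = "binary_exclude_negative"),
    if (!is.null(x$binary$hr_os))
      dplyr::mutate(x$binary$hr_os, endpoint = "os",
                    comparison = "binary_exclude_negative"),
    purrr::imap(x$tps, function(s, nm) {
      dplyr::bind_rows(
        if (!is.null(s$hr_pfs))
          dplyr::mutate(s$hr_pfs, endpoint = "pfs", comparison = paste0("tps_", nm)),
        if (!is.null(s$hr_os))
          dplyr::mutate(s$hr_os, endpoint = "os", comparison = paste0("tps_", nm))
      )
    }) |> purrr::list_rbind()
  )
  if (nrow(hrs) > 0L) {
    hrs <- dplyr::select(hrs, "comparison", "endpoint", "hr",
                         "ci_lower", "ci_upper", hr_p = "p_value")
    rows <- dplyr::left_join(rows, hrs, by = c("comparison", "endpoint"))
  }
  dplyr::relocate(tibble::as_tibble(rows), "comparison", "endpoint", "group")
}

#' One-row endpoint report summary
#'
#' @param x A `ctdna_endpoints` object.
#' @param ... Unused.
#' @return A one-row tibble: number of patients, PFS/OS log-rank p-values
#'   and hazard ratios for the binary decrease vs no-decrease comparison,
#'   and DCB rates per arm.
#' @method glance ctdna_endpoints
#' @export
glance.ctdna_endpoints <- function(x, ...) {
  rates <- x$binary$dcb$rates
  rate_of <- function(g) {
    r <- rates$dcb_rate[rates$group == g]
    if (length(r) == 1L) r else NA_real_
  }
  tibble::tibble(
    n = nrow(x$data),
    pfs_logrank_p = if (is.null(x$binary$pfs$logrank)) NA_real_
      else x$binary$pfs$logrank$p_value,
    os_logrank_p = if (is.null(x$binary$os$logrank)) NA_real_
      else x$binary$os$logrank$p_value,
    pfs_hr = if (is.null(x$binary$hr_pfs)) NA_real_ else x$binary$hr_pfs$hr,
    os_hr = if (is.null(x$binary$hr_os)) NA_real_ else x$binary$hr_os$hr,
    dcb_rate_decrease = rate_of("decrease"),
    dcb_rate_no_decrease = rate_of("no_decrease"),
    dcb_p = x$binary$dcb$p_value
  )
}
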