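#' Simulate droplet counts for a ddPCR well
#'
#' Forward model of droplet partitioning: each of `n_droplets` droplets is
#' independently positive in the mutant channel with probability
#' \eqn{1 - e^{-c_m V_d}} (and analogously for the wildtype channel), then
#' flipped positive with a small per-droplet false-positive rate.
#'
#' @param mut_conc,wt_conc True template concentrations, copies/µL of
#'   reaction. Vectorised (recycled to a common length, one well each).
#' @param n_droplets Accepted droplets per well.
#' @param droplet_volume Droplet volume, µL.
#' @param false_positive_rate Per-droplet false-positive probability,
#'   in `[0, 0.001]`.
#' @param seed Optional integer seed; when given, results are reproducible.
#' @return A tibble with columns `mutant_positive`, `wildtype_positive`,
#'   `total_droplets`.
#' @examples
#' sim_well_counts(10, 1000, seed = 1)
#' @export
sim_well_counts <- function(mut_conc, wt_conc, n_droplets = 15000,
                            droplet_volume = 8.5e-4,
                            false_positive_rate = 0, seed = NULL) {
  if (any(mut_conc < 0) || any(wt_conc < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (any(false_positive_rate < 0) || any(false_positive_rate > 0.001)) {
    stop("false_positive_rate must lie in [0, 0.001]", call. = FALSE)
  }
  if (any(n_droplets < 1)) stop("n_droplets must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  k <- max(length(mut_conc), length(wt_conc))
  mut_conc <- rep_len(mut_conc, k)
  wt_conc <- rep_len(wt_conc, k)
  n <- rep_len(n_droplets, k)
  p_mut <- 1 - exp(-mut_conc * droplet_volume)
  p_wt <- 1 - exp(-wt_conc * droplet_volume)
  fp <- false_positive_rate
  tibble::tibble(
    mutant_positive = stats::rbinom(k, n, p_mut + (1 - p_mut) * fp),
    wildtype_positive = stats::rbinom(k, n, p_wt + (1 - p_wt) * fp),
    total_droplets = n
  )
}

#' Cohort simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults emulate the
#' study conditions the analysis assumes: a lognormal baseline ctDNA
#' burden; five kinetic archetypes (CR, PR, SD, PD, ctDNA-negative) with a
#' ~31% plasma-negative fraction; a transient early spike in 70% of
#' responders; 30% technical coefficient of variation on every
#' measurement; group-dependent exponential PFS/OS anchored on the
#' decrease vs no-decrease medians; and the cohort's PD-L1 TPS
#' distribution (34% / 17% / 35% / 14% unavailable), drawn independently
#' of ctDNA dynamics.
#'
#' @param archetype_mix Named proportions over
#'   `c(CR, PR, SD, PD, ctDNA_negative)`; must sum to 1.
#' @param baseline_log_mean,baseline_log_sd Lognormal parameters of the
#'   baseline mutant copies/mL among plasma-positive patients.
#' @param spike_probability Probability that a responder (CR/PR) shows the
#'   early spike.
#' @param spike_amplitude Multiplicative spike height.
#' @param spike_week Last week at which the spike multiplier applies.
#' @param decay_rate Named per-week multiplicative decay for `CR` and `PR`.
#' @param growth_rate Per-week multiplicative growth for `PD`.
#' @param technical_cv Technical coefficient of variation of a measurement.
#' @param median_pfs_by_group,median_os_by_group Named median PFS/OS in
#'   weeks per archetype.
#' @param censor_week Administrative censoring time, weeks.
#' @param tps_probs Named proportions over
#'   `c("<1%", "1-49%", ">=50%", "unavailable")`.
#' @param wt_copies_per_ml Background wildtype ccfDNA level, copies/mL.
#' @param lod_copies_per_ml Detection floor for series observations,
#'   copies/mL (the plasma-level equivalent of the 3-droplet rule at
#'   15,000 droplets).
#' @param n_droplets Droplets per simulated well.
#' @param sampling_weeks Longitudinal sampling schedule, weeks.
#' @param t1_week Follow-up week used for the two-timepoint droplet tables.
#' @param constants An [assay_constants()] object.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    archetype_mix = c(CR = 0.05, PR = 0.20, SD = 0.14, PD = 0.30,
                      ctDNA_negative = 0.31),
    baseline_log_mean = log(100), baseline_log_sd = 1.5,
    spike_probability = 0.70, spike_amplitude = 2, spike_week = 1,
    decay_rate = c(CR = 0.45, PR = 0.70),
    growth_rate = 1.2,
    technical_cv = 0.30,
    median_pfs_by_group = c(CR = 85, PR = 43, SD = 6, PD = 6,
                            ctDNA_negative = 12),
    median_os_by_group = c(CR = 150, PR = 125, SD = 29, PD = 29,
                           ctDNA_negative = 60),
    censor_week = 260,
    tps_probs = c("<1%" = 0.34, "1-49%" = 0.17, ">=50%" = 0.35,
                  "unavailable" = 0.14),
    wt_copies_per_ml = 2000,
    lod_copies_per_ml = 9.4,
    n_droplets = 15000,
    sampling_weeks = c(0, 1, 2, 4, 6, 12, 18, 24),
    t1_week = 4,
    constants = assay_constants()) {
  if (abs(sum(archetype_mix) - 1) > 1e-9) {
    stop("archetype_mix proportions must sum to 1", call. = FALSE)
  }
  if (abs(sum(tps_probs) - 1) > 1e-9) {
    stop("tps_probs must sum to 1", call. = FALSE)
  }
  if (technical_cv < 0) stop("technical_cv must be >= 0", call. = FALSE)
  if (any(median_pfs_by_group <= 0) || any(median_os_by_group <= 0)) {
    stop("group medians must be positive", call. = FALSE)
  }
  nms <- names(archetype_mix)
  if (any(median_os_by_group[nms] < median_pfs_by_group[nms])) {
    stop("median OS cannot be below median PFS for any group", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_config")
}

# lognormal multiplicative noise with unit mean and the given CV
cv_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one patient's longitudinal ctDNA trajectory
#'
#' The expected level at week `w` is
#' `baseline * rate^w * spike_amplitude^[0 < w <= spike_week]`, where
#' `rate` is the archetype's decay (CR, PR), 1 (SD) or growth (PD)
#' factor; each observation is then multiplied by lognormal technical
#' noise with the configured CV. Observations below the detection floor
#' are reported negative with absent copies; the ctDNA-negative archetype
#' is negative throughout.
#'
#' @param archetype One of `"CR"`, `"PR"`, `"SD"`, `"PD"`,
#'   `"ctDNA_negative"`.
#' @param baseline_copies Baseline mutant copies/mL (ignored for the
#'   negative archetype).
#' @param spiked Whether this patient shows the early spike.
#' @param config A [cohort_config()].
#' @param seed Optional integer seed.
#' @return A tibble: `week`, `copies_per_ml` (`NA` below the detection
#'   floor), `status`.
#' @export
simulate_patient_series <- function(archetype, baseline_copies, spiked = FALSE,
                                    config = cohort_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  weeks <- config$sampling_weeks
  n <- length(weeks)
  if (archetype == "ctDNA_negative") {
    return(tibble::tibble(week = weeks, copies_per_ml = NA_real_,
                          status = "negative"))
  }
  rate <- switch(archetype,
    CR = unname(config$decay_rate["CR"]),
    PR = unname(config$decay_rate["PR"]),
    SD = 1,
    PD = unname(config$growth_rate),
    stop("unknown archetype: ", archetype, call. = FALSE)
  )
  level <- baseline_copies * rate^weeks
  if (spiked) {
    level <- level * ifelse(weeks > 0 & weeks <= config$spike_week,
                            config$spike_amplitude, 1)
  }
  observed <- level * cv_noise(n, config$technical_cv)
  detected <- observed >= config$lod_copies_per_ml
  tibble::tibble(
    week = weeks,
    copies_per_ml = dplyr::if_else(detected, observed, NA_real_),
    status = dplyr::if_else(detected, "positive", "negative")
  )
}

#' Simulate a full synthetic monitoring cohort
#'
#' Generates all linked inputs of the pipeline: per-well droplet-count
#' tables at baseline and follow-up, the longitudinal copies/mL series, a
#' clinical table (exponential PFS per archetype, OS as PFS plus an
#' exponential remainder, administrative censoring, RECIST label, PD-L1
#' TPS drawn independently of dynamics), and a truth manifest for
#' parameter-recovery tests.
#'
#' @param n_patients Cohort size.
#' @param config A [cohort_config()].
#' @param seed Integer seed; identical seeds reproduce the cohort exactly.
#' @return A list of class `ctdna_cohort` with tibbles `droplets`,
#'   `series`, `clinical`, `truth` and the `config`.
#' @examples
#' cohort <- simulate_cohort(20, seed = 1)
#' head(cohort$droplets)
#' @export
simulate_cohort <- function(n_patients = 100, config = cohort_config(),
                            seed = NULL) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  archetypes <- names(config$archetype_mix)
  truth <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n_patients)),
    archetype = sample(archetypes, n_patients, replace = TRUE,
                       prob = config$archetype_mix),
    baseline_copies = stats::rlnorm(n_patients, config$baseline_log_mean,
                                    config$baseline_log_sd),
    spiked = stats::runif(n_patients) < config$spike_probability &
      archetype %in% c("CR", "PR"),
    tps_stratum = sample(names(config$tps_probs), n_patients, replace = TRUE,
                         prob = config$tps_probs)
  )
  truth$baseline_copies[truth$archetype == "ctDNA_negative"] <- 0
  truth$responder <- truth$archetype %in% c("CR", "PR")

  # longitudinal series
  series <- purrr::map2(truth$archetype, seq_len(n_patients), function(arch, i) {
    simulate_patient_series(arch, truth$baseline_copies[i],
                            spiked = truth$spiked[i], config = config) |>
      dplyr::mutate(patient_id = truth$patient_id[i], .before = 1)
  }) |> purrr::list_rbind()

  # droplet tables at t0 and t1 from the observed (noisy) series levels
  plasma_to_rxn <- config$constants$reaction_volume *
    (config$constants$eluate_volume / config$constants$eluate_in_reaction) /
    config$constants$plasma_volume
  two_tp <- series |>
    dplyr::filter(.data$week %in% c(0, config$t1_week)) |>
    dplyr::mutate(
      timepoint = dplyr::if_else(.data$week == 0, "t0", "t1"),
      true_copies = dplyr::coalesce(.data$copies_per_ml, 0)
    )
  counts <- sim_well_counts(
    mut_conc = two_tp$true_copies / plasma_to_rxn,
    wt_conc = config$wt_copies_per_ml / plasma_to_rxn,
    n_droplets = config$n_droplets,
    droplet_volume = config$constants$droplet_volume
  )
  droplets <- dplyr::bind_cols(
    dplyr::select(two_tp, "patient_id", "timepoint"),
    well_id = "w1",
    counts
  ) |> dplyr::arrange(.data$patient_id, .data$timepoint)

  # clinical endpoints: exponential PFS, OS = PFS + exponential remainder
  med_pfs <- config$median_pfs_by_group[truth$archetype]
  med_os <- config$median_os_by_group[truth$archetype]
  pfs_true <- stats::rexp(n_patients, rate = log(2) / med_pfs)
  os_extra <- stats::rexp(n_patients, rate = log(2) / pmax(med_os - med_pfs, 1e-6))
  os_true <- pfs_true + os_extra
  cw <- config$censor_week
  clinical <- tibble::tibble(
    patient_id = truth$patient_id,
    pfs_weeks = pmin(pfs_true, cw),
    pfs_event = as.integer(pfs_true < cw),
    os_weeks = pmin(os_true, cw),
    os_event = as.integer(os_true < cw),
    recist_response = dplyr::if_else(truth$archetype == "ctDNA_negative",
                                     "PD", truth$archetype),
    tps_stratum = truth$tps_stratum
  )
  truth$pfs_weeks_true <- pfs_true
  truth$os_weeks_true <- os_true

  structure(
    list(droplets = droplets, series = series, clinical = clinical,
         truth = truth, config = config),
    class = "ctdna_cohort"
  )
}

#' @export
print.ctdna_cohort <- function(x, ...) {
  cat("synthetic ctDNA monitoring cohort:", nrow(x$truth), "patients\n")
  print(dplyr::count(x$truth, .data$archetype))
  invisible(x)
}
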