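#' Assay constants for back-calculating plasma concentrations
#'
#' Bundles the physical volumes of the ddPCR workflow used to convert a
#' per-reaction template concentration (copies/µL of reaction) into mutant
#' copies per mL of the original plasma sample:
#' \deqn{copies/mL = c_{rxn} \times V_{rxn} \times (V_{elu} / V_{in}) / V_{pl}}
#'
#' Defaults reflect a QX200-style workflow: 0.85 nL droplets, a 20 µL
#' reaction loaded with 13 µL of a 52 µL ccfDNA eluate extracted from 2 mL
#' of plasma.
#'
#' @param droplet_volume Volume of a single droplet in µL.
#' @param reaction_volume Total ddPCR reaction volume in µL.
#' @param eluate_volume Volume the ccfDNA was eluted in, µL.
#' @param eluate_in_reaction Volume of eluate loaded into the reaction, µL.
#' @param plasma_volume Plasma volume extracted, mL.
#' @return An object of class `assay_constants` (a named list).
#' @examples
#' assay_constants()
#' assay_constants(plasma_volume = 4)
#' @export
assay_constants <- function(droplet_volume = 8.5e-4,
                            reaction_volume = 20,
                            eluate_volume = 52,
                            eluate_in_reaction = 13,
                            plasma_volume = 2) {
  vals <- c(droplet_volume = droplet_volume, reaction_volume = reaction_volume,
            eluate_volume = eluate_volume, eluate_in_reaction = eluate_in_reaction,
            plasma_volume = plasma_volume)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all assay constants must be strictly positive", call. = FALSE)
  }
  if (eluate_in_reaction > eluate_volume) {
    stop("eluate_in_reaction cannot exceed eluate_volume", call. = FALSE)
  }
  if (reaction_volume < eluate_in_reaction) {
    stop("reaction_volume cannot be smaller than eluate_in_reaction", call. = FALSE)
  }
  structure(as.list(vals), class = "assay_constants")
}

#' Poisson-corrected template concentration from droplet counts
#'
#' In ddPCR the template is partitioned into droplets; at mean occupancy
#' \eqn{\lambda} copies per droplet, a droplet is positive with probability
#' \eqn{1 - e^{-\lambda}}. Inverting the observed positive fraction gives
#' \eqn{\lambda = -\ln(1 - k/N)}, and dividing by the droplet volume yields
#' the concentration in copies per µL of reaction.
#'
#' @param k Positive-droplet count(s), `0 <= k < n`.
#' @param n Total accepted droplets, `>= 1`.
#' @param droplet_volume Droplet volume in µL.
#' @return Concentration(s) in copies per µL of reaction. Vectorised over
#'   `k` and `n`.
#' @examples
#' poisson_concentration(3, 330)
#' poisson_concentration(0, 15000)
#' @export
poisson_concentration <- function(k, n, droplet_volume = 8.5e-4) {
  if (length(droplet_volume) != 1L || !is.finite(droplet_volume) || droplet_volume <= 0) {
    stop("droplet_volume must be a single positive number", call. = FALSE)
  }
  if (any(n < 1)) stop("total droplet count must be >= 1", call. = FALSE)
  if (any(k < 0) || any(k > n)) {
    stop("positive-droplet count must satisfy 0 <= k <= n", call. = FALSE)
  }
  if (any(k == n)) {
    stop("all droplets positive: concentration is unbounded (saturated well)",
         call. = FALSE)
  }
  -log1p(-k / n) / droplet_volume
}

#' Pool replicate wells of one sample
#'
#' Replicate wells for the same patient and timepoint are merged by summing
#' droplet counts before Poisson correction, the standard merged-well
#' practice (lower variance than averaging per-well concentrations).
#'
#' @param wells A data frame with columns `patient_id`, `timepoint`,
#'   `mutant_positive`, `wildtype_positive`, `total_droplets` describing
#'   wells of a single sample.
#' @return A one-row tibble with the summed counts.
#' @examples
#' merge_wells(tibble::tibble(
#'   patient_id = "P1", timepoint = "t0",
#'   mutant_positive = c(1, 2), wildtype_positive = c(100, 120),
#'   total_droplets = c(10000, 11000)
#' ))
#' @export
merge_wells <- function(wells) {
  wells <- tibble::as_tibble(wells)
  if (nrow(wells) == 0L) stop("no wells to merge", call. = FALSE)
  if (dplyr::n_distinct(wells$patient_id) != 1L ||
      dplyr::n_distinct(wells$timepoint) != 1L) {
    stop("merge_wells() expects wells from a single patient and timepoint",
         call. = FALSE)
  }
  dplyr::summarise(
    wells,
    mutant_positive = sum(.data$mutant_positive),
    wildtype_positive = sum(.data$wildtype_positive),
    total_droplets = sum(.data$total_droplets),
    .by = c("patient_id", "timepoint")
  )
}

#' Back-calculate mutant copies per mL plasma
#'
#' @param conc_rxn Concentration in copies per µL of reaction (`>= 0`).
#' @param constants An [assay_constants()] object.
#' @return Copies per mL plasma; linear in `conc_rxn`.
#' @examples
#' copies_per_ml_plasma(10, assay_constants())
#' @export
copies_per_ml_plasma <- function(conc_rxn, constants = assay_constants()) {
  if (!inherits(constants, "assay_constants")) {
    stop("`constants` must be created by assay_constants()", call. = FALSE)
  }
  if (any(conc_rxn < 0)) stop("concentration must be non-negative", call. = FALSE)
  conc_rxn * constants$reaction_volume *
    (constants$eluate_volume / constants$eluate_in_reaction) /
    constants$plasma_volume
}

#' Variant allele frequency from channel concentrations
#'
#' @param conc_mut Mutant-channel concentration, copies/µL.
#' @param conc_wt Wildtype-channel concentration, copies/µL.
#' @return Mutant fraction in `[0, 1]`; `NA` when both concentrations are 0
#'   (no template observed, fraction undefined).
#' @examples
#' variant_allele_frequency(5, 5)
#' variant_allele_frequency(0, 0)
#' @export
variant_allele_frequency <- function(conc_mut, conc_wt) {
  if (any(conc_mut < 0) || any(conc_wt < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  total <- conc_mut + conc_wt
  dplyr::if_else(total > 0, conc_mut / total, NA_real_)
}

#' Call sample positivity from droplet counts
#'
#' A sample is positive when at least 3 mutant droplets are detected;
#' negative when fewer than 3 mutant droplets are seen among at least 330
#' informative (mutant + wildtype positive) droplets, which bounds the
#' analytical sensitivity below 1%; otherwise there are too few informative
#' droplets to claim negativity and the sample is invalid. Downstream
#' stages must treat invalid as missing, never as negative.
#'
#' @param mutant_positive Mutant-positive droplet count(s).
#' @param informative_droplets Informative droplet count(s),
#'   mutant + wildtype positive.
#' @param min_mutant_droplets Positivity threshold (droplets).
#' @param min_informative Negativity requirement (informative droplets).
#' @return Character vector in `c("positive", "negative", "invalid")`.
#' @examples
#' call_sample_status(c(3, 2, 2), c(100, 400, 200))
#' @export
call_sample_status <- function(mutant_positive, informative_droplets,
                               min_mutant_droplets = 3,
                               min_informative = 330) {
  if (any(mutant_positive < 0) || any(informative_droplets < 0)) {
    stop("droplet counts must be non-negative", call. = FALSE)
  }
  if (any(mutant_positive > informative_droplets)) {
    stop("mutant-positive droplets cannot exceed informative droplets",
         call. = FALSE)
  }
  dplyr::case_when(
    mutant_positive >= min_mutant_droplets ~ "positive",
    informative_droplets >= min_informative ~ "negative",
    .default = "invalid"
  )
}

#' Limit of detection implied by the positivity rule
#'
#' The smallest callable mutant fraction given that positivity requires
#' `min_positive_droplets` mutant droplets among `informative_droplets`
#' informative droplets: the Poisson-corrected droplet fraction
#' \eqn{-\ln(1 - k/n)}. At the rule's 3-of-330 this is ~0.91%, i.e. an
#' analytical sensitivity below 1%.
#'
#' @param min_positive_droplets Mutant droplets required for positivity.
#' @param informative_droplets Informative droplets available.
#' @return Minimal callable mutant fraction (not a percentage);
#'   monotonically decreasing in `informative_droplets`.
#' @examples
#' limit_of_detection(3, 330)
#' @export
limit_of_detection <- function(min_positive_droplets, informative_droplets) {
  if (any(min_positive_droplets <= 0) || any(informative_droplets <= 0)) {
    stop("droplet counts must be positive", call. = FALSE)
  }
  if (any(min_positive_droplets > informative_droplets)) {
    stop("required droplets cannot exceed informative droplets", call. = FALSE)
  }
  if (any(min_positive_droplets == informative_droplets)) {
    stop("all droplets positive: fraction saturates (log of zero)", call. = FALSE)
  }
  -log1p(-min_positive_droplets / informative_droplets)
}

#' Quantify mutant ctDNA from a droplet-count table
#'
#' The main quantification entry point: pools replicate wells per patient
#' and timepoint, Poisson-corrects both channels, back-calculates mutant
#' copies per mL plasma, computes the variant allele frequency, and applies
#' the positivity/negativity rules.
#'
#' @param wells Data frame of per-well droplet counts with columns
#'   `patient_id`, `timepoint`, `mutant_positive`, `wildtype_positive`,
#'   `total_droplets` (a `well_id` column is allowed and ignored).
#' @param constants An [assay_constants()] object.
#' @param validate Warn when a well's total droplet count falls outside the
#'   plausible 10,000-20,000 emulsification range.
#' @inheritParams call_sample_status
#' @return A tibble with one row per patient x timepoint: the pooled counts,
#'   `informative_droplets`, `lambda_mut` (mean mutant copies per droplet),
#'   `conc_mut`/`conc_wt` (copies/µL reaction), `copies_per_ml` (mutant
#'   copies per mL plasma), `vaf`, and `status`.
#' @examples
#' wells <- tibble::tibble(
#'   patient_id = "P1", timepoint = c("t0", "t1"),
#'   mutant_positive = c(40, 5), wildtype_positive = c(600, 610),
#'   total_droplets = 15000
#' )
#' quantify_wells(wells)
#' @export
quantify_wells <- function(wells, constants = assay_constants(),
                           validate = TRUE,
                           min_mutant_droplets = 3, min_informative = 330) {
  wells <- tibble::as_tibble(wells)
  required <- c("patient_id", "timepoint", "mutant_positive",
                "wildtype_positive", "total_droplets")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols) > 0L) {
    stop("droplet table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(wells) == 0L) stop("droplet table is empty", call. = FALSE)
  bad <- which(wells$mutant_positive > wells$total_droplets |
                 wells$wildtype_positive > wells$total_droplets |
                 wells$mutant_positive < 0 | wells$wildtype_positive < 0 |
                 wells$total_droplets < 1)
  if (length(bad) > 0L) {
    stop("malformed droplet counts in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (validate) {
    outside <- wells$total_droplets < 10000 | wells$total_droplets > 20000
    if (any(outside)) {
      warning(sum(outside), " well(s) outside the plausible 10,000-20,000 ",
              "droplet range", call. = FALSE)
    }
  }

  if (any(wells$mutant_positive == wells$total_droplets |
            wells$wildtype_positive == wells$total_droplets)) {
    stop("saturated well (all droplets positive in one channel): ",
         "concentration is unbounded", call. = FALSE)
  }

  pooled <- dplyr::summarise(
    wells,
    mutant_positive = as.numeric(sum(.data$mutant_positive)),
    wildtype_positive = as.numeric(sum(.data$wildtype_positive)),
    total_droplets = as.numeric(sum(.data$total_droplets)),
    .by = c("patient_id", "timepoint")
  )

  v_d <- constants$droplet_volume
  pooled |>
    dplyr::mutate(
      informative_droplets = .data$mutant_positive + .data$wildtype_positive,
      lambda_mut = -log1p(-.data$mutant_positive / .data$total_droplets),
      conc_mut = .data$lambda_mut / v_d,
      conc_wt = -log1p(-.data$wildtype_positive / .data$total_droplets) / v_d,
      copies_per_ml = copies_per_ml_plasma(.data$conc_mut, constants),
      vaf = variant_allele_frequency(.data$conc_mut, .data$conc_wt),
      status = call_sample_status(.data$mutant_positive,
                                  .data$informative_droplets,
                                  min_mutant_droplets, min_informative)
    )
}
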