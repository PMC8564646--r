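#' Read pipeline input tables
#'
#' Thin readers for the pipeline's delimited-text inputs (comma-separated,
#' header row, UTF-8, '.' decimal separator). Each checks the required
#' columns and reports what is missing.
#'
#' @param path Path to a CSV file.
#' @return A tibble.
#' @name pipeline-io
NULL

read_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0L) {
    stop(what, " file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl
}

#' @rdname pipeline-io
#' @export
read_droplet_table <- function(path) {
  read_checked(path, c("patient_id", "timepoint", "mutant_positive",
                       "wildtype_positive", "total_droplets"), "droplet")
}

#' @rdname pipeline-io
#' @export
read_clinical_table <- function(path) {
  read_checked(path, c("patient_id", "pfs_weeks", "pfs_event",
                       "os_weeks", "os_event"), "clinical")
}

#' @rdname pipeline-io
#' @export
read_series_table <- function(path) {
  read_checked(path, c("patient_id", "week", "copies_per_ml", "status"),
               "series")
}

#' Run the quantification stage on a droplet CSV
#'
#' @param droplet_csv Path to the per-well droplet-count table.
#' @param out Optional path to write the quantification table as CSV.
#' @inheritParams quantify_wells
#' @return The [quantify_wells()] tibble, invisibly written to `out` when
#'   given.
#' @export
run_quantify <- function(droplet_csv, constants = assay_constants(),
                         out = NULL, validate = TRUE) {
  quant <- quantify_wells(read_droplet_table(droplet_csv),
                          constants = constants, validate = validate)
  if (!is.null(out)) readr::write_csv(quant, out)
  quant
}

#' Run the dynamics-classification stage
#'
#' @param quant Quantification table (tibble or CSV path).
#' @inheritParams classify_dynamics
#' @param convention Binary grouping convention for the added `group`
#'   column.
#' @param out Optional output CSV path.
#' @return The classified dynamics tibble with binary grouping attached.
#' @export
run_classify <- function(quant, threshold = 0.30,
                         convention = c("exclude_negative", "include_negative"),
                         negative_baseline = c("increasing", "exclude"),
                         out = NULL) {
  convention <- match.arg(convention)
  if (is.character(quant) && length(quant) == 1L) {
    quant <- read_checked(quant, c("patient_id", "timepoint", "copies_per_ml",
                                   "status"), "quantification")
  }
  calls <- classify_dynamics(quant, threshold = threshold,
                             negative_baseline = match.arg(negative_baseline))
  calls <- group_binary(calls, convention)
  if (!is.null(out)) readr::write_csv(calls, out)
  calls
}

#' Run the survival stage
#'
#' @param clinical Clinical table (tibble or CSV path).
#' @param dynamics Dynamics table from [run_classify()] /
#'   [classify_dynamics()].
#' @inheritParams endpoint_report
#' @param out_dir Optional directory; when given, KM curve points are
#'   written as TSV and the endpoint summary as JSON.
#' @return The [endpoint_report()] object.
#' @export
run_survival <- function(clinical, dynamics, dcb_weeks = 26, out_dir = NULL) {
  if (is.character(clinical) && length(clinical) == 1L) {
    clinical <- read_clinical_table(clinical)
  }
  rep <- endpoint_report(clinical, dynamics, dcb_weeks = dcb_weeks)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    km <- rep$data |>
      dplyr::mutate(group = .data$category) |>
      (\(d) split(d, d$group))() |>
      purrr::imap(function(g, nm) {
        dplyr::mutate(km_curve(g$pfs_weeks, g$pfs_event), group = nm)
      }) |>
      purrr::list_rbind()
    readr::write_tsv(km, file.path(out_dir, "km_pfs_four_level.tsv"))
    jsonlite::write_json(endpoint_summary_list(rep),
                         file.path(out_dir, "endpoints.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  rep
}

endpoint_summary_list <- function(rep) {
  sec <- function(s) {
    out <- list(medians = s$medians)
    if (!is.null(s$logrank)) out$logrank <- as.list(s$logrank)
    for (nm in c("hr_pfs", "hr_os")) {
      if (!is.null(s[[nm]])) out[[nm]] <- as.list(s[[nm]])
    }
    if (!is.null(s$dcb)) {
      out$dcb <- list(rates = s$dcb$rates, p_value = s$dcb$p_value)
    }
    out
  }
  list(
    four_level = list(pfs = sec(rep$four_level$pfs), os = sec(rep$four_level$os)),
    binary_exclude_negative = list(
      pfs = sec(rep$binary$pfs),
      os = sec(rep$binary$os),
      hr_pfs = if (!is.null(rep$binary$hr_pfs)) as.list(rep$binary$hr_pfs),
      hr_os = if (!is.null(rep$binary$hr_os)) as.list(rep$binary$hr_os),
      dcb = list(rates = rep$binary$dcb$rates,
                 p_value = rep$binary$dcb$p_value)
    ),
    tps = purrr::map(rep$tps, function(s) {
      list(pfs = sec(s$pfs), os = sec(s$os),
           hr_pfs = if (!is.null(s$hr_pfs)) as.list(s$hr_pfs),
           hr_os = if (!is.null(s$hr_os)) as.list(s$hr_os),
           dcb = list(rates = s$dcb$rates, p_value = s$dcb$p_value))
    }),
    dcb_weeks = rep$dcb_weeks,
    n = nrow(rep$data)
  )
}

#' Simulate and write a full synthetic input set
#'
#' @inheritParams simulate_cohort
#' @param out_dir Directory to write `droplets.csv`, `series.csv`,
#'   `clinical.csv` and the truth manifest `truth.json`.
#' @return The [simulate_cohort()] object, invisibly.
#' @export
run_simulate <- function(out_dir, n_patients = 100, config = cohort_config(),
                         seed = NULL) {
  cohort <- simulate_cohort(n_patients, config = config, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$droplets, file.path(out_dir, "droplets.csv"))
  readr::write_csv(cohort$series, file.path(out_dir, "series.csv"))
  readr::write_csv(cohort$clinical, file.path(out_dir, "clinical.csv"))
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cohort)
}

#' Assemble a deterministic pipeline report
#'
#' Aggregates the stage outputs into a single list (serialisable to JSON):
#' quantification QC (status counts), the dynamics table, endpoint
#' summaries, and optional concordance and timepoint sections. The package
#' version and a hash of the configuration are embedded so a report is
#' traceable to the run that produced it.
#'
#' @param quant Quantification tibble.
#' @param dynamics Dynamics tibble.
#' @param endpoints A `ctdna_endpoints` object, or `NULL`.
#' @param concordance Optional [platform_concordance()] tibble.
#' @param timepoints Optional [separation_by_timepoint()] tibble.
#' @param config Optional configuration object to hash into the report.
#' @param out Optional JSON output path.
#' @return A named list.
#' @export
run_report <- function(quant, dynamics, endpoints = NULL, concordance = NULL,
                       timepoints = NULL, config = NULL, out = NULL) {
  report <- list(
    package_version = as.character(utils::packageVersion("ctdnadyn")),
    config_hash = rlang::hash(config),
    qc = list(
      n_samples = nrow(quant),
      status_counts = as.list(table(quant$status))
    ),
    dynamics = list(
      n_patients = nrow(dynamics),
      category_counts = as.list(table(dynamics$category, useNA = "no")),
      n_excluded = sum(!is.na(dynamics$excluded_reason))
    )
  )
  if (!is.null(endpoints)) report$endpoints <- endpoint_summary_list(endpoints)
  if (!is.null(concordance)) {
    report$concordance <- as.list(dplyr::select(concordance, -"excluded_ids"))
    report$concordance$excluded_ids <- concordance$excluded_ids[[1]]
  }
  if (!is.null(timepoints)) {
    report$timepoints <- list(
      table = timepoints,
      recommended_week = attr(timepoints, "recommended_week")
    )
  }
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}
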