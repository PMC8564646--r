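#' Squared Pearson correlation between paired platform measurements
#'
#' @param a,b Paired numeric vectors (copies/mL from each platform).
#' @return r-squared in `[0, 1]`; `NA` with a warning when either side has
#'   zero variance.
#' @examples
#' pearson_r2(1:10, 3 * (1:10) + 1)
#' @export
pearson_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors differ in length", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("zero variance on one platform: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b)^2
}

#' Cohen's kappa for categorical agreement
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with
#' the expected agreement \eqn{p_e} from the product of marginal
#' proportions; supports any number of categories. When both raters are
#' constant and identical (\eqn{p_e = 1}) the agreement is perfect and
#' kappa is defined as 1 by convention.
#'
#' @param calls_a,calls_b Equal-length categorical vectors over a shared
#'   label alphabet.
#' @return Kappa in `[-1, 1]`.
#' @examples
#' cohens_kappa(c("x", "x", "y"), c("x", "x", "y"))
#' @export
cohens_kappa <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) {
    stop("call vectors differ in length", call. = FALSE)
  }
  if (length(calls_a) < 2L) stop("need at least 2 paired calls", call. = FALSE)
  labels <- sort(unique(c(as.character(calls_a), as.character(calls_b))))
  a <- factor(as.character(calls_a), labels)
  b <- factor(as.character(calls_b), labels)
  tab <- table(a, b) / length(a)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (1 - p_e < .Machine$double.eps) {
    message("both raters constant and identical; kappa = 1 by convention")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Cross-platform concordance summary
#'
#' Agreement between two quantification platforms on paired samples:
#' squared Pearson correlation of copies/mL (overall and, optionally,
#' after excluding very-high-level samples above an explicit cutoff) and
#' Cohen's kappa on paired categorical dynamics calls when supplied.
#'
#' @param pairs Data frame with columns `sample_id`, `value_a`, `value_b`
#'   (copies/mL from each platform; pairs must be complete).
#' @param high_level_cutoff Optional copies/mL cutoff; pairs where either
#'   platform exceeds it are excluded from the secondary r-squared.
#' @param calls_a,calls_b Optional paired dynamics calls (e.g. binary
#'   decrease / no-decrease) for the kappa computation.
#' @return A tibble with `r2_all`, `r2_filtered`, `kappa`, `n_pairs`,
#'   `n_excluded`, and the excluded sample ids as a list column.
#' @export
platform_concordance <- function(pairs, high_level_cutoff = NULL,
                                 calls_a = NULL, calls_b = NULL) {
  pairs <- tibble::as_tibble(pairs)
  required <- c("sample_id", "value_a", "value_b")
  missing_cols <- setdiff(required, names(pairs))
  if (length(missing_cols) > 0L) {
    stop("paired table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyNA(pairs$value_a) || anyNA(pairs$value_b)) {
    stop("pairs must be complete (no missing side)", call. = FALSE)
  }
  if (any(pairs$value_a < 0) || any(pairs$value_b < 0)) {
    stop("copies/mL values must be non-negative", call. = FALSE)
  }

  r2_all <- pearson_r2(pairs$value_a, pairs$value_b)
  excluded_ids <- character(0)
  r2_filtered <- NA_real_
  if (!is.null(high_level_cutoff)) {
    keep <- pairs$value_a <= high_level_cutoff & pairs$value_b <= high_level_cutoff
    excluded_ids <- as.character(pairs$sample_id[!keep])
    if (sum(keep) >= 3L) {
      r2_filtered <- pearson_r2(pairs$value_a[keep], pairs$value_b[keep])
    }
  }
  kappa <- if (!is.null(calls_a) && !is.null(calls_b)) {
    cohens_kappa(calls_a, calls_b)
  } else {
    NA_real_
  }
  tibble::tibble(
    r2_all = r2_all,
    r2_filtered = r2_filtered,
    kappa = kappa,
    n_pairs = nrow(pairs),
    n_excluded = length(excluded_ids),
    excluded_ids = list(excluded_ids)
  )
}
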