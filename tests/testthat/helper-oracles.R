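# Independent brute-force oracles used to cross-check the survival wrappers.

# Direct evaluation of the Mantel-Cox observed-expected sums with the
# hypergeometric variance at each distinct event time (two groups).
oracle_logrank_chisq <- function(time, event, in_group1) {
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_group1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in_group1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(0)
  (O - E)^2 / V
}

# Exact two-sided Mann-Whitney p by full enumeration of label assignments.
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  idx <- utils::combn(n, length(a))
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  m <- length(a) * length(b)
  us <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  # two-sided: distance of U from its null mean
  mean(abs(us - m / 2) >= abs(u_obs - m / 2) - 1e-12)
}

# Hand product-limit estimator on (time, event) pairs.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    surv <- surv * (1 - d / n)
    out[i] <- surv
  }
  tibble::tibble(time = ts, survival = out)
}

# A small two-timepoint quantification table built directly from levels.
make_quant <- function(copies_t0, copies_t1, status_t0 = NULL, status_t1 = NULL,
                       ids = NULL) {
  n <- length(copies_t0)
  if (is.null(ids)) ids <- sprintf("P%02d", seq_len(n))
  if (is.null(status_t0)) status_t0 <- rep("positive", n)
  if (is.null(status_t1)) status_t1 <- rep("positive", n)
  tibble::tibble(
    patient_id = rep(ids, 2),
    timepoint = rep(c("t0", "t1"), each = n),
    copies_per_ml = c(copies_t0, copies_t1),
    status = c(status_t0, status_t1)
  )
}
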