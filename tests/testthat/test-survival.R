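test_that("KM curve matches the hand product-limit computation", {
  km <- km_curve(1:5, rep(1, 5))
  expect_equal(km$survival, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(attr(km, "median"), 3)
  # single event drops survival from 1 to 0
  one <- km_curve(10, 1)
  expect_equal(one$survival, 0)
  expect_equal(attr(one, "median"), 10)
  # all censored: flat at 1, median not reached
  flat <- km_curve(c(5, 8, 12), c(0, 0, 0))
  expect_true(all(flat$survival == 1))
  expect_true(is.na(attr(flat, "median")))
  expect_error(km_curve(numeric(0), numeric(0)), "no survival records")
})

test_that("KM on uncensored data equals the empirical survivor function", {
  set.seed(31)
  for (i in 1:5) {
    t <- round(rexp(40, 0.1), 1)
    km <- km_curve(t, rep(1, 40))
    oracle <- oracle_km(t, rep(1, 40))
    emp <- vapply(oracle$time, function(x) mean(t > x), numeric(1))
    expect_equal(km$survival, oracle$survival)
    expect_equal(oracle$survival, emp)
  }
})

test_that("log-rank statistic matches direct Mantel-Cox evaluation", {
  # symmetric input: statistic 0, p = 1
  t <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  lr <- logrank_test(t, rep(1, 6), g)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  # fully separated small groups vs the hand oracle
  t2 <- c(1, 2, 10, 11)
  lr2 <- logrank_test(t2, rep(1, 4), rep(c("a", "b"), each = 2))
  expect_equal(lr2$statistic,
               oracle_logrank_chisq(t2, rep(1, 4), c(TRUE, TRUE, FALSE, FALSE)))
  # random datasets vs the oracle, and invariance to common time rescaling
  set.seed(53)
  for (i in 1:10) {
    tt <- rexp(16)
    ee <- rbinom(16, 1, 0.8)
    gg <- rep(c("a", "b"), 8)
    lr3 <- logrank_test(tt, ee, gg)
    expect_equal(lr3$statistic, oracle_logrank_chisq(tt, ee, gg == "a"),
                 tolerance = 1e-8)
    expect_equal(logrank_test(tt * 52, ee, gg)$statistic, lr3$statistic)
  }
  expect_error(logrank_test(t, rep(1, 6), rep("a", 6)), "two groups")
})

test_that("Cox hazard ratio behaves at symmetric, tied and simulated inputs", {
  # identical groups: HR exactly 1
  t <- c(3, 7, 12, 20, 3, 7, 12, 20)
  e <- rep(1, 8)
  g <- rep(c("a", "b"), each = 4)
  fit <- cox_hr(t, e, g)
  expect_equal(fit$hr, 1, tolerance = 1e-6)
  # two tied events, one per group: partial likelihood maximised at beta = 0
  tied <- cox_hr(c(5, 5), c(1, 1), c("a", "b"))
  expect_equal(tied$hr, 1, tolerance = 1e-6)
  # label swap flips the sign of beta
  t2 <- c(2, 4, 9, 15, 3, 8, 18, 30)
  e2 <- rep(1, 8)
  g2 <- rep(c("x", "y"), each = 4)
  hr_a <- cox_hr(t2, e2, g2)
  hr_b <- cox_hr(t2, e2, factor(g2, levels = c("y", "x")))
  expect_equal(log(hr_a$hr), -log(hr_b$hr), tolerance = 1e-8)
  # time rescaling leaves the HR unchanged
  expect_equal(cox_hr(t2 * 7, e2, g2)$hr, hr_a$hr, tolerance = 1e-8)
  # consistency on simulated exponential data with true HR 0.5
  set.seed(61)
  n <- 500
  grp <- rep(c("ref", "treat"), each = n / 2)
  rate <- ifelse(grp == "ref", 1, 0.5)
  tt <- rexp(n, rate)
  est <- cox_hr(tt, rep(1, n), factor(grp, c("ref", "treat")))
  expect_gt(est$hr, 0.40)
  expect_lt(est$hr, 0.62)
  expect_true(est$converged)
  # complete separation is flagged, not raised
  sep <- cox_hr(c(1, 2, 3, 10, 11, 12), rep(1, 6), rep(c("a", "b"), each = 3))
  expect_false(sep$converged)
  expect_error(cox_hr(t, e, rep("a", 8)), "two-level")
})

test_that("durable clinical benefit partitions patients at the 26-week landmark", {
  expect_equal(durable_clinical_benefit(30, 1), "true")
  expect_equal(durable_clinical_benefit(10, 1), "false")
  expect_equal(durable_clinical_benefit(12, 0), "indeterminate")
  expect_equal(durable_clinical_benefit(26, 0), "true")
  set.seed(71)
  w <- runif(200, 0, 60)
  ev <- rbinom(200, 1, 0.6)
  dcb <- durable_clinical_benefit(w, ev)
  expect_true(all(dcb %in% c("true", "false", "indeterminate")))
  expect_true(all(w[dcb == "true"] >= 26 | ev[dcb == "true"] == 0))
  expect_true(all(w[dcb == "false"] < 26 & ev[dcb == "false"] == 1))
})

test_that("Mann-Whitney U matches exact enumeration for small samples", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$p_value, 0.1)
  expect_true(res$exact)
  expect_equal(res$p_value, oracle_mw_exact_p(c(1, 2, 3), c(4, 5, 6)))
  # identical multisets: U = n^2 / 2, p at the boundary
  same <- suppressMessages(mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(same$u, 8)
  expect_gte(same$p_value, 0.97)
  # the continuity-corrected normal approximation tracks the exact p to
  # about 0.02 at n = 8 + 8
  set.seed(83)
  for (i in 1:5) {
    a <- rnorm(8)
    b <- rnorm(8, 0.5)
    exact_p <- mann_whitney_u(a, b)$p_value
    approx_p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    )
    expect_lt(abs(exact_p - approx_p), 0.02)
    expect_equal(exact_p, oracle_mw_exact_p(a, b), tolerance = 1e-10)
  }
})

test_that("endpoint report reproduces the full comparison structure", {
  set.seed(97)
  cohort <- simulate_cohort(150, seed = 97)
  quant <- quantify_wells(cohort$droplets, validate = FALSE)
  calls <- classify_dynamics(quant)
  rep <- endpoint_report(cohort$clinical, calls)
  expect_s3_class(rep, "ctdna_endpoints")
  expect_true(all(c("pfs", "os") %in% names(rep$four_level)))
  expect_true(all(rep$binary$pfs$medians$group %in% c("decrease", "no_decrease")))
  expect_true(all(names(rep$tps) %in% c("<1%", ">=1%")))
  # planted ordering: decrease group outlives no-decrease on median PFS
  med <- rep$binary$pfs$medians
  expect_gt(med$median_weeks[med$group == "decrease"],
            med$median_weeks[med$group == "no_decrease"])
  td <- tidy(rep)
  expect_true(all(c("comparison", "endpoint", "group", "median_weeks",
                    "logrank_p", "hr") %in% names(td)))
  gl <- glance(rep)
  expect_equal(nrow(gl), 1L)
  expect_lt(gl$pfs_logrank_p, 0.05)
  expect_lt(gl$pfs_hr, 1)
  expect_gt(gl$dcb_rate_decrease, gl$dcb_rate_no_decrease)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(autoplot(rep, "os", "binary"), "ggplot")
})

test_that("endpoint report degrades gracefully on degenerate strata", {
  clinical <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:6),
    pfs_weeks = c(10, 20, 30, 40, 50, 60), pfs_event = 1,
    os_weeks = c(15, 25, 35, 45, 55, 65), os_event = 1,
    tps_stratum = "unavailable"
  )
  calls <- tibble::tibble(
    patient_id = clinical$patient_id,
    category = "decreasing",
    excluded_reason = NA_character_
  )
  rep <- endpoint_report(clinical, calls)
  expect_null(rep$four_level$pfs$logrank)   # single group: no pairwise test
  expect_null(rep$binary$hr_pfs)
  expect_equal(length(rep$tps), 0L)         # no TPS data: section empty
  expect_equal(nrow(glance(rep)), 1L)
})
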