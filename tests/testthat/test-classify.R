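test_that("relative_change is the signed fraction of baseline", {
  expect_equal(relative_change(100, 70), -0.30)
  expect_equal(relative_change(100, 131), 0.31)
  expect_equal(relative_change(50, 0), -1)
  expect_error(relative_change(0, 10), "strictly positive")
  expect_error(relative_change(10, -1), "non-negative")
})

test_that("dynamics classification follows the 30% rule with the boundary stable", {
  quant <- make_quant(
    copies_t0 = c(100, 100, 100, 100),
    copies_t1 = c(65, 70, 130, 130.01)
  )
  calls <- classify_dynamics(quant)
  expect_equal(calls$category, c("decreasing", "stable", "stable", "increasing"))
  expect_equal(calls$relative_change, c(-0.35, -0.30, 0.30, 0.3001))
})

test_that("negativity and invalidity conventions are honoured", {
  quant <- make_quant(
    copies_t0 = c(NA, NA, 120, 80),
    copies_t1 = c(NA, 90, NA, 90),
    status_t0 = c("negative", "negative", "positive", "invalid"),
    status_t1 = c("negative", "positive", "negative", "positive")
  )
  calls <- classify_dynamics(quant)
  expect_equal(calls$category[1], "negative")
  expect_equal(calls$category[2], "increasing")   # new detection at t1
  expect_equal(calls$category[3], "decreasing")   # cleared below LoD
  expect_equal(calls$relative_change[3], -1)
  expect_true(is.na(calls$category[4]))
  expect_equal(calls$excluded_reason[4], "invalid measurement")

  excl <- classify_dynamics(quant, negative_baseline = "exclude")
  expect_equal(excl$excluded_reason[2], "negative baseline")
  expect_true(is.na(excl$category[2]))
})

test_that("every non-excluded patient gets exactly one category and calls are scale-free", {
  set.seed(11)
  n <- 300
  status_pool <- c("positive", "negative", "invalid")
  quant <- make_quant(
    copies_t0 = runif(n, 1, 500),
    copies_t1 = runif(n, 0, 500),
    status_t0 = sample(status_pool, n, TRUE, prob = c(0.7, 0.2, 0.1)),
    status_t1 = sample(status_pool, n, TRUE, prob = c(0.7, 0.2, 0.1))
  )
  calls <- classify_dynamics(quant)
  ok <- is.na(calls$excluded_reason)
  expect_true(all(calls$category[ok] %in%
                    c("decreasing", "stable", "increasing", "negative")))
  expect_true(all(is.na(calls$category[!ok])))
  # positive rescaling of copies/mL leaves every call unchanged
  scaled <- quant
  scaled$copies_per_ml <- scaled$copies_per_ml * 37.5
  expect_equal(classify_dynamics(scaled)$category, calls$category)
})

test_that("binary grouping applies both conventions", {
  calls <- tibble::tibble(
    patient_id = 1:3,
    category = c("decreasing", "stable", "negative"),
    excluded_reason = NA_character_
  )
  excl <- group_binary(calls, "exclude_negative")
  expect_equal(excl$group, c("decrease", "no_decrease", NA))
  expect_equal(sum(excl$excluded), 1L)
  incl <- group_binary(calls, "include_negative")
  expect_equal(incl$group, c("decrease", "no_decrease", "no_decrease"))
  expect_equal(nrow(group_binary(calls[0, ], "exclude_negative")), 0L)
  expect_error(group_binary(calls, "bogus"))
})

test_that("threshold sweep reproduces single-threshold calls and is monotone", {
  quant <- make_quant(copies_t0 = c(100, 100), copies_t1 = c(55, 0.001))
  sweep <- threshold_sweep(quant, c(0.30, 0.40, 0.50))
  p1 <- sweep[sweep$patient_id == "P01", ]   # r = -0.45
  expect_equal(p1$category, c("decreasing", "decreasing", "stable"))
  p2 <- sweep[sweep$patient_id == "P02", ]   # r ~ -1
  expect_equal(p2$category, rep("decreasing", 3))
  expect_equal(threshold_sweep(quant, 0.30), classify_dynamics(quant))
  expect_error(threshold_sweep(quant, c(0.3, 1.2)), "\\(0, 1\\)")

  # property: decreasing set shrinks as the threshold grows
  set.seed(23)
  n <- 200
  rq <- make_quant(runif(n, 1, 300), runif(n, 0, 300))
  rs <- threshold_sweep(rq, c(0.30, 0.40, 0.50))
  dec <- lapply(split(rs, rs$threshold),
                function(d) d$patient_id[d$category == "decreasing"])
  expect_true(all(dec[["0.4"]] %in% dec[["0.3"]]))
  expect_true(all(dec[["0.5"]] %in% dec[["0.4"]]))
})
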