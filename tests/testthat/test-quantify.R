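test_that("poisson_concentration inverts droplet occupancy", {
  expect_identical(poisson_concentration(0, 15000, 8.5e-4), 0)
  # frozen high-precision evaluation of -ln(1 - 3/330) / 8.5e-4
  expect_equal(poisson_concentration(3, 330, 8.5e-4), 10.7440983097,
               tolerance = 1e-10)
  # strictly increasing in k at fixed N
  ks <- 0:500
  concs <- poisson_concentration(ks, 15000)
  expect_true(all(diff(concs) > 0))
  # agrees with the naive estimate within 1% when occupancy <= 1%
  k <- c(1, 50, 150)
  n <- 15000
  naive <- (k / n) / 8.5e-4
  expect_lt(max(abs(poisson_concentration(k, n) / naive - 1)), 0.01)
})

test_that("poisson_concentration rejects saturated and malformed wells", {
  expect_error(poisson_concentration(330, 330), "saturated")
  expect_error(poisson_concentration(5, 0), ">= 1")
  expect_error(poisson_concentration(-1, 100), "0 <= k")
  expect_error(poisson_concentration(101, 100), "0 <= k")
  expect_error(poisson_concentration(3, 330, droplet_volume = 0), "positive")
})

test_that("merge_wells pools replicate wells by summing counts", {
  wells <- tibble::tibble(
    patient_id = "P1", timepoint = "t0",
    mutant_positive = c(1, 2), wildtype_positive = c(100, 120),
    total_droplets = c(10000, 11000)
  )
  merged <- merge_wells(wells)
  expect_equal(merged$mutant_positive, 3)
  expect_equal(merged$wildtype_positive, 220)
  expect_equal(merged$total_droplets, 21000)
  # single well is its own merge
  expect_equal(merge_wells(wells[1, ])[, names(wells)], wells[1, ])
  expect_error(merge_wells(wells[0, ]), "no wells")
  mixed <- wells
  mixed$timepoint <- c("t0", "t1")
  expect_error(merge_wells(mixed), "single patient")
})

test_that("copies_per_ml_plasma applies the volume back-calculation linearly", {
  const <- assay_constants(reaction_volume = 20, eluate_volume = 52,
                           eluate_in_reaction = 13, plasma_volume = 2)
  expect_equal(copies_per_ml_plasma(10, const), 400)  # 10 * 20 * 4 / 2
  expect_equal(copies_per_ml_plasma(0, const), 0)
  x <- c(0.5, 1, 7, 100)
  expect_equal(copies_per_ml_plasma(x, const), x * copies_per_ml_plasma(1, const))
  expect_error(assay_constants(eluate_in_reaction = 0), "positive")
  expect_error(copies_per_ml_plasma(-1, const), "non-negative")
})

test_that("variant allele frequency is the mutant fraction of total copies", {
  expect_equal(variant_allele_frequency(5, 5), 0.5)
  expect_equal(variant_allele_frequency(0, 80), 0)
  expect_equal(variant_allele_frequency(10.74, 1052.3), 0.0101031,
               tolerance = 1e-6)
  expect_true(is.na(variant_allele_frequency(0, 0)))
  expect_error(variant_allele_frequency(-1, 5), "non-negative")
})

test_that("sample status rules partition every droplet-count input", {
  expect_equal(call_sample_status(3, 100), "positive")
  expect_equal(call_sample_status(2, 400), "negative")
  expect_equal(call_sample_status(2, 200), "invalid")
  # exactly one state for arbitrary (k, n)
  set.seed(7)
  n <- sample(0:2000, 500, replace = TRUE)
  k <- floor(runif(500) * (n + 1))
  status <- call_sample_status(k, n)
  expect_true(all(status %in% c("positive", "negative", "invalid")))
  expect_true(all((k >= 3) == (status == "positive")))
  expect_true(all((k < 3 & n >= 330) == (status == "negative")))
})

test_that("limit of detection matches the 3-of-330 sensitivity bound", {
  lod <- limit_of_detection(3, 330)
  expect_equal(lod, 0.00913248356, tolerance = 1e-8)
  expect_lt(lod, 0.01)
  # halves (to first order) when informative droplets double
  expect_equal(limit_of_detection(3, 660) / lod, 0.5, tolerance = 0.005)
  # monotonically decreasing in informative droplets
  lods <- limit_of_detection(3, seq(330, 5000, by = 10))
  expect_true(all(diff(lods) < 0))
  expect_error(limit_of_detection(330, 330), "saturates")
  expect_error(limit_of_detection(0, 330), "positive")
})

test_that("quantify_wells pools, quantifies and calls status per sample", {
  wells <- tibble::tibble(
    patient_id = c("P1", "P1", "P1", "P2"),
    timepoint = c("t0", "t0", "t1", "t0"),
    well_id = c("w1", "w2", "w1", "w1"),
    mutant_positive = c(2, 1, 0, 2),
    wildtype_positive = c(200, 180, 500, 100),
    total_droplets = c(15000, 15000, 15000, 15000)
  )
  quant <- quantify_wells(wells)
  expect_equal(nrow(quant), 3L)
  p1t0 <- quant[quant$patient_id == "P1" & quant$timepoint == "t0", ]
  expect_equal(p1t0$mutant_positive, 3)       # wells merged before correction
  expect_equal(p1t0$total_droplets, 30000)
  expect_equal(p1t0$status, "positive")
  expect_equal(p1t0$conc_mut, poisson_concentration(3, 30000))
  expect_equal(p1t0$copies_per_ml, copies_per_ml_plasma(p1t0$conc_mut))
  expect_equal(quant$status[quant$patient_id == "P1" &
                              quant$timepoint == "t1"], "negative")
  expect_equal(quant$status[quant$patient_id == "P2"], "invalid")
})

test_that("quantify_wells validates its input table", {
  wells <- tibble::tibble(
    patient_id = "P1", timepoint = "t0",
    mutant_positive = 3, wildtype_positive = 400, total_droplets = 5000
  )
  expect_warning(quantify_wells(wells), "10,000-20,000")
  expect_silent(quantify_wells(wells, validate = FALSE))
  expect_error(quantify_wells(wells[, -3]), "missing column")
  expect_error(quantify_wells(wells[0, ]), "empty")
  bad <- wells
  bad$mutant_positive <- 6000
  expect_error(quantify_wells(bad, validate = FALSE), "malformed")
  sat <- wells
  sat$wildtype_positive <- 5000
  expect_error(quantify_wells(sat, validate = FALSE), "saturated")
})
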