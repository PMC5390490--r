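test_that("14C assay arithmetic reproduces the protocol example", {
  # 0.4662 kBq / 15.54 kBq umol-1 = 0.03 umol in 60 s over
  # 10 uL x 10 mg mL-1 = 0.1 mg TSP -> 0.30 umol mg-1 min-1
  raw <- assay_raw(0.4662, tsp_conc = 10)
  expect_equal(activity_from_counts(raw), 0.30)
  expect_equal(activity_from_counts(assay_raw(0, tsp_conc = 10)), 0)
  # doubling the reaction time halves the per-minute rate
  slow <- assay_raw(0.4662, tsp_conc = 10, reaction_time = 120)
  expect_equal(activity_from_counts(slow), 0.15)
  expect_error(assay_raw(0.4, tsp_conc = 0), "tsp_conc")
})

test_that("activation state is the initial/total ratio with soft clip", {
  expect_equal(activation_state(0.31, 0.36), 0.31 / 0.36)
  expect_equal(activation_state(0.19, 0.44), 0.19 / 0.44)
  expect_equal(activation_state(0.36, 0.36), 1)
  expect_warning(s <- activation_state(0.37, 0.36), "clipped")
  expect_equal(s, 1)
  expect_error(activation_state(0.40, 0.36), "above")
  expect_error(activation_state(0.3, 0), "total")
})

test_that("activation state is invariant to assay normalisation", {
  # TSP concentration and aliquot volume cancel in the ratio
  set.seed(9)
  for (i in 1:10) {
    tsp <- runif(1, 2, 20)
    vol <- runif(1, 0.005, 0.02)
    k1 <- activity_from_counts(assay_raw(0.30, tsp_conc = tsp,
                                         aliquot_volume = vol))
    k2 <- activity_from_counts(assay_raw(0.45, tsp_conc = tsp,
                                         aliquot_volume = vol))
    expect_equal(activation_state(k1, k2), 0.30 / 0.45)
  }
})

test_that("densitometry inverts the purified-standard line", {
  cal <- data.frame(load = c(5, 10, 15), od = c(0.5, 1.0, 1.5))
  # od 0.75 -> 7.5 ug Rubisco over 15 ug TSP
  expect_equal(densitometry_amount(0.75, cal), 7.5 / 15)
  expect_equal(densitometry_amount(1.0, cal), 10 / 15)
  w <- capture_warnings(out <- densitometry_amount(0, cal))
  expect_match(w, "outside|clipped", all = TRUE)
  expect_equal(out, 0)
  bad <- data.frame(load = c(5, 10, 15), od = c(0.5, 1.5, 0.6))
  expect_error(densitometry_amount(0.75, bad), "linear")
})

test_that("activase amounts are relative to the control standard line", {
  std <- data.frame(load = c(5, 10, 15), signal = c(50, 100, 150))
  # identical per-ug signal as control -> 1; doubled -> 2
  expect_equal(rca_relative(60, std), 1)
  expect_equal(rca_relative(120, std), 2)
  expect_equal(rca_relative(c(60, 84), std), c(1, 1.4))
  bad <- std
  bad$signal[2] <- 160
  expect_error(rca_relative(60, bad), "monotone")
})

test_that("a synthetic blot with a 1.4x isoform increase reads back 1.4", {
  set.seed(31)
  per_ug <- 11.3  # arbitrary control per-ug signal
  std <- data.frame(load = c(5, 10, 15),
                    signal = per_ug * c(5, 10, 15) * (1 + rnorm(3, 0, 0.01)))
  sample_signal <- 1.4 * per_ug * 6
  expect_equal(rca_relative(sample_signal, std), 1.4, tolerance = 0.02)
})

test_that("biochemical Vcmax is the site-density x activation x kcat product", {
  # 2 g m-2 x 8 / 550000 = 2.909e-5 mol sites m-2
  expect_equal(vcmax_biochemical(2.0, 0.861, 2.1),
               2.0 * 8 / 550000 * 0.861 * 2.1 * 1e6)
  expect_equal(vcmax_biochemical(2.0, 0.861, 2.1), 52.6, tolerance = 0.01)
  expect_equal(vcmax_biochemical(2.0, 0, 2.1), 0)
  expect_equal(vcmax_biochemical(4.0, 0.861, 2.1),
               2 * vcmax_biochemical(2.0, 0.861, 2.1))
})

test_that("Vcmax is exactly multiplicative (log-additive)", {
  set.seed(13)
  for (i in 1:10) {
    d <- runif(1, 0.5, 4)
    a <- runif(1, 0.2, 1)
    kc <- runif(1, 1, 5)
    expect_equal(log(vcmax_biochemical(d, a, kc)),
                 log(vcmax_biochemical(1, 1, 1)) + log(d) + log(a) + log(kc))
  }
})

test_that("derive_biochem records which TSP-per-area source was used", {
  bio <- data.frame(
    species = "rice", irrigation = "WW", temperature = "control25",
    replicate_id = "r1", initial_activity = 0.31, total_activity = 0.36,
    rubisco_amount = 0.49, rca_total = 1, rca_large = 1, rca_small = 1)
  bio <- validate_biochem_records(bio)
  out <- derive_biochem(bio, tsp_area = 6)
  expect_equal(attr(out, "tsp_area_source"), "config-constant")
  expect_equal(out$rubisco_area_density, 0.49 * 6)
  expect_equal(out$Vcmax,
               vcmax_biochemical(0.49 * 6, 0.31 / 0.36, 2.1))
  bio$tsp_area <- 5
  out2 <- derive_biochem(bio)
  expect_equal(attr(out2, "tsp_area_source"), "measured-column")
  expect_equal(out2$rubisco_area_density, 0.49 * 5)
})
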