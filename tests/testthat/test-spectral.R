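test_that("Welch grid, resolution and error contract match the conventions", {
  rec <- sine_recording(10, fs = 250, duration = 60)
  ps <- welch_psd(rec)
  expect_equal(ps$df, 0.5)
  expect_equal(ps$freqs[1:4], c(0, 0.5, 1, 1.5))
  expect_false(ps$normalized)
  short <- sine_recording(10, fs = 250, duration = 3)
  expect_error(welch_psd(short), "too short")
  expect_error(welch_psd(rec, window_s = 2, overlap_s = 2), "overlap")
})

test_that("a DC signal concentrates all Welch power at the bottom of the grid", {
  rec <- recording(matrix(3, 1, 2000), fs = 250, region_labels = "r1",
                   hemisphere = "left")
  ps <- welch_psd(rec)
  expect_equal(which.max(ps$power[1, ]), 1)
  # Hann taper leaks DC only into the immediately adjacent bin
  expect_true(all(ps$power[1, ps$freqs > 0.5] < 1e-12 * ps$power[1, 1]))
})

test_that("a 10 Hz unit sinusoid peaks exactly at the 10.0 Hz bin", {
  ps <- welch_psd(sine_recording(10, fs = 250, duration = 60))
  expect_equal(ps$freqs[which.max(ps$power[1, ])], 10.0)
})

test_that("white-noise Welch spectra are flat in the mean (100 seeds)", {
  acc <- 0
  for (s in 1:100) {
    set.seed(600 + s)
    rec <- recording(matrix(rnorm(250 * 10), 1), fs = 250,
                     region_labels = "r1", hemisphere = "left")
    acc <- acc + welch_psd(rec)$power[1, ]
  }
  f <- welch_psd(sine_recording(1, duration = 10))$freqs
  m <- acc[f >= 1 & f <= 40] / 100
  expect_lt(max(m) / min(m), 1.5)
})

test_that("Welch total power matches the signal variance (Parseval)", {
  rec <- simulate_subject(cohort_spec(duration = 30, n_regions = 4),
                          "control", seed = 2)
  ps <- welch_psd(rec)
  tot <- rowSums(ps$power[, ps$freqs > 0]) * ps$df
  v <- apply(rec$data, 1, var)
  expect_true(all(abs(tot / v - 1) < 0.10))
})

test_that("relative power sums to one, zeroes out-of-band bins and guards misuse", {
  rec <- simulate_subject(cohort_spec(duration = 20, n_regions = 4),
                          "control", seed = 3)
  ps <- relative_power(welch_psd(rec))
  expect_true(all(abs(rowSums(ps$power) - 1) < 1e-9))
  expect_true(all(ps$power[, ps$freqs < 1 | ps$freqs > 47.5] == 0))
  expect_error(relative_power(ps), "already normalized")
  # scale invariance
  rec2 <- rec; rec2$data <- rec2$data * 1000
  ps2 <- relative_power(welch_psd(rec2))
  expect_equal(ps$power, ps2$power, tolerance = 1e-12)
})

test_that("two-bin toy spectrum normalizes to the expected proportions", {
  ps <- toy_spectrum(rbind(c(0.3, 0.1)), freqs = c(2, 3))
  rel <- relative_power(ps, norm_band = c(1, 4))
  expect_equal(unname(rel$power[1, ]), c(0.75, 0.25))
})

test_that("band power follows the inclusive bin-centre edge rule and is additive", {
  freqs <- seq(0, 20, by = 0.5)
  p <- matrix(runif(2 * length(freqs)), nrow = 2)
  ps <- relative_power(toy_spectrum(p, freqs), norm_band = c(1, 20))
  fast <- band_power(ps, fast_alpha_band())
  bins <- freqs >= 10 & freqs <= 11
  expect_equal(sum(bins), 3)                 # 10.0, 10.5, 11.0
  expect_equal(unname(fast), unname(rowSums(ps$power[, bins])))
  # additivity over disjoint non-edge-sharing bands
  b1 <- band_definition("a", 2, 5); b2 <- band_definition("b", 5.5, 9)
  u <- band_definition("u", 2, 9)
  expect_equal(band_power(ps, b1) + band_power(ps, b2), band_power(ps, u))
  # partition of unity
  parts <- list(band_definition("p1", 1, 9.5),
                band_definition("p2", 10, 20))
  expect_equal(unname(Reduce(`+`, lapply(parts, band_power, ps = ps))),
               rep(1, 2), tolerance = 1e-9)
  expect_error(band_power(ps, band_definition("x", 0.25, 2)), "outside")
  expect_error(band_power(welch_psd(sine_recording(10, duration = 10)),
                          fast_alpha_band()), "normalized")
})

test_that("a slow-alpha subject has more slow than fast band power posteriorly", {
  spec <- cohort_spec(duration = 30, alpha_peak_mean_control = 8,
                      alpha_peak_sd = 0)
  rec <- simulate_subject(spec, "control", seed = 9)
  ps <- relative_power(welch_psd(rec))
  occ <- which.max(dk68_parcellation()$weight)   # maximal-topography region
  expect_gt(band_power(ps, slow_alpha_band())[occ],
            band_power(ps, fast_alpha_band())[occ])
})

test_that("global band power averages subjects and regions with a 95% CI", {
  freqs <- seq(0, 20, by = 0.5)
  p <- matrix(rep(runif(length(freqs)), 2), nrow = 2, byrow = TRUE)
  ps1 <- relative_power(toy_spectrum(p, freqs), norm_band = c(1, 20))
  # single subject, identical regions: curve equals the region spectrum,
  # zero-width CI
  g1 <- global_band_power(list(ps1))
  sel <- freqs >= 1 & freqs <= 20
  expect_equal(g1$mean, unname(ps1$power[1, sel]))
  expect_equal(g1$ci_lo, g1$ci_hi)
  # two subjects: curve is the per-bin average
  p2 <- matrix(rep(runif(length(freqs)), 2), nrow = 2, byrow = TRUE)
  ps2 <- relative_power(toy_spectrum(p2, freqs), norm_band = c(1, 20))
  g2 <- global_band_power(list(ps1, ps2))
  expect_equal(g2$mean, unname((ps1$power[1, sel] + ps2$power[1, sel]) / 2))
  expect_error(global_band_power(list(ps1, toy_spectrum(p, freqs * 2,
                                                        normalized = TRUE))),
               "grid")
})

test_that("patient global curves peak at lower frequencies than controls (>=95/100)", {
  mc <- mc_results("alt")
  expect_gte(sum(mc$pat_argmax < mc$con_argmax), 95)
})
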