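# The synthetic-data generator: per-second cases, raw EEG, histogram counts.

noiseless_spec <- function(seed = 7) {
  case_spec(noise_sd = c(bsr = 0, sef = 0, emg = 0, rbr = 0, sfs = 0),
            bis_noise_sd = 0, outlier_fraction = 0, seed = seed)
}

test_that("noiseless generation is an exact fixed point of the model", {
  m <- default_bis_model()
  cs <- generate_case(noiseless_spec(), m)
  pred <- predict_bis(cs$samples, m)
  expect_equal(cs$samples$bis, pred$bis)
  expect_equal(cs$true_range, pred$range)
})

test_that("generated values respect their physical ranges", {
  cs <- generate_case(case_spec(seed = 3))
  s <- cs$samples
  expect_true(all(s$bis >= 0 & s$bis <= 98))
  expect_true(all(s$bsr >= 0 & s$bsr <= 100))
  expect_true(all(s$sqi >= 0 & s$sqi <= 100))
  expect_true(all(s$sef >= 0.5 & s$sef <= 30))
  expect_equal(nrow(s), sum(default_phase_plan()$duration_s))
})

test_that("a burst-suppression phase lands entirely in the isoelectric range", {
  plan <- data.frame(phase = "bs", duration_s = 120, bsr = 60, sef = 10,
                     emg = 28, rbr = -0.5, sfs = 2)
  cs <- generate_case(case_spec(phase_plan = plan, seed = 1))
  expect_true(all(cs$true_range == "0-21"))
})

test_that("an EMG spike mid-maintenance lifts BIS above 61 as on real monitors", {
  plan <- data.frame(
    phase = c("adequate", "emg_spike", "adequate"),
    duration_s = c(200, 120, 200),
    bsr = 0.5, sef = c(17, 25, 17), emg = c(30, 45, 30),
    rbr = c(-1.2, -1.0, -1.2), sfs = 1.3
  )
  cs <- generate_case(case_spec(phase_plan = plan, seed = 2))
  spike <- cs$samples$time_s > 240 & cs$samples$time_s <= 310
  before <- cs$samples$time_s <= 190
  expect_gt(stats::median(cs$samples$bis[spike]), 61)
  expect_lt(stats::median(cs$samples$bis[before]), 61)
})

test_that("datasets are reproducible and cover all five ranges", {
  d1 <- generate_dataset(3, case_spec(), seed = 5)
  d2 <- generate_dataset(3, case_spec(), seed = 5)
  expect_identical(d1, d2)
  pooled <- pool_samples(generate_dataset(2, case_spec(), seed = 6))
  expect_setequal(as.character(unique(bis_range_of(round(pooled$bis)))),
                  bis_range_labels())
  expect_error(generate_dataset(0), class = "bisre_argument_error")
})

test_that("case spec validation names the offending field", {
  expect_error(case_spec(outlier_fraction = 1.2), "outlier_fraction",
               class = "bisre_config_error")
  expect_error(case_spec(noise_sd = c(bsr = -1, sef = 0, emg = 0,
                                      rbr = 0, sfs = 0)),
               "noise_sd", class = "bisre_config_error")
  expect_error(case_spec(phase_plan = data.frame(duration_s = -5, bsr = 0,
                                                 sef = 10, emg = 30,
                                                 rbr = 0, sfs = 1)),
               "duration_s", class = "bisre_config_error")
})

test_that("synthesized EEG reproduces requested band powers", {
  for (seed in 1:20) {
    spec <- eeg_synthesis_spec(60, 256,
                               band_powers = list(c(1, 30, 100), c(30, 47, 5)),
                               seed = seed)
    seg <- synthesize_eeg(spec)
    ps <- power_spectrum(make_epochs(seg))
    lowband <- band_power(ps, 1, 30) * ps$df
    expect_equal(lowband, 100, tolerance = 0.1)
  }
})

test_that("suppression intervals stay below the suppression amplitude", {
  spec <- eeg_synthesis_spec(70, 256, suppression_intervals = list(c(10, 40)),
                             suppression_amplitude = 3, seed = 4)
  seg <- synthesize_eeg(spec)
  idx <- (10 * 256 + 1):(40 * 256)
  expect_lt(max(abs(seg$samples[idx])), 3)
  expect_gt(max(abs(seg$samples[-idx])), 3)
})

test_that("EEG synthesis rejects bands above Nyquist", {
  expect_error(eeg_synthesis_spec(10, 128, band_powers = list(c(70, 110, 1))),
               "Nyquist", class = "bisre_config_error")
})

test_that("synthetic histogram counts are reproducible with sharp rate jumps", {
  h1 <- generate_histogram_counts(seed = 9)
  h2 <- generate_histogram_counts(seed = 9)
  expect_identical(h1$counts, h2$counts)
  expect_gte(h1$total, 5e5 * 0.9)
  # a >= 3-fold jump at each boundary
  for (b in c(41, 61, 78)) {
    ratio <- h1$counts[b + 2] / h1$counts[b + 1]
    expect_true(ratio >= 3 * 0.7 || ratio <= 1 / (3 * 0.7))
  }
  expect_error(generate_histogram_counts(per_range_rates = c(1, 2, 0, 4)),
               class = "bisre_argument_error")
  expect_error(generate_histogram_counts(boundaries = c(50, 40),
                                         per_range_rates = c(1, 2, 3)),
               class = "bisre_argument_error")
})
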