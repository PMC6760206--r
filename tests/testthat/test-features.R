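# EEG feature extraction: detrending, epoching, spectra, bispectra and the
# five subparameters.

test_that("epoching reproduces the monitor's epoch counts", {
  fs <- 128
  seg30 <- sine_segment(10, 30, fs)
  seg15 <- sine_segment(10, 15, fs)
  seg2 <- sine_segment(10, 2, fs)
  expect_equal(nrow(make_epochs(seg30)$epochs), 57)
  expect_equal(nrow(make_epochs(seg15)$epochs), 27)
  expect_equal(nrow(make_epochs(seg2)$epochs), 1)
  expect_error(make_epochs(sine_segment(10, 1, fs)),
               class = "bisre_argument_error")
})

test_that("Savitzky-Golay detrending removes slow trends, keeps the passband", {
  fs <- 128
  n <- 10 * fs
  const <- detrend_eeg(eeg_segment(rep(10, n), fs))
  expect_lt(max(abs(const$samples)), 1e-8)
  ramp <- detrend_eeg(eeg_segment(seq(0, 100, length.out = n), fs))
  expect_lt(max(abs(ramp$samples)), 0.01 * 100)
  x <- sine_segment(10, 10, fs)
  kept <- detrend_eeg(x)
  expect_gt(stats::cor(kept$samples, x$samples), 0.99)
  expect_error(detrend_eeg(sine_segment(10, 0.1, fs), window_s = 1),
               class = "bisre_argument_error")
})

test_that("Blackman periodogram concentrates a sinusoid and stays flat for noise", {
  spec <- power_spectrum(make_epochs(sine_segment(10, 30, 128)))
  expect_gte(band_power(spec, 9.5, 10.5) / band_power(spec, 0, 64), 0.95)
  zero <- power_spectrum(make_epochs(eeg_segment(rep(0, 256), 128)))
  expect_true(all(zero$power == 0))
  # epoch averaging shrinks the variance of the bin estimates
  set.seed(2)
  x <- stats::rnorm(30 * 128)
  many <- power_spectrum(make_epochs(eeg_segment(x, 128)))
  one <- power_spectrum(make_epochs(eeg_segment(x[1:256], 128)))
  sel <- many$frequencies > 1 & many$frequencies < 60
  expect_lt(stats::var(many$power[sel]), stats::var(one$power[sel]))
})

test_that("total spectral power scales linearly with input variance", {
  set.seed(7)
  slopes <- replicate(20, {
    x <- stats::rnorm(30 * 128)
    p1 <- sum(power_spectrum(make_epochs(eeg_segment(x, 128)))$power)
    p4 <- sum(power_spectrum(make_epochs(eeg_segment(2 * x, 128)))$power)
    p4 / p1
  })
  expect_equal(mean(slopes), 4, tolerance = 0.05)
})

test_that("bispectrum detects quadratic phase coupling and rejects random phases", {
  fs <- 256
  t <- seq(1 / fs, 20, by = 1 / fs)
  locked <- cos(2 * pi * 6 * t + 0.3) + cos(2 * pi * 9 * t + 1.1) +
    cos(2 * pi * 15 * t + 0.3 + 1.1)
  b <- bispectrum(make_epochs(eeg_segment(locked, fs)))
  idx <- which(b$magnitude == max(b$magnitude, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(sort(c(b$frequencies[idx[1]], b$frequencies[idx[2]])), c(6, 9))

  set.seed(5)
  rand_mag <- function(n_epochs) {
    # independent phases per epoch: the triple product averages towards zero
    vals <- replicate(n_epochs, {
      ph <- stats::runif(3, 0, 2 * pi)
      tt <- seq(1 / fs, 2, by = 1 / fs)
      x <- cos(2 * pi * 6 * tt + ph[1]) + cos(2 * pi * 9 * tt + ph[2]) +
        cos(2 * pi * 15 * tt + ph[3])
      x
    })
    seg <- eeg_segment(as.vector(vals), fs)
    ep <- make_epochs(seg, overlap = 0)   # epoch-aligned independent phases
    bb <- bispectrum(ep)
    i6 <- which(bb$frequencies == 6)
    i9 <- which(bb$frequencies == 9)
    bb$magnitude[i6, i9]
  }
  expect_lt(rand_mag(60), rand_mag(4))

  zero <- bispectrum(make_epochs(eeg_segment(rep(0, 512), 256)))
  expect_true(all(zero$magnitude[!is.na(zero$magnitude)] == 0))
})

test_that("band power uses inclusive edges on the half-hertz grid", {
  flat <- flat_spectrum(1)
  expect_equal(band_power(flat, 30, 47), 35)
  expect_equal(band_power(flat, 11, 20), 19)
  expect_equal(band_power(flat, 0, 64), sum(flat$power))
  expect_error(band_power(flat, 20, 11), class = "bisre_argument_error")
})

test_that("RBR follows its log-ratio definition", {
  expect_equal(compute_rbr(flat_spectrum(1)), log10(35 / 19))
  tenfold <- flat_spectrum(0)
  tenfold$power[tenfold$frequencies >= 30 & tenfold$frequencies <= 47] <- 10
  tenfold$power[tenfold$frequencies >= 11 & tenfold$frequencies <= 20] <- 1
  expect_equal(compute_rbr(tenfold), 1 + log10(35 / 19))
  only_beta <- flat_spectrum(0)
  only_beta$power[only_beta$frequencies >= 11 & only_beta$frequencies <= 20] <- 1
  expect_error(compute_rbr(only_beta), class = "bisre_undefined_value")
})

test_that("SFS follows its bispectral log-ratio definition, with the sign switch", {
  fake_bispectrum <- function(cells) {
    f <- seq(0, 64, by = 0.5)
    m <- matrix(NA_real_, length(f), length(f))
    valid <- outer(f, f, function(a, b) a <= b & a + b <= 64)
    m[valid] <- 0
    for (cl in cells) {
      m[which.min(abs(f - cl[1])), which.min(abs(f - cl[2]))] <- cl[3]
    }
    structure(list(frequencies = f, magnitude = m, df = 0.5, n_epochs = 1),
              class = "bis_bispectrum")
  }
  # all mass at f1 + f2 = 42 Hz: numerator equals denominator
  b42 <- fake_bispectrum(list(c(18, 24, 5)))
  expect_equal(compute_sfs(b42), 0)
  # broad band carries 100x the fast band
  b100 <- fake_bispectrum(list(c(5, 10, 99), c(18, 24, 1)))
  expect_equal(compute_sfs(b100), 2)
  expect_equal(compute_sfs(b100, invert = TRUE), -2)
  # degenerate: an all-zero bispectrum has no defined ratio
  expect_error(compute_sfs(fake_bispectrum(list())),
               class = "bisre_undefined_value")
})

test_that("SEF is the 95% quantile frequency of the 0.5-30 Hz band", {
  expect_equal(compute_sef(point_mass_spectrum(10)), 10)
  flat <- flat_spectrum(1)
  expect_equal(compute_sef(flat), 28.5)   # 57th of 60 bins
  high_only <- flat_spectrum(0)
  high_only$power[high_only$frequencies > 30] <- 1
  expect_error(compute_sef(high_only), class = "bisre_undefined_value")
})

test_that("SEF is monotone under upward shifts of spectral mass", {
  base <- point_mass_spectrum(10, power = 1)
  for (f in seq(10, 28, by = 2)) {
    expect_gte(compute_sef(point_mass_spectrum(f)), compute_sef(base))
    base <- point_mass_spectrum(f)
  }
})

test_that("BSR counts suppressed subepochs in the trailing minute", {
  fs <- 128
  expect_equal(compute_bsr(eeg_segment(rep(0, 60 * fs), fs)), 100)
  expect_equal(compute_bsr(sine_segment(10, 60, fs, amplitude = 10)), 0)
  half <- eeg_segment(c(rep(0, 30 * fs),
                        10 * sin(2 * pi * 10 * seq(1 / fs, 30, by = 1 / fs))),
                      fs)
  expect_equal(compute_bsr(half), 50)
  expect_error(compute_bsr(sine_segment(10, 30, fs)),
               class = "bisre_argument_error")
})

test_that("BSR is scale-invariant above the suppression threshold", {
  seg <- sine_segment(10, 60, 128, amplitude = 8)
  for (k in c(1, 2, 10, 100)) {
    scaled <- eeg_segment(k * seg$samples, 128)
    expect_equal(compute_bsr(scaled), 0)
  }
})

test_that("EMG converts 70-110 Hz power to dB and demands adequate sampling", {
  spec <- eeg_synthesis_spec(60, 256, band_powers = list(c(1, 30, 100),
                                                         c(70, 110, 1)))
  seg <- synthesize_eeg(spec)
  expect_equal(compute_emg(seg), 40, tolerance = 0.1)   # 10 log10(1 / 1e-4)
  expect_equal(compute_emg(seg, reference_power = 1), 0, tolerance = 0.1)
  expect_error(compute_emg(sine_segment(10, 60, 128)),
               class = "bisre_capability_error")
})

test_that("per-second extraction windows the trailing EEG correctly", {
  spec <- eeg_synthesis_spec(120, 256,
                             band_powers = list(c(1, 12, 60), c(12, 25, 30),
                                                c(30, 47, 5), c(70, 110, 0.5)))
  seg <- synthesize_eeg(spec)
  sub <- extract_subparameters(seg)
  expect_equal(nrow(sub), 61)              # t = 60..120 s
  expect_equal(sub$time_s, 60:120)
  expect_lt(stats::sd(sub$sef), 1)         # stationary input, stable SEF
  expect_true(all(is.finite(sub$emg)))

  shifted <- seg
  shifted$start_time <- 1000
  sub2 <- extract_subparameters(shifted)
  expect_equal(sub2$time_s, sub$time_s + 1000)
  expect_equal(sub2$bsr, sub$bsr)
  expect_equal(sub2$sef, sub$sef)
})

test_that("fully suppressed EEG yields BSR 100 on every extracted sample", {
  spec <- eeg_synthesis_spec(90, 256, suppression_intervals = list(c(0, 90)),
                             suppression_amplitude = 2)
  sub <- extract_subparameters(synthesize_eeg(spec), detrend = FALSE)
  expect_true(all(sub$bsr == 100))
})

test_that("128 Hz input yields NA EMG with a warning, not an error", {
  set.seed(3)
  seg <- eeg_segment(stats::rnorm(70 * 128, sd = 10), 128)
  expect_warning(sub <- extract_subparameters(seg), "EMG")
  expect_true(all(is.na(sub$emg)))
  expect_true(all(is.finite(sub$sef)))
})
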