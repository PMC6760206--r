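# Synthetic anaesthesia cases and raw EEG.
#
# The per-second case generator inverts the published estimator: a phase plan
# prescribes subparameter means over time (piecewise constant with first-order
# exponential smoothing, so trajectories sweep continuously through the tree's
# decision thresholds during transitions); Gaussian jitter is added per
# subparameter; the BIS value is the model prediction plus Gaussian residual
# noise, with a small fraction of samples shifted by a fixed offset to mimic
# the smoothing-delay discrepancies seen on real monitors. The raw-EEG
# synthesiser produces band-limited Gaussian noise with exactly calibrated
# band powers and amplitude-scaled suppression intervals, which is what the
# feature extractors need for oracle tests.

#' Default anaesthesia-course phase plan
#'
#' A ~60 min case traversing awake, sedation, adequate and profound
#' anaesthesia, burst suppression and emergence. Phase means were chosen by
#' inverting the published model so that each phase's predicted BIS lies
#' inside the range its subparameters classify into (a consistency real
#' monitor data has by construction), and several phases deliberately
#' straddle the published decision thresholds so the discovery pipeline sees
#' dense data on both sides of every boundary.
#'
#' @return data.frame with columns `phase`, `duration_s`, `bsr`, `sef`,
#'   `emg`, `rbr`, `sfs`.
#' @export
default_phase_plan <- function() {
  plan <- rbind(
    c(150, 0.0, 24.0, 35.0, 1.4, 0.6),    # awake
    c(90, 0.0, 18.5, 38.0, 0.5, 0.7),     # awake_emg
    c(150, 0.0, 23.5, 30.0, 0.5, 0.7),    # awake_calm
    c(120, 0.0, 23.5, 29.0, -0.2, 0.8),   # light_sedation
    c(180, 0.0, 25.0, 20.0, -0.7, 0.9),   # rbr_boundary
    c(180, 0.0, 22.0, 37.0, -1.0, 1.0),   # sedation_deep
    c(120, 0.0, 18.5, 40.0, -0.9, 1.0),   # sedation
    c(180, 0.0, 20.7, 36.0, -1.45, 1.05), # sedation_low
    c(180, 0.5, 19.5, 34.2, -1.0, 1.1),   # emg_boundary
    c(120, 0.5, 18.8, 32.0, -1.4, 1.2),   # adequate_light
    c(150, 0.5, 18.0, 32.0, -0.4, 1.2),   # adequate_var
    c(180, 0.5, 16.5, 30.0, -1.2, 1.3),   # adequate
    c(210, 0.3, 14.8, 33.0, -2.0, 1.5),   # sef_boundary
    c(150, 0.5, 16.5, 28.0, -0.6, 1.6),   # mixed_profound
    c(180, 1.0, 12.0, 30.0, -1.5, 1.7),   # profound
    c(150, 0.5, 10.0, 30.0, -2.3, 1.8),   # profound_slow
    c(150, 27.0, 11.0, 29.0, -1.8, 1.9),  # profound_deep
    c(150, 46.0, 16.5, 31.0, -0.2, 2.0),  # suppression_onset
    c(150, 54.5, 14.0, 28.0, -1.0, 2.1),  # suppression_light
    c(210, 75.0, 10.0, 28.0, -1.3, 2.2),  # burst_suppression
    c(150, 97.0, 8.0, 27.0, -1.1, 2.4),   # isoelectric
    c(120, 54.5, 14.0, 28.0, -1.0, 2.1),  # suppression_light_2
    c(120, 46.0, 16.5, 31.0, -0.2, 2.0),  # suppression_onset_2
    c(150, 1.0, 12.0, 30.0, -1.5, 1.7),   # profound_2
    c(180, 0.5, 16.5, 30.0, -1.2, 1.3),   # adequate_2
    c(120, 0.0, 18.5, 40.0, -0.9, 1.0),   # sedation_2
    c(120, 0.0, 25.0, 20.0, -0.7, 0.9),   # rbr_boundary_2
    c(120, 0.0, 24.0, 33.0, 0.9, 0.6)     # emergence
  )
  data.frame(
    phase = c("awake", "awake_emg", "awake_calm", "light_sedation",
              "rbr_boundary", "sedation_deep", "sedation", "sedation_low",
              "emg_boundary",
              "adequate_light", "adequate_var", "adequate", "sef_boundary",
              "mixed_profound",
              "profound", "profound_slow", "profound_deep",
              "suppression_onset", "suppression_light", "burst_suppression",
              "isoelectric", "suppression_light_2", "suppression_onset_2",
              "profound_2", "adequate_2", "sedation_2", "rbr_boundary_2",
              "emergence"),
    duration_s = plan[, 1], bsr = plan[, 2], sef = plan[, 3],
    emg = plan[, 4], rbr = plan[, 5], sfs = plan[, 6],
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic anaesthesia case
#'
#' @param phase_plan data.frame as returned by [default_phase_plan()]:
#'   ordered phases with durations (s) and target subparameter means.
#' @param noise_sd named per-subparameter jitter standard deviations. The
#'   defaults are 1.0 for BSR (%), SEF (Hz) and EMG (dB) and 0.1 for the
#'   log10-scale RBR and SFS.
#' @param bis_noise_sd standard deviation of the BIS residual around the
#'   model prediction (BIS units).
#' @param outlier_fraction proportion of samples in `[0, 1)` shifted by
#'   `outlier_offset` BIS units.
#' @param outlier_offset additive BIS offset applied to outlier samples.
#' @param sqi_noise_sd scale of the downward SQI noise (SQI is generated as
#'   100 minus a folded-normal term, floored above the 90% filter).
#' @param sqi_low_fraction proportion of samples given SQI <= 90; zero by
#'   default so low-quality samples exist only when explicitly requested.
#' @param smoothing_tau_s time constant (s) of the first-order smoothing
#'   between phase targets.
#' @param seed integer seed for the case.
#' @return object of class `bis_case_spec`.
#' @export
case_spec <- function(phase_plan = default_phase_plan(),
                      noise_sd = c(bsr = 1, sef = 1, emg = 1,
                                   rbr = 0.1, sfs = 0.1),
                      bis_noise_sd = 1,
                      outlier_fraction = 0.02,
                      outlier_offset = 10,
                      sqi_noise_sd = 2,
                      sqi_low_fraction = 0,
                      smoothing_tau_s = 10,
                      seed = 1L) {
  pars <- c("bsr", "sef", "emg", "rbr", "sfs")
  if (!is.data.frame(phase_plan) ||
      !all(c("duration_s", pars) %in% names(phase_plan)) ||
      nrow(phase_plan) < 1) {
    abort_bisre("phase_plan must have columns duration_s, bsr, sef, emg, rbr, sfs",
                "bisre_config_error")
  }
  if (any(phase_plan$duration_s <= 0)) {
    abort_bisre("field 'phase_plan$duration_s' must be positive",
                "bisre_config_error")
  }
  miss <- setdiff(pars, names(noise_sd))
  if (length(miss)) {
    abort_bisre(paste0("field 'noise_sd' missing entries: ",
                       paste(miss, collapse = ", ")), "bisre_config_error")
  }
  if (any(noise_sd < 0)) {
    abort_bisre("field 'noise_sd' must be non-negative elementwise",
                "bisre_config_error")
  }
  check_number(bis_noise_sd, "bis_noise_sd", 0)
  check_number(outlier_fraction, "outlier_fraction", 0, 1 - 1e-12)
  check_number(outlier_offset, "outlier_offset")
  check_number(sqi_noise_sd, "sqi_noise_sd", 0)
  check_number(sqi_low_fraction, "sqi_low_fraction", 0, 1 - 1e-12)
  check_number(smoothing_tau_s, "smoothing_tau_s", 1e-9)
  structure(
    list(phase_plan = phase_plan,
         duration_s = sum(phase_plan$duration_s),
         noise_sd = noise_sd[pars],
         bis_noise_sd = bis_noise_sd,
         outlier_fraction = outlier_fraction,
         outlier_offset = outlier_offset,
         sqi_noise_sd = sqi_noise_sd,
         sqi_low_fraction = sqi_low_fraction,
         smoothing_tau_s = smoothing_tau_s,
         seed = as.integer(seed)),
    class = "bis_case_spec"
  )
}

#' Generate one synthetic anaesthesia case
#'
#' Per-second subparameters follow the phase-plan means (exponentially
#' smoothed) plus Gaussian jitter; the observed BIS is the model prediction
#' for the jittered subparameters plus Gaussian residual noise and optional
#' outlier offsets, clipped to `[0, 98]`. With all noise terms zero the
#' generated BIS equals the model prediction exactly.
#'
#' @param spec a [case_spec()].
#' @param model the generating [bis_model()].
#' @return object of class `bis_synthetic_case`: list with `samples`
#'   (data.frame `time_s`, `bis`, `sqi`, `bsr`, `sef`, `emg`, `rbr`, `sfs`),
#'   `true_range` (factor, the generator tree's classification of each
#'   sample) and `spec`.
#' @export
generate_case <- function(spec, model = default_bis_model()) {
  if (!inherits(spec, "bis_case_spec")) {
    abort_bisre("'spec' must be a bis_case_spec", "bisre_config_error")
  }
  pars <- c("bsr", "sef", "emg", "rbr", "sfs")
  n <- as.integer(round(spec$duration_s))
  phase_idx <- rep(seq_len(nrow(spec$phase_plan)),
                   times = round(spec$phase_plan$duration_s))[seq_len(n)]
  alpha <- 1 - exp(-1 / spec$smoothing_tau_s)
  with_seed(spec$seed, {
    traj <- sapply(pars, function(p) {
      target <- spec$phase_plan[[p]][phase_idx]
      as.numeric(stats::filter(alpha * target, 1 - alpha,
                               method = "recursive", init = target[1]))
    })
    jit <- sapply(pars, function(p) stats::rnorm(n, 0, spec$noise_sd[[p]]))
    vals <- as.data.frame(traj + jit)
    vals$bsr <- pmin(pmax(vals$bsr, 0), 100)
    vals$sef <- pmin(pmax(vals$sef, 0.5), 30)
    pred <- predict_bis(vals, model)
    bis <- pred$bis + stats::rnorm(n, 0, spec$bis_noise_sd)
    n_out <- floor(spec$outlier_fraction * n)
    if (n_out > 0) {
      out_idx <- sample.int(n, n_out)
      bis[out_idx] <- bis[out_idx] + spec$outlier_offset
    }
    bis <- pmin(pmax(bis, 0), 98)
    sqi <- pmax(90.5, 100 - abs(stats::rnorm(n, 0, spec$sqi_noise_sd)))
    n_low <- floor(spec$sqi_low_fraction * n)
    if (n_low > 0) sqi[sample.int(n, n_low)] <- stats::runif(n_low, 50, 90)
    structure(
      list(samples = data.frame(time_s = seq_len(n), bis = bis, sqi = sqi,
                                vals[, pars]),
           true_range = pred$range,
           spec = spec),
      class = "bis_synthetic_case"
    )
  })
}

#' Generate a reproducible collection of synthetic cases
#'
#' Per-case seeds are derived deterministically from the master seed, so the
#' same call yields bitwise-identical output.
#'
#' @param n_cases number of cases (>= 1).
#' @param spec_template a [case_spec()] whose seed field is overridden per
#'   case.
#' @param model the generating [bis_model()].
#' @param seed master seed.
#' @return list of `bis_synthetic_case` objects.
#' @export
generate_dataset <- function(n_cases, spec_template = case_spec(),
                             model = default_bis_model(), seed = 1L) {
  if (!is.numeric(n_cases) || n_cases < 1) {
    abort_bisre("n_cases must be >= 1", "bisre_argument_error")
  }
  lapply(seq_len(n_cases), function(i) {
    sp <- spec_template
    sp$seed <- derive_seed(seed, i)
    generate_case(sp, model)
  })
}

#' Pool case samples into one data.frame
#'
#' @param cases list of `bis_synthetic_case` objects.
#' @return data.frame of all per-second samples with a leading `case`
#'   column and the generator's `true_range` labels.
#' @export
pool_samples <- function(cases) {
  do.call(rbind, lapply(seq_along(cases), function(i) {
    data.frame(case = i, cases[[i]]$samples,
               true_range = cases[[i]]$true_range)
  }))
}

#' Specification for synthetic raw EEG
#'
#' @param duration_s segment duration in seconds.
#' @param sampling_rate Hz; the default 256 Hz carries the 70-110 Hz EMG
#'   band, which a 128 Hz export cannot (Nyquist 64 Hz).
#' @param band_powers list of `c(low_hz, high_hz, power_uv2)` triples; each
#'   contributes band-limited Gaussian noise whose realised variance equals
#'   the requested power exactly.
#' @param suppression_intervals list of `c(start_s, end_s)` pairs whose
#'   samples are rescaled below `suppression_amplitude`.
#' @param suppression_amplitude peak amplitude (uV, < 5) inside suppression
#'   intervals.
#' @param seed integer seed.
#' @return object of class `bis_eeg_synthesis_spec`.
#' @export
eeg_synthesis_spec <- function(duration_s,
                               sampling_rate = 256,
                               band_powers = list(c(1, 30, 100),
                                                  c(30, 47, 5),
                                                  c(70, 110, 0.5)),
                               suppression_intervals = list(),
                               suppression_amplitude = 2,
                               seed = 1L) {
  check_number(duration_s, "duration_s", 1e-9)
  check_number(sampling_rate, "sampling_rate", 1e-9)
  check_number(suppression_amplitude, "suppression_amplitude", 1e-9,
               5 - 1e-12)
  for (b in band_powers) {
    if (length(b) != 3 || b[1] < 0 || b[2] <= b[1] || b[3] < 0) {
      abort_bisre("each band_powers entry must be c(low, high, power) with 0 <= low < high and power >= 0",
                  "bisre_config_error")
    }
    if (b[2] > sampling_rate / 2) {
      abort_bisre(sprintf("band edge %.4g Hz above Nyquist %.4g Hz",
                          b[2], sampling_rate / 2), "bisre_config_error")
    }
  }
  for (iv in suppression_intervals) {
    if (length(iv) != 2 || iv[1] < 0 || iv[2] <= iv[1] || iv[2] > duration_s) {
      abort_bisre("suppression intervals must lie within [0, duration_s]",
                  "bisre_config_error")
    }
  }
  structure(list(duration_s = duration_s, sampling_rate = sampling_rate,
                 band_powers = band_powers,
                 suppression_intervals = suppression_intervals,
                 suppression_amplitude = suppression_amplitude,
                 seed = as.integer(seed)),
            class = "bis_eeg_synthesis_spec")
}

#' Synthesize raw EEG with prescribed spectral content
#'
#' Builds each band in the frequency domain (complex Gaussian coefficients
#' on the in-band bins, zero elsewhere) and rescales it so the realised band
#' power equals the request exactly, then sums the bands and attenuates
#' suppression intervals below the suppression amplitude.
#'
#' @param spec an [eeg_synthesis_spec()].
#' @return a [eeg_segment()].
#' @export
synthesize_eeg <- function(spec) {
  if (!inherits(spec, "bis_eeg_synthesis_spec")) {
    abort_bisre("'spec' must be an eeg_synthesis_spec", "bisre_config_error")
  }
  fs <- spec$sampling_rate
  n <- round(spec$duration_s * fs)
  half <- floor(n / 2)
  freqs <- (1:half) / spec$duration_s
  with_seed(spec$seed, {
    x <- numeric(n)
    for (b in spec$band_powers) {
      if (b[3] <= 0) next
      sel <- which(freqs >= b[1] & freqs <= b[2])
      if (!length(sel)) next
      Z <- complex(real = rep(0, n), imaginary = rep(0, n))
      Z[sel + 1] <- complex(real = stats::rnorm(length(sel)),
                            imaginary = stats::rnorm(length(sel)))
      Z[n - sel + 1] <- Conj(Z[sel + 1])
      xb <- Re(stats::fft(Z, inverse = TRUE)) / n
      xb <- xb - mean(xb)
      xb <- xb * sqrt(b[3] / mean(xb^2))
      x <- x + xb
    }
    for (iv in spec$suppression_intervals) {
      idx <- (round(iv[1] * fs) + 1):round(iv[2] * fs)
      peak <- max(abs(x[idx]), 1e-12)
      x[idx] <- x[idx] * (0.45 * spec$suppression_amplitude / peak)
    }
    eeg_segment(x, fs)
  })
}

#' Synthetic BIS histogram counts with range-boundary discontinuities
#'
#' Emulates the observed intraoperative BIS histogram: piecewise-constant
#' sampling rates per range with an abrupt rate change exactly at each
#' boundary value, multiplicative log-normal rate noise and Poisson counts.
#' Value `b` belongs to the range below its boundary (ranges are
#' upper-inclusive), so the count jump occurs between `b` and `b + 1`.
#'
#' @param boundaries strictly increasing boundary values within `(0, 98)`;
#'   default the three boundaries visible in intraoperative data.
#' @param per_range_rates expected count per BIS value in each of the
#'   `length(boundaries) + 1` ranges. The defaults give ~5e5 total counts
#'   with >= 3-fold rate changes across every boundary and the bulk of the
#'   mass at BIS 42-61, as in intraoperative recordings.
#' @param jump_noise standard deviation of the multiplicative log-normal
#'   rate noise.
#' @param seed integer seed.
#' @return a [bis_histogram()] of counts over BIS 0..98.
#' @export
generate_histogram_counts <- function(boundaries = c(41, 61, 78),
                                      per_range_rates = c(3000, 15000,
                                                          5000, 1500),
                                      jump_noise = 0.05,
                                      seed = 1L) {
  if (length(boundaries)) {
    if (any(diff(boundaries) <= 0) || any(boundaries <= 0) ||
        any(boundaries >= 98)) {
      abort_bisre("boundaries must be strictly increasing within (0, 98)",
                  "bisre_argument_error")
    }
  }
  if (length(per_range_rates) != length(boundaries) + 1) {
    abort_bisre("need one rate per range (length(boundaries) + 1)",
                "bisre_argument_error")
  }
  if (any(per_range_rates <= 0)) {
    abort_bisre("per-range rates must be positive", "bisre_argument_error")
  }
  check_number(jump_noise, "jump_noise", 0, class = "bisre_argument_error")
  values <- 0:98
  range_of <- findInterval(values, c(boundaries + 0.5), left.open = FALSE) + 1
  lambda <- per_range_rates[range_of]
  with_seed(seed, {
    lambda <- lambda * exp(stats::rnorm(99, 0, jump_noise))
    bis_histogram(stats::rpois(99, lambda))
  })
}
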