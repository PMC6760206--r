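# Extraction of the five EEG subparameters from raw waveforms.
#
# Processing chain: Savitzky-Golay detrending; division into 2-s epochs with
# 75% overlap; Blackman-windowed FFT per epoch; epoch-averaged power spectrum
# (57 epochs from the trailing 30 s) and bispectrum (27 epochs from the
# trailing 15 s). From these:
#   BSR  - % of the trailing 60 s whose 0.5-s subepochs stay below 5 uV,
#   SEF  - frequency below which 95% of the 0.5-30 Hz power lies,
#   EMG  - absolute 70-110 Hz power in dB re a reference power,
#   RBR  - log10(P[30-47 Hz] / P[11-20 Hz]),
#   SFS  - log10(B[0.5-47 Hz] / B[40-47 Hz]).
# Band edges are inclusive on the 0.5 Hz grid, so 30-47 Hz covers 35 bins and
# 11-20 Hz covers 19 bins; every log-ratio depends on that convention.

#' Construct a raw EEG segment
#'
#' @param samples numeric vector of amplitudes in microvolts.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param start_time segment start time in seconds.
#' @return object of class `bis_eeg_segment` with fields `samples`,
#'   `sampling_rate`, `start_time`.
#' @export
eeg_segment <- function(samples, sampling_rate, start_time = 0) {
  if (!length(samples) || any(!is.finite(samples))) {
    abort_bisre("samples must be a non-empty finite numeric vector",
                "bisre_argument_error")
  }
  check_number(sampling_rate, "sampling_rate", min = 1e-9,
               class = "bisre_argument_error")
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 start_time = start_time),
            class = "bis_eeg_segment")
}

segment_duration <- function(segment) {
  length(segment$samples) / segment$sampling_rate
}

#' Detrend an EEG segment with a Savitzky-Golay filter
#'
#' Subtracts the Savitzky-Golay-smoothed trend from the signal. The default
#' 0.5 s window with a second-order polynomial removes drift below the
#' 0.5 Hz analysis floor without attenuating the delta band.
#'
#' @param segment a [eeg_segment()].
#' @param window_s smoothing window length in seconds; converted to the
#'   nearest odd sample count.
#' @param poly_order polynomial order of the filter.
#' @return the detrended `bis_eeg_segment`.
#' @export
detrend_eeg <- function(segment, window_s = 0.5, poly_order = 2) {
  n <- round(window_s * segment$sampling_rate)
  if (n %% 2 == 0) n <- n + 1
  if (n <= poly_order) n <- poly_order + 1 + (poly_order %% 2)
  if (n > length(segment$samples)) {
    abort_bisre("detrend window longer than segment", "bisre_argument_error")
  }
  trend <- signal::sgolayfilt(segment$samples, p = poly_order, n = n)
  eeg_segment(segment$samples - trend, segment$sampling_rate,
              segment$start_time)
}

#' Divide a segment into overlapping epochs
#'
#' With 2-s epochs and 75% overlap, a 30 s segment yields 57 epochs and a
#' 15 s segment yields 27 epochs.
#'
#' @param segment a [eeg_segment()].
#' @param epoch_length_s epoch length in seconds.
#' @param overlap fractional overlap between consecutive epochs in `[0, 1)`.
#' @return object of class `bis_epoch_set`: a list with `epochs` (matrix,
#'   one row per epoch), `epoch_length_s`, `overlap`, `source_rate`.
#' @export
make_epochs <- function(segment, epoch_length_s = 2, overlap = 0.75) {
  fs <- segment$sampling_rate
  L <- round(epoch_length_s * fs)
  if (L > length(segment$samples)) {
    abort_bisre("segment shorter than one epoch", "bisre_argument_error")
  }
  step <- round(L * (1 - overlap))
  if (step < 1) abort_bisre("overlap too close to 1", "bisre_argument_error")
  starts <- seq(1L, length(segment$samples) - L + 1L, by = step)
  epochs <- matrix(0, nrow = length(starts), ncol = L)
  for (i in seq_along(starts)) {
    epochs[i, ] <- segment$samples[starts[i]:(starts[i] + L - 1L)]
  }
  structure(list(epochs = epochs,
                 epoch_length_s = epoch_length_s,
                 overlap = overlap,
                 source_rate = fs),
            class = "bis_epoch_set")
}

# Blackman-windowed FFT of every epoch; rows are epochs, columns frequency
# bins 0..Nyquist (one-sided).
epoch_ffts <- function(epochs) {
  L <- ncol(epochs$epochs)
  w <- signal::blackman(L)
  half <- floor(L / 2)
  X <- t(apply(epochs$epochs, 1, function(x) stats::fft(x * w)))
  if (nrow(epochs$epochs) == 1L) X <- matrix(X, nrow = 1)
  list(X = X[, seq_len(half + 1), drop = FALSE], w = w, half = half)
}

#' Epoch-averaged power spectrum
#'
#' One-sided Blackman-windowed periodogram averaged across epochs, with
#' window power normalisation so a unit-variance white input has flat
#' expected power density. For 2-s epochs the frequency grid has 0.5 Hz
#' resolution.
#'
#' @param epochs a [make_epochs()] result.
#' @return object of class `bis_spectrum`: list with `frequencies` (Hz),
#'   `power` (uV^2/Hz per bin, epoch mean), `df` (grid step), `n_epochs`.
#' @export
power_spectrum <- function(epochs) {
  ft <- epoch_ffts(epochs)
  fs <- epochs$source_rate
  scale <- 1 / (fs * sum(ft$w^2))
  p <- Mod(ft$X)^2 * scale
  # double all interior bins of the one-sided spectrum
  if (ncol(p) > 2) p[, 2:(ncol(p) - 1)] <- 2 * p[, 2:(ncol(p) - 1)]
  power <- colMeans(p)
  freqs <- (seq_len(ncol(p)) - 1) * fs / ncol(epochs$epochs)
  structure(list(frequencies = freqs, power = power,
                 df = fs / ncol(epochs$epochs),
                 n_epochs = nrow(epochs$epochs)),
            class = "bis_spectrum")
}

#' Epoch-averaged bispectrum
#'
#' `B(f1, f2) = |mean over epochs of X(f1) X(f2) conj(X(f1 + f2))|` on the
#' principal domain `f1 <= f2`, `f1 + f2 <= Nyquist`, with `X` the
#' Blackman-windowed FFT of each epoch. Quadratic phase coupling between a
#' frequency pair and its sum survives the epoch average; independent phases
#' cancel.
#'
#' @param epochs a [make_epochs()] result.
#' @return object of class `bis_bispectrum`: list with `frequencies` (grid
#'   shared by both axes), `magnitude` (matrix indexed `[f1, f2]`, `NA`
#'   outside the principal domain), `n_epochs`.
#' @export
bispectrum <- function(epochs) {
  ft <- epoch_ffts(epochs)
  fs <- epochs$source_rate
  L <- ncol(epochs$epochs)
  half <- ft$half
  nb <- half + 1L
  idx <- outer(0:half, 0:half, "+")       # frequency-bin index of f1+f2
  valid <- outer(0:half, 0:half, function(i, j) i <= j & (i + j) <= half)
  ipj <- pmin(idx, half) + 1L             # clamp; invalid cells masked later
  acc <- matrix(0 + 0i, nb, nb)
  for (e in seq_len(nrow(ft$X))) {
    Xe <- ft$X[e, ]
    acc <- acc + outer(Xe, Xe) * Conj(matrix(Xe[ipj], nb, nb))
  }
  mag <- Mod(acc) / nrow(ft$X)
  mag[!valid] <- NA_real_
  freqs <- (0:half) * fs / L
  structure(list(frequencies = freqs, magnitude = mag,
                 df = fs / L, n_epochs = nrow(ft$X)),
            class = "bis_bispectrum")
}

#' Band power of a spectral or bispectral estimate
#'
#' Sums the estimate over all bins with `low <= f <= high` (inclusive of
#' both edges on the grid). For a bispectrum the sum runs over principal-
#' domain pairs with `low <= f1 + f2 <= high`.
#'
#' @param estimate a `bis_spectrum` or `bis_bispectrum`.
#' @param low,high band edges in Hz, `0 <= low < high <= Nyquist`.
#' @return the summed power (spectrum) or summed bispectral magnitude.
#' @export
band_power <- function(estimate, low, high) {
  if (low >= high || low < 0) {
    abort_bisre("band edges must satisfy 0 <= low < high",
                "bisre_argument_error")
  }
  eps <- 1e-9
  if (inherits(estimate, "bis_spectrum")) {
    sel <- estimate$frequencies >= low - eps & estimate$frequencies <= high + eps
    return(sum(estimate$power[sel]))
  }
  if (inherits(estimate, "bis_bispectrum")) {
    f <- estimate$frequencies
    fsum <- outer(f, f, "+")
    sel <- !is.na(estimate$magnitude) & fsum >= low - eps & fsum <= high + eps
    return(sum(estimate$magnitude[sel]))
  }
  abort_bisre("estimate must be a bis_spectrum or bis_bispectrum",
              "bisre_argument_error")
}

#' Relative beta ratio
#'
#' `RBR = log10(P[30-47 Hz] / P[11-20 Hz])` from an epoch-averaged power
#' spectrum.
#'
#' @param spec a `bis_spectrum`.
#' @return RBR (dimensionless log10 ratio).
#' @export
compute_rbr <- function(spec) {
  num <- band_power(spec, 30, 47)
  den <- band_power(spec, 11, 20)
  if (num <= 0 || den <= 0) {
    abort_bisre("RBR undefined: zero power in the 30-47 or 11-20 Hz band",
                "bisre_undefined_value")
  }
  log10(num / den)
}

#' SyncFastSlow
#'
#' `SFS = log10(B[0.5-47 Hz] / B[40-47 Hz])` over bispectral magnitude sums,
#' bands taken over `f1 + f2`. Set `invert = TRUE` for the opposite
#' orientation `log10(B[40-47]/B[0.5-47])` used in some descriptions of the
#' parameter.
#'
#' @param bispec a `bis_bispectrum`.
#' @param invert flip the ratio orientation.
#' @return SFS (dimensionless log10 ratio).
#' @export
compute_sfs <- function(bispec, invert = FALSE) {
  broad <- band_power(bispec, 0.5, 47)
  fast <- band_power(bispec, 40, 47)
  if (broad <= 0 || fast <= 0) {
    abort_bisre("SFS undefined: zero bispectral mass in a band",
                "bisre_undefined_value")
  }
  out <- log10(broad / fast)
  if (invert) -out else out
}

#' 95% spectral edge frequency
#'
#' Smallest grid frequency `f` in `[0.5, 30]` Hz such that the cumulative
#' power from 0.5 Hz up to `f` reaches 95% of the total 0.5-30 Hz power.
#'
#' @param spec a `bis_spectrum`.
#' @param edge quantile of the in-band power (default 0.95).
#' @return SEF in Hz.
#' @export
compute_sef <- function(spec, edge = 0.95) {
  eps <- 1e-9
  sel <- spec$frequencies >= 0.5 - eps & spec$frequencies <= 30 + eps
  f <- spec$frequencies[sel]
  p <- spec$power[sel]
  total <- sum(p)
  if (total <= 0) {
    abort_bisre("SEF undefined: zero power in 0.5-30 Hz",
                "bisre_undefined_value")
  }
  f[which(cumsum(p) >= edge * total - eps)[1]]
}

#' Burst suppression ratio
#'
#' Percentage of the trailing `window_s` seconds whose subepochs have a
#' maximum absolute amplitude below `threshold_uv` microvolts.
#'
#' @param segment a [eeg_segment()].
#' @param window_s analysis window in seconds (default 60).
#' @param subepoch_s subepoch length in seconds over which the amplitude
#'   criterion is evaluated (default 0.5).
#' @param threshold_uv suppression amplitude threshold in microvolts.
#' @return BSR as a percentage in `[0, 100]`.
#' @export
compute_bsr <- function(segment, window_s = 60, subepoch_s = 0.5,
                        threshold_uv = 5) {
  fs <- segment$sampling_rate
  need <- round(window_s * fs)
  if (length(segment$samples) < need) {
    abort_bisre("segment shorter than the BSR window", "bisre_argument_error")
  }
  x <- utils::tail(segment$samples, need)
  sub <- max(1L, round(subepoch_s * fs))
  n_sub <- floor(length(x) / sub)
  x <- x[seq_len(n_sub * sub)]
  peak <- apply(matrix(abs(x), nrow = sub), 2, max)
  100 * mean(peak < threshold_uv)
}

#' Electromyographic power in dB
#'
#' Absolute spectral power in the 70-110 Hz band, expressed as
#' `10 log10(P / reference_power)`. Requires a sampling rate of at least
#' 220 Hz so the band lies below Nyquist; the monitor's own dB reference is
#' undisclosed, so it is configurable.
#'
#' @param segment a [eeg_segment()].
#' @param reference_power dB reference in uV^2 (default 1e-4, which places
#'   typical intraoperative values in the 25-45 dB region).
#' @return EMG power in dB.
#' @export
compute_emg <- function(segment, reference_power = 1e-4) {
  if (segment$sampling_rate < 220) {
    abort_bisre(sprintf(
      "EMG needs the 70-110 Hz band: sampling rate %.4g Hz gives Nyquist %.4g Hz (< 110 Hz); supply >= 220 Hz data or a monitor EMG track",
      segment$sampling_rate, segment$sampling_rate / 2),
      "bisre_capability_error")
  }
  spec <- power_spectrum(make_epochs(segment))
  p <- band_power(spec, 70, 110) * spec$df   # density bins -> absolute uV^2
  if (p <= 0) {
    abort_bisre("EMG undefined: zero 70-110 Hz power", "bisre_undefined_value")
  }
  10 * log10(p / reference_power)
}

#' Per-second subparameter track from raw EEG
#'
#' Emits one subparameter sample per second from `t = bsr_window_s` onward.
#' Spectral parameters (SEF, RBR, EMG) use 57 epochs from the trailing 30 s,
#' bispectral SFS uses 27 epochs from the trailing 15 s, and BSR uses the
#' trailing 60 s, mirroring the monitor's default smoothing rates.
#'
#' @param segment a [eeg_segment()] of at least `bsr_window_s` seconds.
#' @param reference_power EMG dB reference (see [compute_emg()]).
#' @param spectral_window_s,bispectral_window_s,bsr_window_s trailing window
#'   lengths in seconds.
#' @param detrend detrend the full segment first (default `TRUE`).
#' @param sfs_invert passed to [compute_sfs()].
#' @return data.frame with columns `time_s`, `bsr`, `sef`, `emg`, `rbr`,
#'   `sfs`. `emg` is `NA` (with one warning) when the sampling rate cannot
#'   carry the 70-110 Hz band.
#' @export
extract_subparameters <- function(segment, reference_power = 1e-4,
                                  spectral_window_s = 30,
                                  bispectral_window_s = 15,
                                  bsr_window_s = 60,
                                  detrend = TRUE,
                                  sfs_invert = FALSE) {
  fs <- segment$sampling_rate
  dur <- segment_duration(segment)
  if (dur < bsr_window_s) {
    abort_bisre("segment shorter than the BSR window", "bisre_argument_error")
  }
  if (detrend) segment <- detrend_eeg(segment)
  emg_ok <- fs >= 220
  if (!emg_ok) {
    warning(sprintf(
      "sampling rate %.4g Hz cannot carry the 70-110 Hz EMG band; emg set to NA",
      fs), call. = FALSE)
  }
  times <- seq(bsr_window_s, floor(dur), by = 1)
  window_of <- function(t_end, width_s) {
    i1 <- round((t_end - width_s) * fs) + 1L
    i2 <- round(t_end * fs)
    eeg_segment(segment$samples[i1:i2], fs,
                segment$start_time + t_end - width_s)
  }
  res <- lapply(times, function(t_end) {
    spec_seg <- window_of(t_end, spectral_window_s)
    spec <- power_spectrum(make_epochs(spec_seg))
    bspec <- bispectrum(make_epochs(window_of(t_end, bispectral_window_s)))
    wrap <- function(expr) tryCatch(expr, bisre_error = function(e) {
      abort_bisre(sprintf("t = %g s: %s", segment$start_time + t_end,
                          conditionMessage(e)), class(e)[1])
    })
    data.frame(
      time_s = segment$start_time + t_end,
      bsr = wrap(compute_bsr(window_of(t_end, bsr_window_s))),
      sef = wrap(compute_sef(spec)),
      emg = if (emg_ok) {
        p70 <- band_power(spec, 70, 110) * spec$df
        if (p70 <= 0) NA_real_ else 10 * log10(p70 / reference_power)
      } else NA_real_,
      rbr = wrap(compute_rbr(spec)),
      sfs = wrap(compute_sfs(bspec, invert = sfs_invert))
    )
  })
  do.call(rbind, res)
}
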