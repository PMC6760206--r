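# Shared fixtures and independent oracles used across the suite.
# Everything here is built in code at test time; nothing is loaded from disk.

# A spectral estimate with all power in a single bin: the degenerate input
# for SEF/RBR contracts.
point_mass_spectrum <- function(freq_hz, power = 1, fmax = 64, df = 0.5) {
  f <- seq(0, fmax, by = df)
  p <- numeric(length(f))
  p[which.min(abs(f - freq_hz))] <- power
  structure(list(frequencies = f, power = p, df = df, n_epochs = 1),
            class = "bis_spectrum")
}

flat_spectrum <- function(value = 1, fmax = 64, df = 0.5) {
  f <- seq(0, fmax, by = df)
  structure(list(frequencies = f, power = rep(value, length(f)),
                 df = df, n_epochs = 1),
            class = "bis_spectrum")
}

sine_segment <- function(freq_hz, duration_s, fs = 128, amplitude = 1,
                         phase = 0) {
  t <- seq(1 / fs, duration_s, by = 1 / fs)
  eeg_segment(amplitude * sin(2 * pi * freq_hz * t + phase), fs)
}

# Exhaustive entropy-gain split search on small data: the independent oracle
# for the CART implementation. Returns the best (feature, cut, gain).
entropy_split_oracle <- function(data, features, labels) {
  ent <- function(y) {
    p <- table(y) / length(y)
    -sum(ifelse(p > 0, p * log(p), 0))
  }
  h0 <- ent(labels)
  best <- list(gain = -Inf)
  for (f in features) {
    x <- data[[f]]
    xs <- sort(unique(x))
    if (length(xs) < 2) next
    cuts <- (xs[-1] + xs[-length(xs)]) / 2
    for (cc in cuts) {
      lo <- x < cc
      g <- h0 - mean(lo) * ent(labels[lo]) - mean(!lo) * ent(labels[!lo])
      if (g > best$gain) best <- list(feature = f, cut = cc, gain = g)
    }
  }
  best
}

# Small, fast subparameter pool drawn directly around the published model:
# uniform coverage of the feature space, BIS from the model plus noise.
quick_pool <- function(n = 5000, seed = 1, bis_noise = 0) {
  set.seed(seed)
  x <- data.frame(
    bsr = c(runif(n / 2, 0, 3), runif(n / 2, 0, 100)),
    sef = runif(n, 8, 26),
    emg = runif(n, 25, 45),
    rbr = runif(n, -2.5, 1),
    sfs = runif(n, 0.5, 2.5)
  )
  pred <- predict_bis(x, default_bis_model())
  x$bis <- pmin(pmax(pred$bis + stats::rnorm(n, 0, bis_noise), 0), 98)
  x$true_range <- pred$range
  x
}
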