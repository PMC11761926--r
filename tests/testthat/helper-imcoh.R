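# Independent naive MSC oracle: explicit segmentation, explicit DFT matrix,
# explicit periodogram averaging. Shares no code with the package's Welch
# path beyond the Hamming coefficients' published formula.
naive_msc <- function(x, y, window_samples, step, fs) {
  W <- window_samples
  L <- floor((length(x) - W) / step) + 1
  n <- 0:(W - 1)
  w <- 0.54 - 0.46 * cos(2 * pi * n / (W - 1))
  half <- floor(W / 2) + 1
  # DFT matrix, rows = frequency bins 0..W/2
  D <- exp(-2i * pi * outer(0:(half - 1), n) / W)
  Sxx <- Syy <- numeric(half)
  Sxy <- complex(half)
  for (j in seq_len(L)) {
    idx <- ((j - 1) * step + 1):((j - 1) * step + W)
    X <- as.vector(D %*% (x[idx] * w))
    Y <- as.vector(D %*% (y[idx] * w))
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + Conj(X) * Y
  }
  Mod(Sxy)^2 / (Sxx * Syy)
}

# small factorial design used by fast end-to-end tests
tiny_design <- function(participants = c("P01", "P02"),
                        conditions = c("EOFT", "ECFT", "EOTanDB"),
                        trials = 3, duration = 10, fs = 600) {
  study_design(participants = participants, conditions = conditions,
               trials_per_condition = trials, trial_duration = duration,
               fs = fs)
}

# mean band PSD of a signal over [lo, hi) Hz
band_psd <- function(x, lo, hi, params) {
  p <- welch_psd(x, params)
  sel <- p$freq >= lo & p$freq < hi
  mean(p$density[sel])
}
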