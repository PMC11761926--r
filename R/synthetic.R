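# Deterministic sub-seed derivation: mixes a top-level seed with integer
# indices (participant, condition, trial, channel, ...) into a 31-bit seed.
# All arithmetic stays below 2^53 so the result is exact in doubles.
sub_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 69069 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Band-limited Gaussian noise with flat in-band spectrum
#'
#' Generates a zero-mean Gaussian signal whose one-sided power spectral
#' density is flat at `psd` inside the half-open band `[lo, hi)` and zero
#' outside, by spectral masking of white Gaussian noise. Reproducible for a
#' fixed seed.
#'
#' @param lo,hi Band edges in Hz; `0 <= lo < hi <= fs/2`.
#' @param n Number of samples (>= 2).
#' @param fs Sampling rate in Hz.
#' @param psd Target one-sided in-band power spectral density (units^2/Hz).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (and advanced).
#' @return Numeric vector of length `n`.
#' @export
bandlimited_noise <- function(lo, hi, n, fs, psd = 1, seed = NULL) {
  if (!(lo >= 0 && lo < hi && hi <= fs / 2)) {
    stop(sprintf("invalid band [%g, %g) Hz: need 0 <= lo < hi <= fs/2 = %g",
                 lo, hi, fs / 2))
  }
  if (n < 2) stop("n must be at least 2 samples")
  stopifnot(psd >= 0)
  gen <- function() {
    z <- stats::rnorm(n)
    k <- 0:(n - 1)
    f <- pmin(k, n - k) * fs / n  # folded (absolute) bin frequency
    mask <- f >= lo & f < hi
    x <- Re(stats::fft(stats::fft(z) * mask, inverse = TRUE) / n)
    x * sqrt(psd * fs / 2)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Closed-form MSC of the linear common-drive model
#'
#' For two channels `x = a1*s + e1`, `y = a2*s + e2` with a shared drive of
#' power spectral density `S_s` and independent noises of densities `S_n1`,
#' `S_n2`, the true magnitude-squared coherence at in-band frequencies is
#' \deqn{\gamma^2 = (a_1 a_2 S_s)^2 / ((a_1^2 S_s + S_{n1})(a_2^2 S_s + S_{n2})).}
#' With unit gains and equal noise densities this reduces to
#' `(r / (1 + r))^2` where `r = S_s / S_n` is the in-band drive-to-noise
#' ratio.
#'
#' @param a1,a2 Per-channel drive gains.
#' @param S_s Shared-drive PSD (units^2/Hz).
#' @param S_n1,S_n2 Per-channel noise PSDs (units^2/Hz).
#' @return Coherence value in `[0, 1]`.
#' @export
theoretical_msc <- function(a1, a2, S_s, S_n1, S_n2 = S_n1) {
  stopifnot(S_s >= 0, S_n1 >= 0, S_n2 >= 0)
  d1 <- a1^2 * S_s + S_n1
  d2 <- a2^2 * S_s + S_n2
  if (d1 == 0 || d2 == 0) {
    stop("coherence undefined: a channel has zero total power in band")
  }
  (a1 * a2 * S_s)^2 / (d1 * d2)
}

#' Drive-to-noise ratio achieving a target coherence
#'
#' Inverts `(r/(1+r))^2 = msc` for the unit-gain, equal-noise common-drive
#' model: `r = sqrt(msc) / (1 - sqrt(msc))`.
#'
#' @param msc Target magnitude-squared coherence in `[0, 1)`.
#' @return In-band drive-to-noise power ratio `r >= 0`.
#' @examples
#' snr_for_coherence(0.25)  # 1
#' @export
snr_for_coherence <- function(msc) {
  stopifnot(msc >= 0, msc < 1)
  s <- sqrt(msc)
  s / (1 - s)
}

#' Shared-drive specification for a coherent channel pair
#'
#' @param band_lo,band_hi Drive band edges in Hz.
#' @param drive_power One-sided in-band drive PSD (units^2/Hz).
#' @param gains Length-2 numeric vector of per-channel gains.
#' @return An object of class `drive_spec`.
#' @export
drive_spec <- function(band_lo, band_hi, drive_power, gains = c(1, 1)) {
  stopifnot(band_lo >= 0, band_lo < band_hi, drive_power >= 0,
            length(gains) == 2, all(is.finite(gains)))
  structure(list(band_lo = band_lo, band_hi = band_hi,
                 drive_power = drive_power, gains = gains),
            class = "drive_spec")
}

#' Simulate a coherent signal pair
#'
#' Generates `x = a1*s + e1`, `y = a2*s + e2` with `s` a band-limited shared
#' drive and `e1`, `e2` independent broadband (10-500 Hz) noises, so the true
#' in-band coherence equals [theoretical_msc()] of the same parameters. The
#' drive band should lie inside the broadband noise band for the closed form
#' to apply exactly.
#'
#' @param drive A [drive_spec()].
#' @param noise_power One-sided broadband noise PSD per channel (> 0).
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param noise_band Length-2 band of the broadband noise in Hz.
#' @return List with numeric vectors `x` and `y`.
#' @export
simulate_coherent_pair <- function(drive, noise_power, n, fs, seed,
                                   noise_band = c(10, min(500, fs / 2))) {
  stopifnot(inherits(drive, "drive_spec"))
  if (noise_power <= 0) {
    if (drive$drive_power == 0) {
      stop("degenerate signals: zero noise power and zero drive power")
    }
    stop("noise_power must be > 0")
  }
  s <- bandlimited_noise(drive$band_lo, drive$band_hi, n, fs,
                         psd = drive$drive_power, seed = sub_seed(seed, 1))
  e1 <- bandlimited_noise(noise_band[1], noise_band[2], n, fs,
                          psd = noise_power, seed = sub_seed(seed, 2))
  e2 <- bandlimited_noise(noise_band[1], noise_band[2], n, fs,
                          psd = noise_power, seed = sub_seed(seed, 3))
  list(x = drive$gains[1] * s + e1, y = drive$gains[2] * s + e2)
}

#' Add sinusoidal powerline interference
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param f0 Interference frequency in Hz (must be below Nyquist).
#' @param amplitude Peak amplitude, same units as `x`.
#' @param phase Phase offset in radians.
#' @return `x + amplitude * sin(2*pi*f0*t + phase)`, same length as `x`.
#' @export
inject_line_interference <- function(x, fs, f0 = 60, amplitude = 1,
                                     phase = 0) {
  if (!(f0 > 0 && f0 < fs / 2)) {
    stop(sprintf("interference frequency %g Hz must lie in (0, %g) Hz",
                 f0, fs / 2))
  }
  t <- (seq_along(x) - 1) / fs
  x + amplitude * sin(2 * pi * f0 * t + phase)
}

#' Factorial layout of a standing-balance EMG study
#'
#' Defaults reproduce a six-participant design with six standing conditions
#' (eyes open/closed crossed with feet-together and two tandem placements),
#' five 30 s trials per condition, and six lower-leg muscles (bilateral
#' tibialis anterior, medial gastrocnemius, soleus) sampled at 1200 Hz.
#'
#' @param participants Character vector of participant labels.
#' @param conditions Character vector of condition labels; order is kept in
#'   all outputs (first is conventionally the stable baseline).
#' @param trials_per_condition Trials per condition.
#' @param trial_duration Trial length in seconds.
#' @param fs Sampling rate in Hz.
#' @param muscles Character vector of muscle labels.
#' @return An object of class `study_design`.
#' @export
study_design <- function(participants = sprintf("P%02d", 1:6),
                         conditions = c("EOFT", "ECFT", "EOTanDB",
                                        "ECTanDB", "EOTanDF", "ECTanDF"),
                         trials_per_condition = 5,
                         trial_duration = 30,
                         fs = 1200,
                         muscles = c("LTA", "LMG", "LS",
                                     "RTA", "RMG", "RS")) {
  stopifnot(trials_per_condition >= 1, trial_duration > 0, fs > 0)
  if (anyDuplicated(participants) || anyDuplicated(conditions) ||
      anyDuplicated(muscles)) {
    stop("participant, condition and muscle labels must be unique")
  }
  ns <- trial_duration * fs
  if (abs(ns - round(ns)) > 1e-8) {
    stop("trial_duration * fs must be an integer sample count")
  }
  structure(
    list(participants = participants, conditions = conditions,
         trials_per_condition = as.integer(trials_per_condition),
         trial_duration = trial_duration, fs = fs,
         n_samples = as.integer(round(ns)), muscles = muscles),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "Study design: %d participants x %d conditions x %d trials of %g s, %d muscles @ %g Hz\n",
    length(x$participants), length(x$conditions), x$trials_per_condition,
    x$trial_duration, length(x$muscles), x$fs))
  invisible(x)
}

#' Planted condition-dependent coupling strengths
#'
#' An effect map assigns an in-band drive-to-noise ratio `snr` to specific
#' (condition, muscle pair, band) cells. Within a simulated trial, the two
#' muscles of a keyed pair share one band-limited drive realization at the
#' keyed ratio; any cell not keyed gets `baseline_snr` (default 0, no shared
#' drive) in [simulate_study()].
#'
#' @param condition,pair,band,snr Equal-length vectors (recycled by
#'   `data.frame`); `pair` uses the `"A:B"` muscle-pair syntax, `band` names
#'   a row of [band_definitions()], `snr >= 0`.
#' @return A data.frame of class `effect_map`.
#' @examples
#' # raise RMG:RS beta coherence to 0.25 in the four tandem conditions
#' effect_map(
#'   condition = c("EOTanDB", "ECTanDB", "EOTanDF", "ECTanDF"),
#'   pair = "RMG:RS", band = "beta", snr = snr_for_coherence(0.25)
#' )
#' @export
effect_map <- function(condition = character(), pair = character(),
                       band = character(), snr = numeric()) {
  em <- data.frame(condition = condition, pair = pair, band = band,
                   snr = snr, stringsAsFactors = FALSE)
  if (nrow(em) > 0) {
    stopifnot(all(em$snr >= 0))
    band_definitions(unique(em$band))  # validates band names
  }
  class(em) <- c("effect_map", "data.frame")
  em
}

split_pair <- function(pair) {
  parts <- strsplit(pair, ":", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    stop("malformed muscle pair(s): ", paste(pair[bad], collapse = ", "),
         " (expected \"A:B\")")
  }
  parts
}

#' Simulate a full multichannel EMG study
#'
#' Generates one recording per (participant, condition, trial, muscle) under
#' the linear common-drive model: each muscle receives independent broadband
#' (10-500 Hz) Gaussian noise, and each (condition, pair, band) cell keyed in
#' the effect map adds one shared band-limited drive realization to both
#' muscles of the pair at the keyed drive-to-noise ratio, so the true
#' in-band coherence is `(r/(1+r))^2`. Every (participant, condition, trial)
#' uses an independent sub-seed derived deterministically from `seed`;
#' regeneration with the same arguments is bit-identical.
#'
#' Optionally the acquisition chain is emulated by a 10 Hz 2nd-order
#' Butterworth high-pass on every channel (coherence between identically
#' filtered channels is unaffected), and 60 Hz powerline interference can be
#' injected with a random per-trial phase.
#'
#' @param design A [study_design()].
#' @param effects An [effect_map()] (possibly empty).
#' @param seed Integer top-level seed.
#' @param baseline_snr Drive-to-noise ratio for unkeyed cells of pairs that
#'   appear in `effects` (default 0).
#' @param noise_psd One-sided broadband noise PSD per muscle (arbitrary
#'   units^2/Hz; amplitudes are nominally microvolts but coherence is
#'   scale-invariant).
#' @param highpass Emulate the 10 Hz acquisition high-pass.
#' @param line_amplitude Peak amplitude of injected 60 Hz interference
#'   (0 disables).
#' @return An object of class `emg_trial_set`: list with `samples` (matrix,
#'   samples x recordings), `meta` (data.frame with participant, condition,
#'   trial, muscle per column of `samples`), `fs`, `design`, `effects`,
#'   `seed`, and `theory` (theoretical band coherence per keyed cell).
#' @export
simulate_study <- function(design = study_design(), effects = effect_map(),
                           seed = 1, baseline_snr = 0, noise_psd = 1,
                           highpass = TRUE, line_amplitude = 0) {
  stopifnot(inherits(design, "study_design"))
  if (!inherits(effects, "effect_map")) {
    stop("effects must be an effect_map")
  }
  if (nrow(effects) > 0) {
    bad_cond <- setdiff(effects$condition, design$conditions)
    if (length(bad_cond) > 0) {
      stop("effect map references unknown condition(s): ",
           paste(bad_cond, collapse = ", "))
    }
    mus <- unique(unlist(split_pair(effects$pair)))
    bad_mus <- setdiff(mus, design$muscles)
    if (length(bad_mus) > 0) {
      stop("effect map references unknown muscle(s): ",
           paste(bad_mus, collapse = ", "))
    }
  }

  n <- design$n_samples
  fs <- design$fs
  nb <- c(10, min(500, fs / 2))
  M <- length(design$muscles)
  n_rec <- length(design$participants) * length(design$conditions) *
    design$trials_per_condition * M
  samples <- matrix(0, nrow = n, ncol = n_rec)
  meta <- data.frame(participant = character(n_rec),
                     condition = character(n_rec),
                     trial = integer(n_rec), muscle = character(n_rec),
                     stringsAsFactors = FALSE)
  hp <- if (highpass) design_highpass(10, 2, fs) else NULL

  # per-(pair, band) planted cells, expanded to every condition when a
  # baseline drive-to-noise ratio is requested
  cells <- effects
  if (baseline_snr > 0 && nrow(effects) > 0) {
    pb <- unique(effects[, c("pair", "band")])
    full <- merge(data.frame(condition = design$conditions), pb)
    full <- merge(full, effects, all.x = TRUE,
                  by = c("condition", "pair", "band"))
    full$snr[is.na(full$snr)] <- baseline_snr
    cells <- full
  }

  col <- 0L
  for (pi in seq_along(design$participants)) {
    for (ci in seq_along(design$conditions)) {
      cond <- design$conditions[ci]
      ce <- cells[cells$condition == cond & cells$snr > 0, , drop = FALSE]
      pair_mus <- if (nrow(ce) > 0) split_pair(ce$pair) else list()
      ce_bands <- if (nrow(ce) > 0) band_definitions(ce$band) else NULL
      for (ti in seq_len(design$trials_per_condition)) {
        X <- matrix(0, nrow = n, ncol = M)
        for (mi in seq_len(M)) {
          X[, mi] <- bandlimited_noise(
            nb[1], nb[2], n, fs, psd = noise_psd,
            seed = sub_seed(seed, pi, ci, ti, mi))
        }
        if (nrow(ce) > 0) {
          for (ei in seq_len(nrow(ce))) {
            s <- bandlimited_noise(
              ce_bands$lo[ei], ce_bands$hi[ei], n, fs,
              psd = ce$snr[ei] * noise_psd,
              seed = sub_seed(seed, pi, ci, ti, 1000L + ei))
            idx <- match(pair_mus[[ei]], design$muscles)
            X[, idx[1]] <- X[, idx[1]] + s
            X[, idx[2]] <- X[, idx[2]] + s
          }
        }
        if (line_amplitude > 0) {
          ph <- with_seed(sub_seed(seed, pi, ci, ti, 2000L),
                          stats::runif(M, 0, 2 * pi))
          for (mi in seq_len(M)) {
            X[, mi] <- inject_line_interference(X[, mi], fs, 60,
                                                line_amplitude, ph[mi])
          }
        }
        if (!is.null(hp)) {
          for (mi in seq_len(M)) X[, mi] <- apply_filter(X[, mi], hp)
        }
        rng <- col + seq_len(M)
        samples[, rng] <- X
        meta$participant[rng] <- design$participants[pi]
        meta$condition[rng] <- cond
        meta$trial[rng] <- ti
        meta$muscle[rng] <- design$muscles
        col <- col + M
      }
    }
  }

  theory <- NULL
  if (nrow(cells) > 0) {
    theory <- cells
    theory$msc <- (theory$snr / (1 + theory$snr))^2
  }
  structure(
    list(samples = samples, meta = meta, fs = fs, design = design,
         effects = effects, seed = seed, theory = theory),
    class = "emg_trial_set"
  )
}

#' @export
print.emg_trial_set <- function(x, ...) {
  cat(sprintf(
    "EMG trial set: %d recordings of %d samples @ %g Hz (%d participants, %d conditions, %d muscles)\n",
    ncol(x$samples), nrow(x$samples), x$fs,
    length(unique(x$meta$participant)), length(unique(x$meta$condition)),
    length(unique(x$meta$muscle))))
  invisible(x)
}

#' Extract one recording from a trial set
#'
#' @param trials An `emg_trial_set`.
#' @param participant,condition,trial,muscle Labels identifying the
#'   recording.
#' @return Numeric sample vector.
#' @export
get_recording <- function(trials, participant, condition, trial, muscle) {
  stopifnot(inherits(trials, "emg_trial_set"))
  sel <- which(trials$meta$participant == participant &
                 trials$meta$condition == condition &
                 trials$meta$trial == trial &
                 trials$meta$muscle == muscle)
  if (length(sel) != 1) {
    stop("recording not found (or not unique) for the requested labels")
  }
  trials$samples[, sel]
}
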