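test_that("segment bookkeeping matches the acquisition constants", {
  p <- welch_params(window_duration = 2, overlap = 0.25, fs = 1200)
  expect_identical(p$window_samples, 2400L)
  expect_identical(segment_count(36000, p), 19L)
  expect_identical(segment_count(p$window_samples, p), 1L)
  p0 <- welch_params(window_duration = 2, overlap = 0, fs = 1200)
  expect_identical(segment_count(36000, p0), 15L)
  expect_error(segment_count(1000, p), "short")
})

test_that("only overlap-as-fraction-of-window reproduces 19 segments", {
  # if 25% had meant "the hop is 25% of the window", the hop would be 600
  # samples and a 30 s trial would yield 57 segments, not the documented 19
  W <- 2400
  hop_if_step_convention <- round(0.25 * W)
  expect_identical(floor((36000 - W) / hop_if_step_convention) + 1, 57)
  expect_identical(segment_count(36000, welch_params(2, 0.25, 1200)), 19L)
})

test_that("cross-spectra behave as bilinear forms with shared segmentation", {
  p <- welch_params(fs = 600)
  x <- bandlimited_noise(5, 250, 9000, 600, seed = 60)
  y <- bandlimited_noise(5, 250, 9000, 600, seed = 61)
  cs <- welch_cross_spectra(x, x, p)
  expect_equal(cs$Pxy, complex(real = cs$Pxx), tolerance = 1e-12)
  cs2 <- welch_cross_spectra(3 * x, y, p)
  cs1 <- welch_cross_spectra(x, y, p)
  expect_equal(cs2$Pxx, 9 * cs1$Pxx, tolerance = 1e-12)
  expect_equal(cs2$Pxy, 3 * cs1$Pxy, tolerance = 1e-12)
  expect_error(welch_cross_spectra(x, y[-1], p), "equal length")
})

test_that("cross-spectrum magnitude of independent noises shrinks with segment count", {
  fs <- 600
  mean_xspec <- function(T, seed) {
    p <- welch_params(fs = fs)
    x <- bandlimited_noise(5, 250, T * fs, fs, seed = seed)
    y <- bandlimited_noise(5, 250, T * fs, fs, seed = seed + 5000)
    cs <- welch_cross_spectra(x, y, p)
    mean(Mod(cs$Pxy[cs$freq >= 10 & cs$freq <= 250]))
  }
  m_short <- mean(vapply(1:8, function(s) mean_xspec(15, 70 + s), numeric(1)))
  m_long <- mean(vapply(1:8, function(s) mean_xspec(240, 200 + s), numeric(1)))
  # 16x the record -> ~16x the segments -> |Pxy| should drop ~4x; allow slack
  expect_lt(m_long, m_short / 2.5)
})

test_that("MSC identities: self-coherence, scale invariance, symmetry, bounds", {
  p <- welch_params(fs = 600)
  x <- bandlimited_noise(5, 250, 9000, 600, seed = 62)
  expect_equal(msc_spectrum(x, x, p)$msc, rep(1, 601), tolerance = 1e-12)
  expect_equal(msc_spectrum(x, 3 * x, p)$msc, rep(1, 601), tolerance = 1e-12)

  for (s in 1:5) {
    a <- bandlimited_noise(5, 250, 6000, 600, seed = 300 + s)
    b <- 0.5 * a + bandlimited_noise(5, 250, 6000, 600, seed = 400 + s)
    m1 <- msc_spectrum(a, b, p)
    m2 <- msc_spectrum(b, a, p)
    expect_equal(m1$msc, m2$msc, tolerance = 1e-12)
    ok <- !is.na(m1$msc)
    expect_true(all(m1$msc[ok] >= 0 & m1$msc[ok] <= 1))
    expect_gte(m1$L, 2)
  }
})

test_that("single-segment MSC is rejected, zero-power bins are flagged undefined", {
  p <- welch_params(window_duration = 2, overlap = 0, fs = 600)
  expect_error(msc_spectrum(rnorm(1200), rnorm(1200), p), "segments")
  # a channel with no power leaves every bin undefined, not 0 or 1
  y <- bandlimited_noise(50, 100, 6000, 600, seed = 64)
  m <- msc_spectrum(rep(0, 6000), y, welch_params(fs = 600))
  expect_true(all(is.na(m$msc)))
  expect_error(band_average(m, 13, 30), "undefined")
})

test_that("Welch MSC matches the naive direct-DFT oracle bin for bin", {
  fs <- 600
  p <- welch_params(window_duration = 1, overlap = 0.25, fs = fs)
  for (s in 1:3) {
    n <- c(2400, 3300, 4800)[s]
    x <- bandlimited_noise(5, 290, n, fs, seed = 500 + s)
    y <- 0.6 * x + bandlimited_noise(5, 290, n, fs, seed = 600 + s)
    got <- msc_spectrum(x, y, p)
    want <- naive_msc(x, y, p$window_samples, p$step, fs)
    ok <- !is.na(got$msc)
    expect_lt(max(abs(got$msc[ok] - want[ok]) / pmax(want[ok], 1e-300)),
              1e-10)
  }
})

test_that("band averaging follows the half-open bin convention", {
  p <- welch_params(fs = 1200)
  x <- bandlimited_noise(2, 500, 36000, 1200, seed = 70)
  y <- 0.7 * x + bandlimited_noise(2, 500, 36000, 1200, seed = 71)
  m <- msc_spectrum(x, y, p)

  alpha <- band_average(m, 8, 13)
  expect_identical(alpha$n_bins, 10L)          # 8.0, 8.5, ..., 12.5
  expect_equal(alpha$value,
               mean(m$msc[m$freq >= 8 & m$freq < 13]))

  # partition additivity over the six canonical bands
  bands <- band_definitions()
  parts <- lapply(seq_len(nrow(bands)),
                  function(i) band_average(m, bands$lo[i], bands$hi[i]))
  nb <- vapply(parts, `[[`, integer(1), "n_bins")
  vals <- vapply(parts, `[[`, numeric(1), "value")
  whole <- band_average(m, 0, 100)
  expect_identical(sum(nb), whole$n_bins)
  expect_equal(sum(nb * vals) / sum(nb), whole$value, tolerance = 1e-12)

  expect_error(band_average(m, 650, 700), "no frequency bins")
})

test_that("band averaging excludes and counts undefined bins", {
  freq <- seq(0, 100, by = 0.5)
  msc <- rep(0.4, length(freq))
  msc[freq >= 13 & freq < 16] <- NA   # e.g. bins lost to a wide notch
  m <- structure(list(freq = freq, msc = msc, L = 19),
                 class = "coherence_spectrum")
  ba <- band_average(m, 13, 30)
  expect_identical(ba$n_bins, 34L)
  expect_identical(ba$n_undefined, 6L)
  expect_equal(ba$value, 0.4)
})

test_that("constant MSC spectra average to the constant in every band", {
  p <- welch_params(fs = 1200)
  x <- bandlimited_noise(2, 500, 36000, 1200, seed = 74)
  m <- msc_spectrum(x, x, p)   # identically 1
  bands <- band_definitions()
  for (i in seq_len(nrow(bands))) {
    expect_equal(band_average(m, bands$lo[i], bands$hi[i])$value, 1,
                 tolerance = 1e-12)
  }
})

test_that("zero-coherence bound has its closed form and Monte-Carlo calibration", {
  expect_equal(zero_coherence_bound(2, 0.05), 0.95)
  expect_equal(zero_coherence_bound(19, 0.05), 1 - 0.05^(1 / 18))
  expect_lt(zero_coherence_bound(38), zero_coherence_bound(19))
  expect_error(zero_coherence_bound(1), "L >= 2")

  # per-bin null MSC should exceed the bound ~5% of the time; the bound is
  # derived for independent segments, so use non-overlapping windows
  p <- welch_params(window_duration = 1, overlap = 0, fs = 300)
  exceed <- vapply(1:8, function(s) {
    x <- bandlimited_noise(0, 150, 19 * 300, 300, seed = 900 + s)
    y <- bandlimited_noise(0, 150, 19 * 300, 300, seed = 950 + s)
    m <- msc_spectrum(x, y, p)
    bound <- zero_coherence_bound(m$L, 0.05)
    mean(m$msc[m$freq > 0 & m$freq < 150] > bound, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(exceed) - 0.05), 0.02)
})
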