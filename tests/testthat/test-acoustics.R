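make_tone <- function(freq, p_rms, fs = 50e3, dur = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  sqrt(2) * p_rms * sin(2 * pi * freq * t)
}

test_that("PSD of a calibrated tone reads the SPL of its pressure", {
  psd <- compute_psd(make_tone(1000, 1), 50e3)
  # 1 Pa RMS -> 20 log10(1 / 20e-6) = 93.98 dB in the 1-kHz bin
  at_peak <- psd$level_db[psd$frequency == 1000]
  expect_equal(at_peak, 20 * log10(1 / 20e-6), tolerance = 1e-6)
  others <- psd$level_db[abs(psd$frequency - 1000) > 2]
  expect_true(all(others < at_peak - 40))
})

test_that("PSD is Parseval-consistent and floors at zero power", {
  withr::with_seed(5, {
    x <- rnorm(2e5, sd = 0.3)
  })
  psd <- compute_psd(x, 200e3)
  total <- sum(10^(psd$level_db / 10)) * (20e-6)^2
  expect_equal(total, mean(x^2), tolerance = 0.01)
  # full-band level equals the RMS level
  expect_equal(band_level(psd, 1, max(psd$frequency)),
               20 * log10(sqrt(mean(x^2)) / 20e-6), tolerance = 0.1)
  # silence hits the sentinel floor
  psd0 <- compute_psd(numeric(50e3), 50e3)
  expect_true(all(psd0$level_db == -120))
})

test_that("white noise of known variance gives the analytic flat density", {
  fs <- 200e3
  withr::with_seed(7, x <- rnorm(10 * fs, sd = 0.5))
  psd <- compute_psd(x, fs, method = "welch")
  # variance 0.25 Pa^2 spread over 0..100 kHz
  expected <- 10 * log10(0.25 / 1e5 / (20e-6)^2)
  mid <- psd$level_db[psd$frequency > 1000 & psd$frequency < 90000]
  expect_equal(mean(mid), expected, tolerance = 0.5)
})

test_that("PSD estimator rejects bad input", {
  expect_error(compute_psd(c(rnorm(5e4), NA), 50e3),
               class = "quietscope_data_quality")
  expect_error(compute_psd(rnorm(100), 50e3),
               class = "quietscope_data_quality")
})

test_that("band level integrates power, adds 3 dB on doubling", {
  psd <- compute_psd(make_tone(1000, 1), 50e3)
  # single-bin band equals that bin's level
  expect_equal(band_level(psd, 1000, 1000),
               psd$level_db[psd$frequency == 1000])
  # flat spectrum: level + 10 log10(bandwidth)
  flat <- psd
  flat$level_db <- rep(-10, nrow(flat))
  expect_equal(band_level(flat, 100, 24999), -10 + 10 * log10(24900),
               tolerance = 1e-9)
  # two equal tones at disjoint frequencies: +3.01 dB over one
  two <- compute_psd(make_tone(1000, 1) + make_tone(5000, 1), 50e3)
  expect_equal(band_level(two, 900, 5100),
               band_level(two, 900, 1100) + 10 * log10(2), tolerance = 0.01)
  expect_error(band_level(psd, 3000, 1000), class = "quietscope_range_error")
})

test_that("merging spectra switches source at the crossover", {
  fs <- 60e3
  lo <- compute_psd(make_tone(1000, 1, fs), fs, mic_id = "m_lo")
  hi <- compute_psd(make_tone(1000, 1, fs), fs, mic_id = "m_hi")
  # idempotence on identical spectra
  m <- merge_psds(lo, hi, crossover = 23e3)
  expect_equal(m$level_db, lo$level_db)
  # step input: low flat 0 dB, high flat 10 dB
  lo$level_db <- rep(0, nrow(lo)); hi$level_db <- rep(10, nrow(hi))
  m <- merge_psds(lo, hi, crossover = 23e3)
  expect_true(all(m$level_db[m$frequency < 23e3] == 0))
  expect_true(all(m$level_db[m$frequency >= 23e3] == 10))
  # band levels preserved exactly on each side
  expect_equal(band_level(m, 100, 22999), band_level(lo, 100, 22999))
  expect_equal(band_level(m, 23000, max(hi$frequency)),
               band_level(hi, 23000, max(hi$frequency)))
  # crossover above the high spectrum's coverage leaves only the low input
  m2 <- merge_psds(lo, hi, crossover = max(lo$frequency) + 1)
  expect_equal(m2$level_db, lo$level_db)
})

test_that("packaged species profiles load with their published anchors", {
  marm <- load_species_profile("marmoset")
  expect_equal(threshold_at(marm, 8000), 10.6, tolerance = 1e-6)
  for (sp in c("mouse_cba", "mouse_c57bl6j")) {
    prof <- load_species_profile(sp)
    expect_s3_class(prof, "species_profile")
    expect_gt(bandwidth_at(prof, 16e3), 0)
  }
  # C57BL/6J thresholds are elevated relative to CBA at high frequency
  cba <- load_species_profile("mouse_cba")
  b6 <- load_species_profile("mouse_c57bl6j")
  expect_gt(threshold_at(b6, 32e3), threshold_at(cba, 32e3))
  expect_error(load_species_profile("axolotl"),
               class = "quietscope_lookup_error")
  # no extrapolation outside the stated range
  expect_error(threshold_at(marm, 50), class = "quietscope_profile_range")
  expect_error(threshold_at(marm, 90e3), class = "quietscope_profile_range")
})

test_that("profile save/load round-trips", {
  prof <- species_profile("testfish", c(100, 1000, 10000), c(40, 20, 35),
                         bandwidth_a = 0.5, bandwidth_b = 0.8,
                         provenance = "synthetic test profile")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_species_profile(prof, path)
  back <- load_species_profile(path)
  expect_equal(back$threshold_freq, prof$threshold_freq)
  expect_equal(back$threshold_db, prof$threshold_db)
  expect_equal(back$bandwidth_a, prof$bandwidth_a)
  expect_equal(threshold_at(back, 1000), 20)
})

test_that("roex filters integrate to the species bandwidth", {
  # equivalent-rectangular property: integral of W over f equals Bs(fc),
  # checked by numeric quadrature over a wide p range
  for (p in c(10, 50, 200, 500)) {
    fc <- 8000
    bs <- 4 * fc / p
    f <- seq(1, 40000, by = 1)
    w <- (1 + p * abs(f - fc) / fc) * exp(-p * abs(f - fc) / fc)
    expect_equal(sum(w), bs, tolerance = 0.005)
  }
})

test_that("excitation pattern has unit gain on-center and the ERB white-noise gain", {
  fs <- 80e3
  prof <- load_species_profile("marmoset")
  # pure tone at a filter center: E(fc) = tone level
  tone <- compute_psd(make_tone(8000, 0.2, fs), fs)
  ep <- excitation_pattern(tone, prof, grid = 8000)
  expect_equal(ep$excitation_db, 20 * log10(0.2 / 20e-6), tolerance = 0.05)
  # white noise: E = N0 + 10 log10(Bs)
  withr::with_seed(9, wn <- rnorm(5 * fs, sd = 0.1))
  psd <- compute_psd(wn, fs, method = "welch")
  n0 <- 10 * log10(0.01 / 4e4 / (20e-6)^2)
  ep <- excitation_pattern(psd, prof, grid = c(2000, 8000))
  for (i in seq_len(2)) {
    expect_equal(ep$excitation_db[i],
                 n0 + 10 * log10(bandwidth_at(prof, ep$frequency[i])),
                 tolerance = 0.5)
  }
})

test_that("off-center tones match the quadrature oracle", {
  fs <- 80e3
  prof <- load_species_profile("marmoset")
  fc <- 8000
  bs <- bandwidth_at(prof, fc)
  f_tone <- fc + bs       # one bandwidth away
  tone <- compute_psd(make_tone(f_tone, 0.2, fs), fs)
  ep <- excitation_pattern(tone, prof, grid = fc)
  oracle <- roex_quadrature(tone$frequency, tone$level_db, fc, bs)
  expect_equal(ep$excitation_db, oracle, tolerance = 0.1)
  expect_lt(ep$excitation_db, 20 * log10(0.2 / 20e-6))
})

test_that("excitation is level-linear: +k dB in, +k dB out", {
  fs <- 60e3
  withr::with_seed(13, x <- rnorm(2 * fs, sd = 0.05))
  psd <- compute_psd(x, fs)
  prof <- load_species_profile("marmoset")
  grid <- 2^seq(log2(500), log2(16000), by = 0.5)
  ep0 <- excitation_pattern(psd, prof, grid = grid)
  for (k in c(6, 17.3)) {
    shifted <- psd
    shifted$level_db <- psd$level_db + k
    epk <- excitation_pattern(shifted, prof, grid = grid)
    expect_equal(epk$excitation_db, ep0$excitation_db + k,
                 tolerance = 1e-9)
  }
})

test_that("narrowband noise excitation approaches its band level", {
  fs <- 100e3
  fc <- 8000
  prof <- load_species_profile("marmoset")
  bs <- bandwidth_at(prof, fc)
  # noise confined to a band much narrower than Bs(fc), centred at fc
  withr::with_seed(21, {
    n <- 4 * fs
    spec_noise <- rnorm(n, sd = 0.02)
  })
  # bandpass by FFT masking to fc +/- bs/20
  sp <- fft(spec_noise)
  f_axis <- (seq_along(sp) - 1) * fs / length(sp)
  keep <- (f_axis > fc - bs / 20 & f_axis < fc + bs / 20) |
    (f_axis > fs - fc - bs / 20 & f_axis < fs - fc + bs / 20)
  sp[!keep] <- 0
  nb <- Re(fft(sp, inverse = TRUE)) / length(sp)
  psd <- compute_psd(nb, fs)
  ep <- excitation_pattern(psd, prof, grid = fc)
  bl <- band_level(psd, fc - bs / 2, fc + bs / 2)
  expect_equal(ep$excitation_db, bl, tolerance = 0.2)
})

test_that("threshold exceedance reports the signed margin and its summary", {
  prof <- load_species_profile("marmoset")
  grid <- 2^seq(log2(500), log2(16000), by = 0.25)
  thr <- threshold_at(prof, grid)
  # excitation everywhere 10 dB below threshold
  ep <- structure(tibble::tibble(frequency = grid,
                                 excitation_db = thr - 10,
                                 species = "marmoset"),
                  class = c("qs_excitation", class(tibble::tibble())))
  ex <- threshold_exceedance(ep, prof)
  g <- glance(ex)
  expect_equal(g$max_exceedance_db, -10, tolerance = 1e-9)
  expect_identical(g$n_above_threshold, 0L)
  # a single 20-dB peak is found at its frequency
  ep2 <- ep
  ep2$excitation_db[10] <- thr[10] + 20
  g2 <- glance(threshold_exceedance(ep2, prof))
  expect_equal(g2$max_exceedance_db, 20, tolerance = 1e-9)
  expect_equal(g2$frequency_at_max, grid[10])
  expect_identical(g2$n_above_threshold, 1L)
})

test_that("a microphone-noise-floor spectrum stays below the marmoset threshold", {
  # regression fixture for the silent-system scenario: a flat spectrum at a
  # low-noise calibration microphone's self-noise (about -26 dB SPL/Hz)
  prof <- load_species_profile("marmoset")
  f <- seq(1, 40000)
  floor_psd <- structure(
    tibble::tibble(frequency = as.numeric(f),
                   level_db = rep(-26, length(f)), mic = "floor"),
    class = c("qs_psd", class(tibble::tibble())))
  grid <- 2^seq(log2(150), log2(36000 / 2^(1 / 64)), by = 1 / 8)
  ep <- excitation_pattern(floor_psd, prof, grid = grid)
  ex <- threshold_exceedance(ep, prof)
  expect_true(all(ex$exceedance_db <= 0))
})
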