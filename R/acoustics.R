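#' Calibrated power spectral density at 1-Hz resolution
#'
#' Fourier-transforms a calibrated sound-pressure record and bins the
#' periodogram to 1-Hz resolution, yielding a spectral density in
#' dB SPL/Hz re 20 uPa. The default estimator is a single magnitude-squared
#' FFT of the whole record with the fine periodogram bins power-summed into
#' 1-Hz bands, which keeps the estimate Parseval-consistent: summing the
#' per-band powers recovers the mean-square pressure. A Welch option (1-s
#' Hann segments, 50% overlap) is provided for variance reduction.
#'
#' @param samples Sound pressure samples in pascal (after microphone
#'   sensitivity and gain calibration).
#' @param sample_rate Sampling rate, Hz (default 200 kHz).
#' @param mic_id Label carried through to the output.
#' @param method `"fft"` (single full-record periodogram, the default) or
#'   `"welch"`.
#' @param f_max Highest 1-Hz bin centre to report; defaults to just below the
#'   Nyquist frequency.
#'
#' @return A tibble of class `qs_psd` with columns `frequency` (Hz, 1-Hz
#'   spaced bin centres starting at 1 Hz), `level_db` (dB SPL/Hz) and `mic`.
#'   Zero-power bins carry the floor sentinel -120 dB.
#' @examples
#' fs <- 50e3
#' t <- seq(0, 1 - 1 / fs, by = 1 / fs)
#' psd <- compute_psd(sqrt(2) * sin(2 * pi * 1000 * t), fs)
#' psd[psd$frequency == 1000, ]
#' @export
compute_psd <- function(samples, sample_rate = 200e3, mic_id = "mic",
                        method = c("fft", "welch"), f_max = NULL) {
  method <- match.arg(method)
  if (anyNA(samples) || any(!is.finite(samples))) {
    abort("samples contain NA or non-finite values",
          class = "quietscope_data_quality")
  }
  n <- length(samples)
  if (n < sample_rate) {
    abort("need at least 1 s of samples", class = "quietscope_data_quality")
  }
  if (is.null(f_max)) f_max <- floor(sample_rate / 2) - 1

  if (method == "fft") {
    pw <- periodogram_power(samples, sample_rate)
  } else {
    seg <- as.integer(sample_rate)          # 1-s segments
    hop <- seg %/% 2L
    starts <- seq(1L, n - seg + 1L, by = hop)
    win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))  # Hann
    wnorm <- mean(win^2)
    acc <- NULL
    for (s in starts) {
      x <- samples[s:(s + seg - 1L)] * win
      p <- periodogram_power(x, sample_rate)
      p$power <- p$power / wnorm
      acc <- if (is.null(acc)) p else {
        acc$power <- acc$power + p$power
        acc
      }
    }
    acc$power <- acc$power / length(starts)
    pw <- acc
  }

  # power-sum fine FFT bins into 1-Hz bands centred on integer frequencies
  centre <- as.integer(round(pw$frequency))
  keep <- centre >= 1L & centre <= f_max
  band_power <- vapply(split(pw$power[keep], centre[keep]), sum, numeric(1))
  freq <- as.integer(names(band_power))
  full <- setNames(numeric(f_max), as.character(seq_len(f_max)))
  full[names(band_power)] <- band_power

  level <- ifelse(full > 0, 10 * log10(full / P_REF^2), DB_FLOOR)
  structure(
    tibble(frequency = as.numeric(seq_len(f_max)),
           level_db = pmax(as.numeric(level), DB_FLOOR),
           mic = mic_id),
    class = c("qs_psd", class(tibble())))
}

# one-sided periodogram: power (Pa^2) per fine bin; sums to mean(x^2)
periodogram_power <- function(x, sample_rate) {
  n <- length(x)
  sp <- abs(fft(x))^2 / n^2
  half <- n %/% 2L
  p <- sp[2:(half + 1L)]
  # double all bins except Nyquist (present only for even n)
  if (n %% 2L == 0L) {
    p[-half] <- 2 * p[-half]
  } else {
    p <- 2 * p
  }
  tibble(frequency = sample_rate * seq_len(half) / n, power = p)
}

#' Band sound pressure level from a PSD
#'
#' Integrates spectral power over `[f_lo, f_hi]` (1-Hz bins, so a power sum)
#' and returns the band level in dB SPL.
#'
#' @param psd A `qs_psd` tibble from [compute_psd()] or [merge_psds()].
#' @param f_lo,f_hi Band edges, Hz.
#'
#' @return Band level in dB SPL.
#' @examples
#' \dontrun{band_level(psd, 100, 40000)}
#' @export
band_level <- function(psd, f_lo, f_hi) {
  stopifnot(is.data.frame(psd))
  if (f_lo > f_hi) {
    abort("f_lo must not exceed f_hi", class = "quietscope_range_error")
  }
  sel <- psd$frequency >= f_lo & psd$frequency <= f_hi
  if (!any(sel)) {
    abort("band contains no PSD bins", class = "quietscope_range_error")
  }
  10 * log10(sum(10^(psd$level_db[sel] / 10)))
}

#' Merge two microphone spectra at a crossover frequency
#'
#' Combines a low-frequency and a high-frequency measurement of the same
#' sound into one spectrum: bins below the crossover come from `low`, bins at
#' or above it from `high`. Used when a low-noise-floor microphone covers the
#' audio band and an extended-range microphone covers the ultrasound band
#' (default crossover 23 kHz).
#'
#' @param low,high `qs_psd` tibbles.
#' @param crossover Crossover frequency, Hz.
#'
#' @return A `qs_psd` tibble; `mic` records both sources.
#' @export
merge_psds <- function(low, high, crossover = 23e3) {
  lo <- dplyr::filter(low, .data$frequency < crossover)
  hi <- dplyr::filter(high, .data$frequency >= crossover)
  if (nrow(hi) == 0 && crossover <= max(low$frequency)) {
    abort("high spectrum does not cover frequencies at/above the crossover",
          class = "quietscope_coverage_error")
  }
  if (nrow(lo) > 0 && nrow(hi) > 0 &&
      hi$frequency[1] - lo$frequency[nrow(lo)] > 1 + 1e-9) {
    abort("spectra leave a gap at the crossover",
          class = "quietscope_coverage_error")
  }
  out <- dplyr::bind_rows(lo, hi)
  structure(dplyr::arrange(out, .data$frequency),
            class = c("qs_psd", class(tibble())))
}

# roex(p) auditory filter weight; g = |f - fc| / fc
roex_weight <- function(g, p) (1 + p * g) * exp(-p * g)

#' Species-specific auditory excitation pattern
#'
#' Passes a calibrated power spectrum through a bank of rounded-exponential
#' (roex) auditory filters whose equivalent rectangular bandwidth follows the
#' species' tuning-bandwidth function `Bs(fc)`, converting dB SPL/Hz into an
#' excitation pattern in dB SPL that reflects the species' frequency
#' selectivity. The filter is the symmetric, level-independent
#' `W(g) = (1 + p g) exp(-p g)` with `g = |f - fc| / fc` and
#' `p = 4 fc / Bs(fc)`, so that the filter integrates exactly to `Bs(fc)`:
#' `E(fc) = 10 log10( sum W(g_i) 10^(L_i / 10) df )` over the 1-Hz PSD bins.
#'
#' @param psd A `qs_psd` tibble.
#' @param profile A [species_profile()].
#' @param grid Filter centre frequencies, Hz; default 64 points/octave
#'   log-spaced over the species hearing range (clipped to the PSD range).
#'
#' @return A tibble of class `qs_excitation` with columns `frequency`
#'   (centre frequency, Hz), `excitation_db` (dB SPL) and `species`.
#' @export
excitation_pattern <- function(psd, profile, grid = NULL) {
  stopifnot(is.data.frame(psd), inherits(profile, "species_profile"))
  if (is.null(grid)) {
    lo <- max(profile$range[1], min(psd$frequency) + 1)
    hi <- min(profile$range[2], max(psd$frequency))
    grid <- 2^seq(log2(lo), log2(hi), by = 1 / 64)
  }
  if (any(grid < profile$range[1] - 1e-9 | grid > profile$range[2] + 1e-9)) {
    abort("grid extends outside the species hearing range",
          class = "quietscope_profile_range")
  }
  pwr <- 10^(psd$level_db / 10)          # Pa^2-equivalent per 1-Hz bin
  f <- psd$frequency
  exc <- vapply(grid, function(fc) {
    bs <- bandwidth_at(profile, fc)
    p <- 4 * fc / bs
    w <- roex_weight(abs(f - fc) / fc, p)
    10 * log10(sum(w * pwr))             # df = 1 Hz
  }, numeric(1))
  structure(
    tibble(frequency = grid, excitation_db = exc, species = profile$species),
    class = c("qs_excitation", class(tibble())))
}

#' Excitation pattern versus hearing threshold
#'
#' Compares an excitation pattern against the species hearing threshold on
#' the pattern's frequency grid. Any sustained positive exceedance indicates
#' the sound can drive the species' auditory system at that frequency.
#'
#' @param ep A `qs_excitation` tibble from [excitation_pattern()].
#' @param profile The matching [species_profile()].
#'
#' @return A tibble of class `qs_exceedance` with columns `frequency`,
#'   `excitation_db`, `threshold_db` and `exceedance_db`. Use [glance()] for
#'   the summary (max exceedance, its frequency, bins above threshold).
#' @export
threshold_exceedance <- function(ep, profile) {
  stopifnot(is.data.frame(ep), inherits(profile, "species_profile"))
  thr <- threshold_at(profile, ep$frequency)
  structure(
    tibble(
      frequency = ep$frequency,
      excitation_db = ep$excitation_db,
      threshold_db = thr,
      exceedance_db = ep$excitation_db - thr,
      species = profile$species
    ),
    class = c("qs_exceedance", class(tibble())))
}

#' @export
glance.qs_exceedance <- function(x, ...) {
  i <- which.max(x$exceedance_db)
  tibble(
    species = x$species[1],
    max_exceedance_db = x$exceedance_db[i],
    frequency_at_max = x$frequency[i],
    n_above_threshold = sum(x$exceedance_db > 0),
    n_bins = nrow(x)
  )
}
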