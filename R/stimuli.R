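#' Tone pip specification
#'
#' A calibrated pure-tone pip: 0.2 s duration with 20-ms sine-squared
#' (raised-cosine) on/off ramps by default.
#'
#' @param frequency Tone frequency, Hz; must be below Nyquist.
#' @param level Sound level, dB SPL re 20 uPa.
#' @param duration Pip duration, s.
#' @param ramp On/off ramp duration, s; `2 * ramp` must not exceed
#'   `duration`.
#' @param sample_rate Sampling rate, Hz.
#'
#' @return An object of class `tone_pip`.
#' @export
tone_pip <- function(frequency, level, duration = 0.2, ramp = 0.020,
                     sample_rate = 200e3) {
  if (2 * ramp > duration) {
    abort("ramps longer than the pip: 2 * ramp must be <= duration",
          class = "quietscope_timing_error")
  }
  if (frequency >= sample_rate / 2) {
    abort("frequency at or above Nyquist", class = "quietscope_sampling_error")
  }
  structure(
    list(frequency = frequency, level = level, duration = duration,
         ramp = ramp, sample_rate = sample_rate),
    class = "tone_pip"
  )
}

# sine-squared on/off envelope; first and last samples are exactly zero
pip_envelope <- function(n, ramp_samples) {
  t_last <- n - 1
  i <- 0:t_last
  env <- rep(1, n)
  on <- i <= ramp_samples
  env[on] <- sin(pi * i[on] / (2 * ramp_samples))^2
  off <- i >= t_last - ramp_samples
  env[off] <- sin(pi * (t_last - i[off]) / (2 * ramp_samples))^2
  env
}

#' Render a calibrated tone pip
#'
#' Synthesizes the pip waveform with sine-squared ramps. Amplitude is set so
#' that the RMS pressure over the plateau equals the requested dB SPL;
#' `calibration_ref` converts pascal to output units (e.g. the pascal
#' produced by a unit-amplitude sample through the playback chain).
#'
#' @param pip A [tone_pip()].
#' @param calibration_ref Pascal per output unit (default 1: output in Pa).
#'
#' @return Numeric waveform; first and last samples are 0.
#' @examples
#' w <- make_pip(tone_pip(1000, 50))
#' length(w) # 0.2 s x 200 kHz
#' @export
make_pip <- function(pip, calibration_ref = 1) {
  stopifnot(inherits(pip, "tone_pip"))
  fs <- pip$sample_rate
  n <- round(pip$duration * fs)
  p_rms <- P_REF * 10^(pip$level / 20)
  amp <- sqrt(2) * p_rms / calibration_ref
  t <- (0:(n - 1)) / fs
  amp * sin(2 * pi * pip$frequency * t) * pip_envelope(n, round(pip$ramp * fs))
}

#' Semitone pip-frequency sequence
#'
#' Frequencies of a pip sequence stepping one semitone (ratio `2^(1/12)`) per
#' pip; the descending sequence is the exact reverse of the ascending one.
#'
#' @param start Starting frequency, Hz (the lowest frequency in either
#'   direction).
#' @param n_pips Number of pips.
#' @param direction `"ascending"` or `"descending"`.
#'
#' @return Numeric vector of frequencies, Hz.
#' @examples
#' tail(semitone_sequence(440, 73), 1) # 28160 Hz, six octaves up
#' @export
semitone_sequence <- function(start, n_pips,
                              direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  stopifnot(n_pips >= 1)
  f <- start * 2^((seq_len(n_pips) - 1) / 12)
  if (direction == "descending") rev(f) else f
}

#' Frequency-by-level stimulus grid for FRA mapping
#'
#' The trial-type grid of a frequency-response-area experiment: frequencies
#' geometric at `step_semitones` semitone spacing, levels arithmetic. The
#' defaults give 31 frequencies at 2-semitone steps from 440 Hz (spanning
#' five octaves to 14080 Hz) crossed with 5 levels from 5 to 65 dB SPL in
#' 15-dB steps: 155 trial types. A 25-frequency variant ending at 7040 Hz is
#' available via `n_freqs = 25`.
#'
#' Trial timing follows the 3-s trial structure: 0.6 s pre-stimulus, 0.6 s
#' stimulus (three contiguous 0.2-s pips of the trial frequency), 1.8 s
#' post-stimulus.
#'
#' @param start Lowest frequency, Hz.
#' @param step_semitones Frequency step, semitones.
#' @param n_freqs Number of frequencies.
#' @param level_lo,level_hi Level range, dB SPL.
#' @param level_step Level step, dB; must divide the range.
#' @param pip_count Pips per trial.
#' @param timing Named numeric `c(pre, stim, post)` in seconds.
#'
#' @return An object of class `stimulus_grid`.
#' @examples
#' g <- fra_grid()
#' length(g$frequencies) * length(g$levels) # 155
#' @export
fra_grid <- function(start = 440, step_semitones = 2, n_freqs = 31,
                     level_lo = 5, level_hi = 65, level_step = 15,
                     pip_count = 3,
                     timing = c(pre = 0.6, stim = 0.6, post = 1.8)) {
  span <- level_hi - level_lo
  if (abs(span / level_step - round(span / level_step)) > 1e-9) {
    abort("level range is not divisible by level_step",
          class = "quietscope_grid_error")
  }
  structure(
    list(
      frequencies = start * 2^(step_semitones * (seq_len(n_freqs) - 1) / 12),
      levels = seq(level_lo, level_hi, by = level_step),
      pip_count = pip_count,
      timing = timing
    ),
    class = "stimulus_grid"
  )
}

#' @export
print.stimulus_grid <- function(x, ...) {
  cat("<stimulus_grid>\n")
  cat(sprintf("  %d frequencies: %.0f - %.0f Hz\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies)))
  cat(sprintf("  %d levels: %g - %g dB SPL\n",
              length(x$levels), min(x$levels), max(x$levels)))
  cat(sprintf("  %d trial types; trial %g s (pre %g / stim %g / post %g)\n",
              length(x$frequencies) * length(x$levels), sum(x$timing),
              x$timing[["pre"]], x$timing[["stim"]], x$timing[["post"]]))
  invisible(x)
}

#' @export
as_tibble.stimulus_grid <- function(x, ...) {
  tidyr::expand_grid(frequency = x$frequencies, level = x$levels)
}

#' Pseudo-randomized session schedule
#'
#' Builds a reproducible trial schedule: `cycles` repetitions of the full
#' grid, each cycle an independent seeded permutation of all trial types
#' (every frequency-level cell appears exactly once per cycle).
#'
#' @param grid A [fra_grid()].
#' @param cycles Number of cycles (default 10).
#' @param seed Integer seed; the same seed reproduces the schedule exactly.
#'
#' @return A tibble of class `session_schedule` with columns `trial`,
#'   `cycle`, `frequency`, `level`, `t_start` (trial onset, s). The grid is
#'   attached as attribute `grid`.
#' @examples
#' sched <- session_schedule(fra_grid(), cycles = 10, seed = 1)
#' nrow(sched) # 1550
#' @export
session_schedule <- function(grid, cycles = 10, seed = 1) {
  stopifnot(inherits(grid, "stimulus_grid"), cycles >= 1)
  cells <- as_tibble(grid)
  trial_dur <- sum(grid$timing)
  sched <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(cycles), function(cy) {
      dplyr::mutate(cells[sample.int(nrow(cells)), ], cycle = cy)
    })
  })
  sched <- dplyr::mutate(sched,
                         trial = dplyr::row_number(),
                         t_start = (.data$trial - 1) * trial_dur)
  out <- dplyr::select(sched, "trial", "cycle", "frequency", "level", "t_start")
  attr(out, "grid") <- grid
  class(out) <- c("session_schedule", class(tibble()))
  out
}

#' Render one trial's audio
#'
#' A full trial waveform: silence during the pre-stimulus window, `pip_count`
#' contiguous calibrated pips of the trial frequency filling the stimulus
#' window, then post-stimulus silence.
#'
#' @param frequency,level Trial frequency (Hz) and level (dB SPL).
#' @param grid A [fra_grid()] supplying timing and pip count.
#' @param sample_rate Sampling rate, Hz.
#' @param calibration_ref Pascal per output unit (see [make_pip()]).
#'
#' @return Numeric waveform of length `sum(timing) * sample_rate`.
#' @export
render_trial_audio <- function(frequency, level, grid = fra_grid(),
                               sample_rate = 200e3, calibration_ref = 1) {
  stopifnot(inherits(grid, "stimulus_grid"))
  if (frequency >= sample_rate / 2) {
    abort("frequency at or above Nyquist", class = "quietscope_sampling_error")
  }
  tm <- grid$timing
  pip_dur <- tm[["stim"]] / grid$pip_count
  pip <- make_pip(tone_pip(frequency, level, duration = pip_dur,
                           sample_rate = sample_rate),
                  calibration_ref = calibration_ref)
  n_total <- round(sum(tm) * sample_rate)
  wave <- numeric(n_total)
  offset <- round(tm[["pre"]] * sample_rate)
  for (k in seq_len(grid$pip_count)) {
    i0 <- offset + (k - 1) * length(pip)
    wave[(i0 + 1):(i0 + length(pip))] <- pip
  }
  wave
}

#' Write a session schedule to CSV
#'
#' @param sched A [session_schedule()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_schedule_csv <- function(sched, path) {
  df <- as.data.frame(sched)[, c("trial", "cycle", "frequency", "level",
                                 "t_start")]
  names(df) <- c("trial_index", "cycle", "frequency_hz", "level_db_spl",
                 "t_start_s")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a session schedule from CSV
#'
#' @param path CSV written by [write_schedule_csv()].
#' @param grid Optional [fra_grid()] to attach.
#' @return A `session_schedule` tibble.
#' @export
read_schedule_csv <- function(path, grid = NULL) {
  df <- utils::read.csv(path)
  out <- tibble(
    trial = df$trial_index, cycle = df$cycle,
    frequency = df$frequency_hz, level = df$level_db_spl,
    t_start = df$t_start_s
  )
  if (!is.null(grid)) attr(out, "grid") <- grid
  class(out) <- c("session_schedule", class(tibble()))
  out
}
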