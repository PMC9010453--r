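#' Simulation configuration
#'
#' Study conditions for the synthetic two-photon session generator. Defaults
#' emulate the reference acquisition: 653 x 652 frames at 23.5 fps with
#' 0.585-um pixels, GCaMP6s-like kinetics, heartbeat motion around 4 Hz plus
#' a slow drift, with the total excursion capped at 5 px per axis, shot-like
#' noise with variance proportional to signal, and a diffuse neuropil
#' background.
#'
#' @param frame_shape `c(rows, cols)` in pixels.
#' @param frame_rate Frames per second.
#' @param pixel_size Pixel size, m.
#' @param n_neurons Number of labelled neurons.
#' @param neuron_radius Soma radius, px.
#' @param baseline_f Mean soma baseline fluorescence (arbitrary counts).
#' @param peak_dff Range of peak response amplitudes sampled per neuron
#'   (dF/F units).
#' @param rise_tau,decay_tau Calcium indicator kinetics, s (GCaMP6s-like
#'   defaults 0.2 / 1.5 s).
#' @param gain Shot-noise gain: noise variance is `gain * signal` counts^2.
#' @param read_noise_sd Additive read noise standard deviation, counts.
#' @param neuropil_level Diffuse background level, counts.
#' @param heartbeat_hz,heartbeat_amp Fast motion component: frequency (Hz)
#'   and amplitude (px).
#' @param drift_px Slow drift over the session, px.
#' @param motion_cap Hard cap on per-axis displacement, px.
#' @param seed Integer seed; every generator is a pure function of
#'   `(config, seed)`.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(frame_shape = c(653, 652),
                       frame_rate = 23.5,
                       pixel_size = 0.585e-6,
                       n_neurons = 50,
                       neuron_radius = 8,
                       baseline_f = 100,
                       peak_dff = c(0.1, 1.0),
                       rise_tau = 0.2,
                       decay_tau = 1.5,
                       gain = 0.2,
                       read_noise_sd = 2,
                       neuropil_level = 20,
                       heartbeat_hz = 4,
                       heartbeat_amp = 2,
                       drift_px = 3,
                       motion_cap = 5,
                       seed = 1) {
  if (heartbeat_amp + drift_px > motion_cap) {
    abort("heartbeat amplitude + drift exceeds the motion cap",
          class = "quietscope_config_error")
  }
  structure(
    list(frame_shape = as.integer(frame_shape), frame_rate = frame_rate,
         pixel_size = pixel_size, n_neurons = as.integer(n_neurons),
         neuron_radius = neuron_radius, baseline_f = baseline_f,
         peak_dff = peak_dff, rise_tau = rise_tau, decay_tau = decay_tau,
         gain = gain, read_noise_sd = read_noise_sd,
         neuropil_level = neuropil_level, heartbeat_hz = heartbeat_hz,
         heartbeat_amp = heartbeat_amp, drift_px = drift_px,
         motion_cap = motion_cap, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Sample a ground-truth neuron population
#'
#' Places non-overlapping somas (centre distance > 2 x radius) uniformly in
#' the frame, draws best frequencies log-uniformly over the stimulus grid
#' (uniform over the geometric grid frequencies), best levels uniformly over
#' the grid levels (so low best levels such as 20 dB SPL occur), and assigns
#' each neuron a V-, I- or O-shaped tuning surface with GCaMP6s-like
#' kinetics. The recorded `bf`/`bl` are the argmax of the neuron's
#' [fra_response()] surface over the grid, so parameter-recovery tests have
#' an exact truth.
#'
#' @param config A [sim_config()].
#' @param grid A [fra_grid()].
#'
#' @return A list of `neuron_truth` objects; also available as a tibble via
#'   [truth_table()].
#' @export
make_population <- function(config, grid) {
  stopifnot(inherits(config, "sim_config"), inherits(grid, "stimulus_grid"))
  withr::with_seed(config$seed, {
    ny <- config$frame_shape[1]; nx <- config$frame_shape[2]
    r <- config$neuron_radius
    # keep somas clear of the frame edge by the motion excursion, so moving
    # cells never leave (or wrap around) the field of view
    margin <- ceiling(r + config$motion_cap + 1)
    centers <- matrix(numeric(0), 0, 2)
    for (i in seq_len(config$n_neurons)) {
      placed <- FALSE
      for (try in seq_len(2000)) {
        cand <- c(runif(1, margin, ny - margin), runif(1, margin, nx - margin))
        if (nrow(centers) == 0 ||
            min((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >
              (2 * r)^2) {
          centers <- rbind(centers, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort("cannot place neurons without overlap; lower n_neurons or radius",
              class = "quietscope_density_error")
      }
    }
    lev_range <- range(grid$levels)
    purrr::map(seq_len(config$n_neurons), function(i) {
      shape <- sample(c("V", "I", "O"), 1, prob = c(0.5, 0.25, 0.25))
      n <- structure(
        list(
          id = i,
          center = centers[i, ],
          radius = r,
          bf = sample(grid$frequencies, 1),
          bl = sample(grid$levels, 1),
          fra_shape = shape,
          bw_oct = runif(1, 0.5, 1.0),
          level_slope = runif(1, 0.5, 1.5),
          level_sigma = 15,
          peak_amp = runif(1, config$peak_dff[1], config$peak_dff[2]),
          level_range = lev_range,
          rise_tau = config$rise_tau,
          decay_tau = config$decay_tau,
          baseline = config$baseline_f * runif(1, 0.7, 1.3)
        ),
        class = "neuron_truth"
      )
      # record the grid argmax of the tuning surface as the ground truth
      surf <- as_tibble(grid)
      surf$amp <- fra_response(n, surf$frequency, surf$level)
      top <- surf[order(surf$level, surf$frequency), ]
      best <- top[which.max(top$amp), ]
      n$bf <- best$frequency
      n$bl <- best$level
      n
    })
  })
}

#' Ground-truth table of a population
#'
#' @param population List from [make_population()].
#' @return Tibble with one row per neuron (id, centre, radius, bf, bl,
#'   shape, peak amplitude).
#' @export
truth_table <- function(population) {
  purrr::map_dfr(population, function(n) {
    tibble(id = n$id, row = n$center[1], col = n$center[2],
           radius = n$radius, bf = n$bf, bl = n$bl,
           fra_shape = n$fra_shape, peak_amp = n$peak_amp)
  })
}

#' Expected response amplitude of a tuning surface
#'
#' Parametric frequency-response-area surfaces of the three classical
#' shapes. All are Gaussian in log2 frequency around the neuron's preferred
#' frequency with bandwidth `bw_oct` octaves:
#' * `V`: bandwidth widens with level (`level_slope`) and gain grows
#'   monotonically with level, so the grid maximum sits at the highest
#'   level;
#' * `I`: level-independent bandwidth with the same monotone level gain;
#' * `O`: separable Gaussians in log2 frequency and in level, peaked at the
#'   neuron's `(bf, bl)`.
#'
#' @param neuron A `neuron_truth` from [make_population()].
#' @param frequency Stimulus frequency, Hz (vectorized).
#' @param level Stimulus level, dB SPL (vectorized).
#' @return Expected dF/F response amplitude.
#' @export
fra_response <- function(neuron, frequency, level) {
  stopifnot(inherits(neuron, "neuron_truth"))
  lr <- neuron$level_range
  lfrac <- (level - lr[1]) / (lr[2] - lr[1])
  df_oct <- log2(frequency) - log2(neuron$bf)
  # bw_oct is a full width at half maximum in octaves; convert to the
  # Gaussian sigma
  sig0 <- neuron$bw_oct / (2 * sqrt(2 * log(2)))
  gain <- (0.25 + 0.75 * lfrac)            # monotone, 1 at the top level
  amp <- switch(
    neuron$fra_shape,
    V = {
      sig <- sig0 * (0.5 + neuron$level_slope * lfrac)
      gain * exp(-0.5 * (df_oct / sig)^2)
    },
    I = gain * exp(-0.5 * (df_oct / sig0)^2),
    O = exp(-0.5 * (df_oct / sig0)^2) *
      exp(-0.5 * ((level - neuron$bl) / neuron$level_sigma)^2)
  )
  neuron$peak_amp * amp
}

# normalized double-exponential calcium kernel sampled at the frame rate;
# scaled so a unit square drive of stim_frames frames peaks at 1
calcium_kernel <- function(rise_tau, decay_tau, frame_rate, stim_frames) {
  t <- seq(0, 6 * decay_tau, by = 1 / frame_rate)
  h <- exp(-t / decay_tau) - exp(-t / rise_tau)
  drive <- rep(1, stim_frames)
  m <- max(convolve_open(drive, h))
  h / m
}

convolve_open <- function(x, k) {
  n <- length(x) + length(k) - 1
  stats::convolve(c(x, numeric(length(k) - 1)),
                  rev(c(k, numeric(length(x) - 1))), type = "circular")[1:n]
}

#' Ideal dF/F trace of one neuron over a session
#'
#' Convolves the per-trial drive (the neuron's expected response amplitude,
#' on during each trial's stimulus window) with a double-exponential calcium
#' impulse response, producing the noise-free dF/F trace the imaging
#' pipeline should recover. The kernel is normalized so a trial's peak dF/F
#' equals its [fra_response()] amplitude.
#'
#' @param neuron A `neuron_truth`.
#' @param schedule A [session_schedule()] (grid attached).
#' @param frame_rate Frames per second.
#' @return Numeric dF/F trace of length `n_trials * frames_per_trial`.
#' @export
simulate_trace <- function(neuron, schedule, frame_rate) {
  grid <- attr(schedule, "grid")
  stopifnot(!is.null(grid))
  win <- trial_windows(grid, frame_rate)
  nft <- win$frames_per_trial
  n_frames <- nrow(schedule) * nft
  drive <- numeric(n_frames)
  amps <- fra_response(neuron, schedule$frequency, schedule$level)
  for (i in seq_len(nrow(schedule))) {
    drive[(i - 1) * nft + win$stim] <- amps[i]
  }
  k <- calcium_kernel(neuron$rise_tau, neuron$decay_tau, frame_rate,
                      length(win$stim))
  convolve_open(drive, k)[seq_len(n_frames)]
}

# heartbeat + drift motion trajectory; pure function of (config, seed).
# The heartbeat carries ~5% beat-to-beat frequency jitter (heart-rate
# variability): a metronomic sinusoid would phase-lock to the frame clock
# and collapse the motion onto a few discrete positions, which real
# cardiac motion never does.
motion_trajectory <- function(config, n_frames) {
  t <- (seq_len(n_frames) - 1) / config$frame_rate
  withr::with_seed(config$seed + 1L, {
    ph <- runif(2, 0, 2 * pi)
    dir <- sample(c(-1, 1), 2, replace = TRUE)
    dphi <- 2 * pi * config$heartbeat_hz / config$frame_rate *
      (1 + 0.05 * rnorm(n_frames))
    phase <- cumsum(dphi)
    dy <- config$heartbeat_amp * sin(phase + ph[1]) +
      dir[1] * config$drift_px * t / max(t[length(t)], 1e-9)
    dx <- config$heartbeat_amp * sin(phase + ph[2]) +
      dir[2] * config$drift_px * t / max(t[length(t)], 1e-9)
    tibble(frame = seq_len(n_frames), dy = dy, dx = dx)
  })
}

# Fourier (sinc-interpolated) subpixel translation; deliberately a different
# interpolator from the bilinear one used by the registration engine
fourier_shift <- function(frame, dy, dx) {
  d <- dim(frame)
  ky <- c(0:floor(d[1] / 2), -(ceiling(d[1] / 2) - 1):-1) / d[1]
  kx <- c(0:floor(d[2] / 2), -(ceiling(d[2] / 2) - 1):-1) / d[2]
  ramp <- exp(-2i * pi * (outer(ky * dy, kx * dx, `+`)))
  Re(fft(fft(frame) * ramp, inverse = TRUE)) / prod(d)
}

#' Render a synthetic two-photon session
#'
#' Composes the movie: Gaussian soma profiles scaled by each neuron's ideal
#' dF/F trace on top of a diffuse neuropil background, rigid motion applied
#' by Fourier (sinc) subpixel translation, and Gaussian shot-like noise with
#' variance `read_noise_sd^2 + gain * signal`. Emits the movie, the true ROI
#' masks, the ground-truth table and the per-frame true displacements.
#'
#' @param population From [make_population()].
#' @param config The [sim_config()] used to build the population.
#' @param schedule A [session_schedule()] (grid attached).
#' @param motion,noise Logical switches; with both off the movie is the
#'   ideal scene and the analysis pipeline recovers each neuron's simulated
#'   dF/F.
#'
#' @return List with `movie` ([qs_movie()]), `rois` (list of [roi_mask()]),
#'   `truth` ([truth_table()] tibble), `displacements` (tibble frame, dy,
#'   dx), `traces` (matrix of ideal dF/F, frames x neurons).
#' @export
render_session <- function(population, config, schedule,
                           motion = TRUE, noise = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  grid <- attr(schedule, "grid")
  win <- trial_windows(grid, config$frame_rate)
  nft <- win$frames_per_trial
  n_trials <- nrow(schedule)
  n_frames <- n_trials * nft
  ny <- config$frame_shape[1]; nx <- config$frame_shape[2]
  np <- ny * nx

  # static background: diffuse level plus a few broad blobs for registration
  # texture
  bg <- withr::with_seed(config$seed + 2L, {
    field <- matrix(config$neuropil_level, ny, nx)
    if (config$neuropil_level > 0) {
      n_blob <- max(3L, as.integer(round(ny * nx / 1500)))
      for (b in seq_len(n_blob)) {
        cy <- runif(1, 1, ny); cx <- runif(1, 1, nx)
        s <- runif(1, 3, 8) * config$neuron_radius / 4
        a <- config$neuropil_level * runif(1, 0.2, 0.6)
        field <- field + a * exp(-0.5 * (outer((1:ny - cy)^2,
                                               (1:nx - cx)^2, `+`)) / s^2)
      }
    }
    field
  })

  scene <- matrix(as.numeric(bg), np, n_frames)
  traces <- matrix(0, n_frames, length(population))
  for (j in seq_along(population)) {
    nrn <- population[[j]]
    dff <- simulate_trace(nrn, schedule, config$frame_rate)
    traces[, j] <- dff
    hw <- ceiling(nrn$radius * 2)
    rows <- max(1, round(nrn$center[1]) - hw):min(ny, round(nrn$center[1]) + hw)
    cols <- max(1, round(nrn$center[2]) - hw):min(nx, round(nrn$center[2]) + hw)
    # sigma = radius/2 keeps ~86% of the soma's emission inside the nominal
    # mask (somatic GCaMP labelling is compact; light does not spill far
    # beyond the soma)
    sig <- nrn$radius / 2
    prof <- exp(-0.5 * (outer((rows - nrn$center[1])^2,
                              (cols - nrn$center[2])^2, `+`)) / sig^2)
    lin <- as.vector(outer(rows, (cols - 1) * ny, `+`))
    scene[lin, ] <- scene[lin, ] +
      outer(as.vector(prof) * nrn$baseline, 1 + dff)
  }

  if (motion) {
    disp <- motion_trajectory(config, n_frames)
    if (max(abs(c(disp$dy, disp$dx))) > config$motion_cap) {
      abort("motion trajectory exceeds the configured cap",
            class = "quietscope_config_error")
    }
  } else {
    disp <- tibble(frame = seq_len(n_frames), dy = 0, dx = 0)
  }

  withr::with_seed(config$seed + 3L, {
    for (k in seq_len(n_frames)) {
      fr <- matrix(scene[, k], ny, nx)
      if (motion && (disp$dy[k] != 0 || disp$dx[k] != 0)) {
        fr <- fourier_shift(fr, disp$dy[k], disp$dx[k])
      }
      if (noise) {
        fr <- fr + rnorm(np, sd = sqrt(config$read_noise_sd^2 +
                                         config$gain * pmax(fr, 0)))
      }
      scene[, k] <- fr
    }
  })

  dim(scene) <- c(ny, nx, n_frames)
  movie <- qs_movie(scene, frame_rate = config$frame_rate,
                    trial = rep(seq_len(n_trials), each = nft),
                    pixel_size = config$pixel_size)
  rois <- purrr::map(population, function(nrn) {
    hw <- ceiling(nrn$radius)
    rows <- max(1, floor(nrn$center[1] - hw)):min(ny, ceiling(nrn$center[1] + hw))
    cols <- max(1, floor(nrn$center[2] - hw)):min(nx, ceiling(nrn$center[2] + hw))
    cand <- as.matrix(expand.grid(row = rows, col = cols))
    keep <- (cand[, 1] - nrn$center[1])^2 + (cand[, 2] - nrn$center[2])^2 <=
      nrn$radius^2
    roi_mask(cand[keep, , drop = FALSE], label = sprintf("n%03d", nrn$id),
             kind = "soma", dim = c(ny, nx))
  })
  list(movie = movie, rois = rois, truth = truth_table(population),
       displacements = disp, traces = traces)
}
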