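# Independent oracles used across tests.

# Paraxial ray-transfer-matrix (ABCD) oracle for the focal depth shift:
# propagates a marginal ray from the DvCL exit plane through the
# scan-lens / tube-lens / objective chain (telecentric spacings) and finds
# the geometric focus behind the objective. Independent of the closed-form
# vergence expression used by focal_depth_shift().
abcd_depth_shift <- function(aod, relay, chirp_rate) {
  T_ <- function(d) matrix(c(1, 0, d, 1), 2, 2)
  L_ <- function(f) matrix(c(1, -1 / f, 0, 1), 2, 2)
  f_chirp <- chirp_focal_length(aod, relay, chirp_rate)
  v0 <- 1 / relay$f_dvcl - 1 / f_chirp
  fs <- relay$f_scan; ft <- relay$f_tube; fo <- relay$f_objective
  sys <- L_(fo) %*% T_(ft + fo) %*% L_(ft) %*% T_(fs + ft) %*% L_(fs) %*% T_(fs)
  ray <- sys %*% c(1e-4, -v0 * 1e-4)   # (height, slope), converging bundle
  z_focus <- -ray[1] / ray[2]
  z_focus - fo
}

# Brute-force numeric quadrature of the roex filter output for an arbitrary
# input power spectrum defined on 1-Hz bins.
roex_quadrature <- function(freq, level_db, fc, bs) {
  p <- 4 * fc / bs
  g <- abs(freq - fc) / fc
  w <- (1 + p * g) * exp(-p * g)
  10 * log10(sum(w * 10^(level_db / 10)))
}

# small smooth synthetic cell image for registration tests
synthetic_cell_image <- function(n = 64, n_cells = 6, seed = 42) {
  withr::with_seed(seed, {
    img <- matrix(0, n, n)
    for (k in seq_len(n_cells)) {
      cy <- runif(1, 10, n - 10); cx <- runif(1, 10, n - 10)
      s <- runif(1, 1.5, 3)
      img <- img + exp(-0.5 * outer((1:n - cy)^2, (1:n - cx)^2, `+`) / s^2)
    }
    img
  })
}

# integer-shift an image with zero fill (independent of shift_frame's
# bilinear interpolation)
integer_shift <- function(img, dy, dx) {
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  ys <- (1:n) - dy; xs <- (1:m) - dx
  ok_y <- ys >= 1 & ys <= n; ok_x <- xs >= 1 & xs <= m
  out[ok_y, ok_x] <- img[ys[ok_y], xs[ok_x]]
  out
}

# tiny default simulated session shared by pipeline tests; the spatial
# downscale uses coarser pixels, so the physical tissue motion (heartbeat
# ~1 um, drift ~2 um) is correspondingly smaller in pixel units
tiny_session <- function(n_neurons = 4, cycles = 2, frame_shape = c(40, 40),
                         frame_rate = 10, seed = 11, motion = TRUE,
                         noise = TRUE, neuropil_level = 20, ...) {
  grid <- fra_grid(n_freqs = 5, step_semitones = 4,
                   level_lo = 5, level_hi = 65, level_step = 30)
  sched <- session_schedule(grid, cycles = cycles, seed = seed)
  cfg <- sim_config(frame_shape = frame_shape, frame_rate = frame_rate,
                    n_neurons = n_neurons, neuron_radius = 2.5,
                    peak_dff = c(0.4, 1.0), neuropil_level = neuropil_level,
                    heartbeat_amp = 0.5, drift_px = 0.75, motion_cap = 1.25,
                    seed = seed, ...)
  pop <- make_population(cfg, grid)
  ses <- render_session(pop, cfg, sched, motion = motion, noise = noise)
  list(grid = grid, sched = sched, cfg = cfg, pop = pop, ses = ses)
}
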