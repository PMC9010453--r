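#' Cylindrical-lens focal length induced by a linear AOD chirp
#'
#' A linear frequency chirp at rate `chirp_rate` across an AOD makes the
#' deflected beam diverge (or converge) on the chirped axis exactly as if a
#' cylindrical lens of focal length `F = v^2 / (lambda * |r|)` had been
#' inserted, where `v` is the acoustic velocity and `lambda` the optical
#' wavelength. The returned focal length carries the sign of the chirp rate;
#' a zero rate returns `Inf` (no chirp-induced focal power).
#'
#' @param aod An [aod_spec()].
#' @param relay A [relay_spec()] (supplies the wavelength).
#' @param chirp_rate Frequency sweep rate, Hz/s. May be negative.
#'
#' @return Signed focal length in metres; `Inf` at rate 0.
#' @examples
#' chirp_focal_length(aod_spec(), relay_spec(), 30e6 / 65.3e-6)
#' @export
chirp_focal_length <- function(aod, relay, chirp_rate) {
  stopifnot(inherits(aod, "aod_spec"), inherits(relay, "relay_spec"))
  if (!is.finite(chirp_rate)) {
    abort("chirp_rate must be finite", class = "quietscope_invalid_spec")
  }
  if (aod$acoustic_velocity <= 0 || relay$wavelength <= 0) {
    abort("acoustic velocity and wavelength must be positive",
          class = "quietscope_invalid_spec")
  }
  if (chirp_rate == 0) return(Inf)
  sign(chirp_rate) * aod$acoustic_velocity^2 /
    (relay$wavelength * abs(chirp_rate))
}

#' Nominal line time for a collimating chirp
#'
#' The chirp rate that the divergence compensation lens (DvCL) exactly
#' collimates is `r = v^2 / (lambda * f_dvcl)`; sweeping the full AOD
#' bandwidth `B` at that rate takes `T = B * lambda * f_dvcl / v^2`. With the
#' defaults (B = 30 MHz, lambda = 920 nm, f = 1000 mm, v = 650 m/s) this is
#' the 65.3-us line of the reference design.
#'
#' @inheritParams chirp_focal_length
#' @param rounding Reporting quantum in seconds (default 0.1 us, the
#'   convention used throughout the frame-geometry calculators); use `0` for
#'   the continuous value.
#'
#' @return Line time in seconds.
#' @examples
#' nominal_line_time(aod_spec(), relay_spec(f_dvcl = 1.0)) # 65.3 us
#' @export
nominal_line_time <- function(aod, relay, rounding = 0.1e-6) {
  stopifnot(inherits(aod, "aod_spec"), inherits(relay, "relay_spec"))
  if (is.null(relay$f_dvcl)) {
    abort("relay has no DvCL focal length (pointing mode); set f_dvcl",
          class = "quietscope_config_error")
  }
  t <- aod$bandwidth * relay$wavelength * relay$f_dvcl /
    aod$acoustic_velocity^2
  if (rounding > 0) t <- round(t / rounding) * rounding
  t
}

#' Nominal (collimating) chirp rate
#'
#' @inheritParams nominal_line_time
#' @return Chirp rate in Hz/s at which [chirp_focal_length()] equals the DvCL
#'   focal length, computed from the un-quantized line time.
#' @export
nominal_chirp_rate <- function(aod, relay) {
  aod$bandwidth / nominal_line_time(aod, relay, rounding = 0)
}

#' Raster frame geometry
#'
#' Derives the full-frame raster geometry from a chirp program: pixels per
#' line from the digitizer rate, lines per frame (one pixel shorter on the
#' slow axis, so that the y chirp range is "one pixel" short of the full
#' bandwidth), the frame rate, the field of view and pixel size, and the dark
#' periphery fraction lost to the AOD transition time between lines.
#'
#' @inheritParams chirp_focal_length
#' @param program A [chirp_program()]; when `NULL`, the nominal program for
#'   `relay$f_dvcl` at a 10-MHz digitizer rate is used.
#'
#' @return A one-row tibble of class `frame_geometry` with columns
#'   `line_time_s`, `pixels_per_line`, `lines_per_frame`, `frame_rate_hz`,
#'   `fov_m`, `pixel_size_m`, `dark_fraction`.
#' @examples
#' raster_frame_geometry(aod_spec(), relay_spec(f_dvcl = 1.0))
#' @export
raster_frame_geometry <- function(aod, relay, program = NULL) {
  stopifnot(inherits(aod, "aod_spec"), inherits(relay, "relay_spec"))
  if (is.null(program)) {
    lt <- nominal_line_time(aod, relay)
    program <- chirp_program(
      chirp_rate = aod$bandwidth / lt,
      line_time = lt,
      bandwidth = aod$bandwidth
    )
  }
  lt <- program$line_time
  if (program$line_time_rounding > 0) {
    lt <- round(lt / program$line_time_rounding) * program$line_time_rounding
  }
  # tolerate float representation of quantized line times (e.g. 49.0 us x
  # 10 MHz must count as exactly 490 pixels)
  px <- floor(lt * program$sample_rate + 1e-6)
  if (px < 2) {
    abort("degenerate frame: fewer than 2 pixels per line",
          class = "quietscope_degenerate_frame")
  }
  lines <- px - 1
  fr <- 1 / (lines * lt)
  fov <- fov_and_pixel_size(aod, relay, px)
  dark <- dark_periphery_fraction(lt, transition_time(aod))
  structure(
    tibble(
      line_time_s = lt,
      pixels_per_line = as.integer(px),
      lines_per_frame = as.integer(lines),
      frame_rate_hz = fr,
      fov_m = fov$fov_m,
      pixel_size_m = fov$pixel_size_m,
      dark_fraction = dark
    ),
    class = c("frame_geometry", class(tibble())))
}

#' Scan-design table over candidate DvCL focal lengths
#'
#' Convenience wrapper tabulating [raster_frame_geometry()] for a set of DvCL
#' focal lengths, as one would when choosing between frame rate and dark
#' periphery.
#'
#' @inheritParams chirp_focal_length
#' @param f_dvcl Numeric vector of DvCL focal lengths, m.
#'
#' @return A tibble with one row per focal length, the `frame_geometry`
#'   columns plus `f_dvcl_m`.
#' @examples
#' scan_design_table(aod_spec(), relay_spec(), c(0.5, 0.75, 1.0))
#' @export
scan_design_table <- function(aod, relay, f_dvcl = c(0.5, 0.75, 1.0)) {
  purrr::map_dfr(f_dvcl, function(f) {
    rl <- relay
    rl$f_dvcl <- f
    dplyr::bind_cols(tibble(f_dvcl_m = f),
                     raster_frame_geometry(aod, rl))
  })
}

#' Field of view and pixel size at the sample plane
#'
#' The full AOD scan angle is `lambda * B / v`; the scan-lens/tube-lens pair
#' relays it with angular magnification `f_scan / f_tube` onto the objective
#' pupil, so the field of view is `(lambda * B / v) * (f_scan / f_tube) *
#' f_objective` and the pixel size is the FOV divided by pixels per line.
#'
#' @inheritParams chirp_focal_length
#' @param pixels_per_line Pixel count along a scan line.
#'
#' @return A list with `fov_m` and `pixel_size_m`.
#' @examples
#' fov_and_pixel_size(aod_spec(), relay_spec(), 653)
#' @export
fov_and_pixel_size <- function(aod, relay, pixels_per_line) {
  stopifnot(inherits(aod, "aod_spec"), inherits(relay, "relay_spec"))
  if (pixels_per_line < 1) {
    abort("pixels_per_line must be >= 1", class = "quietscope_invalid_spec")
  }
  scan_angle <- relay$wavelength * aod$bandwidth / aod$acoustic_velocity
  fov <- scan_angle * (relay$f_scan / relay$f_tube) * relay$f_objective
  list(fov_m = fov, pixel_size_m = fov / pixels_per_line)
}

#' Focal-plane depth shift from off-nominal chirping
#'
#' Chirping slower or faster than the nominal (collimating) rate leaves a
#' residual vergence `V0 = 1/f_dvcl - 1/F_chirp(r)` after the DvCL. The
#' scan-lens/tube-lens telescope scales vergence by `(f_scan/f_tube)^2`, and
#' the objective converts the input vergence `V1` into an axial focus shift
#' `dz = -V1 * f_obj^2 / (1 + V1 * f_obj)`.
#'
#' Sign convention: positive `dz` means the focus moves farther from the
#' objective (deeper into the sample); chirping faster than nominal gives
#' positive `dz`.
#'
#' @inheritParams chirp_focal_length
#' @param chirp_rate Chirp rate, Hz/s; vectorized.
#'
#' @return Depth shift in metres (0 at the nominal rate).
#' @examples
#' r0 <- nominal_chirp_rate(aod_spec(), relay_spec(f_dvcl = 1.0))
#' focal_depth_shift(aod_spec(), relay_spec(f_dvcl = 1.0), 1.1 * r0)
#' @export
focal_depth_shift <- function(aod, relay, chirp_rate) {
  stopifnot(inherits(aod, "aod_spec"), inherits(relay, "relay_spec"))
  if (is.null(relay$f_dvcl)) {
    abort("relay has no DvCL focal length; set f_dvcl",
          class = "quietscope_config_error")
  }
  if (any(chirp_rate == 0)) {
    abort("chirp rate 0 gives infinite defocus",
          class = "quietscope_infinite_defocus")
  }
  f_chirp <- vapply(chirp_rate, function(r) chirp_focal_length(aod, relay, r),
                    numeric(1))
  v0 <- 1 / relay$f_dvcl - 1 / f_chirp
  v1 <- v0 * (relay$f_scan / relay$f_tube)^2
  -v1 * relay$f_objective^2 / (1 + v1 * relay$f_objective)
}

#' Depth-shift curve over line times
#'
#' Tabulates [focal_depth_shift()] against line scan time (the chirp rate
#' expressed as bandwidth / line time), for multi-layer scan planning.
#'
#' @inheritParams focal_depth_shift
#' @param line_time_s Vector of line times, s.
#'
#' @return Tibble with `line_time_us` and `depth_shift_um`.
#' @export
depth_shift_table <- function(aod, relay, line_time_s) {
  rates <- aod$bandwidth / line_time_s
  tibble(
    line_time_us = line_time_s * 1e6,
    depth_shift_um = focal_depth_shift(aod, relay, rates) * 1e6
  )
}

#' AOD transition (fill) time
#'
#' Time for the acoustic wave to cross the illuminated beam, during which the
#' deflected beam is unusable while the drive retraces between lines:
#' `t = beam_diameter / acoustic_velocity`.
#'
#' @param aod An [aod_spec()].
#' @return Transition time in seconds.
#' @examples
#' transition_time(aod_spec()) # ~13 us
#' @export
transition_time <- function(aod) {
  stopifnot(inherits(aod, "aod_spec"))
  aod$beam_diameter / aod$acoustic_velocity
}

#' Dark periphery fraction of the field of view
#'
#' Fraction of each scan line lost to the inter-line transition time. Shorter
#' line times (faster frames) widen the dark band at fixed transition time.
#'
#' @param line_time Line scan time, s (or a [chirp_program()]).
#' @param transition Transition time, s.
#'
#' @return Fraction in `[0, 1)`.
#' @examples
#' dark_periphery_fraction(65.3e-6, 13e-6)
#' @export
dark_periphery_fraction <- function(line_time, transition) {
  if (inherits(line_time, "chirp_program")) line_time <- line_time$line_time
  if (transition < 0 || transition >= line_time) {
    abort("transition time must lie in [0, line_time)",
          class = "quietscope_infeasible_scan")
  }
  transition / line_time
}

#' Pulse width from an autocorrelation FWHM
#'
#' Deconvolution factors for intensity autocorrelation traces: a sech^2 pulse
#' has width 0.65 times the autocorrelation FWHM; a Gaussian pulse has width
#' `ac_fwhm / sqrt(2)`.
#'
#' @param ac_fwhm Autocorrelation full width at half maximum, s.
#' @param shape `"sech2"` or `"gaussian"`.
#'
#' @return Deconvolved pulse FWHM, s.
#' @examples
#' pulse_from_autocorrelation(100.6e-15, "sech2")
#' @export
pulse_from_autocorrelation <- function(ac_fwhm, shape = c("sech2", "gaussian")) {
  shape <- match.arg(shape)
  if (any(ac_fwhm <= 0)) {
    abort("ac_fwhm must be positive", class = "quietscope_invalid_spec")
  }
  switch(shape,
         sech2 = 0.65 * ac_fwhm,
         gaussian = ac_fwhm / sqrt(2))
}

#' Dispersive pulse broadening
#'
#' Gaussian-equivalent broadening of a transform-limited pulse by group delay
#' dispersion: `tau_out = tau_in * sqrt(1 + (4 ln2 GDD / tau_in^2)^2)`. The
#' same formula is applied to both supported shapes (exact sech^2 propagation
#' is deliberately not modelled); broadening is even in the sign of the GDD.
#'
#' @param pulse A [pulse_spec()].
#' @return Broadened FWHM, s.
#' @examples
#' pulse_broadening(pulse_spec(65.4e-15, "sech2", gdd = 5e-27))
#' @export
pulse_broadening <- function(pulse) {
  stopifnot(inherits(pulse, "pulse_spec"))
  tau <- pulse$width_fwhm
  tau * sqrt(1 + (4 * log(2) * pulse$gdd / tau^2)^2)
}

#' Group delay dispersion consistent with an observed broadened width
#'
#' Inverts [pulse_broadening()]: the (positive) GDD magnitude that broadens
#' `tau_in` to `tau_out`.
#'
#' @param tau_in Input FWHM, s.
#' @param tau_out Observed broadened FWHM, s; must be `>= tau_in`.
#' @return GDD in s^2.
#' @export
gdd_from_broadening <- function(tau_in, tau_out) {
  if (tau_out < tau_in) {
    abort("tau_out must be >= tau_in", class = "quietscope_invalid_spec")
  }
  tau_in^2 / (4 * log(2)) * sqrt((tau_out / tau_in)^2 - 1)
}
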