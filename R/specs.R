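#' Acousto-optic deflector specification
#'
#' Physical constants of the AOD scan chain. The defaults describe a TeO2
#' slow-shear device driven around 100 MHz: acoustic velocity 650 m/s and a
#' 30 MHz chirpable bandwidth. The beam diameter at the AOD aperture sets the
#' acoustic fill (transition) time between scan lines.
#'
#' @param acoustic_velocity Acoustic wave velocity in the crystal, m/s.
#' @param bandwidth Chirp frequency span, Hz.
#' @param center_frequency Drive center frequency, Hz (informational).
#' @param aperture Clear aperture of the deflector, m.
#' @param beam_diameter Illuminated beam diameter at the AOD, m. Must not
#'   exceed `aperture`.
#'
#' @return An object of class `aod_spec`.
#' @examples
#' aod_spec()
#' @export
aod_spec <- function(acoustic_velocity = 650,
                     bandwidth = 30e6,
                     center_frequency = 100e6,
                     aperture = 15e-3,
                     beam_diameter = 8.45e-3) {
  stopifnot(is.numeric(acoustic_velocity), is.numeric(bandwidth))
  if (acoustic_velocity <= 0 || bandwidth <= 0 || aperture <= 0 ||
      beam_diameter <= 0 || center_frequency <= 0) {
    abort("all aod_spec fields must be positive", class = "quietscope_invalid_spec")
  }
  if (beam_diameter > aperture) {
    abort("beam_diameter must not exceed aperture", class = "quietscope_invalid_spec")
  }
  structure(
    list(
      acoustic_velocity = acoustic_velocity,
      bandwidth = bandwidth,
      center_frequency = center_frequency,
      aperture = aperture,
      beam_diameter = beam_diameter
    ),
    class = "aod_spec"
  )
}

#' Relay optics specification
#'
#' Focal lengths of the optical chain after the AOD pair: the divergence
#' compensation lens (DvCL, present only in raster modes), the scan lens, the
#' tube lens and the objective, together with the laser wavelength.
#'
#' @param wavelength Laser wavelength, m.
#' @param f_dvcl DvCL focal length, m, or `NULL` in pointing mode.
#' @param f_scan Scan lens focal length, m.
#' @param f_tube Tube lens focal length, m.
#' @param f_objective Objective focal length, m (18 mm for a 10x objective on
#'   a 180-mm tube-length standard).
#'
#' @return An object of class `relay_spec`.
#' @examples
#' relay_spec(f_dvcl = 1.0)
#' @export
relay_spec <- function(wavelength = 920e-9,
                       f_dvcl = 1.000,
                       f_scan = 0.100,
                       f_tube = 0.200,
                       f_objective = 0.018) {
  if (wavelength <= 200e-9 || wavelength >= 2000e-9) {
    abort("wavelength must lie in (200, 2000) nm", class = "quietscope_invalid_spec")
  }
  fl <- c(f_scan, f_tube, f_objective, if (!is.null(f_dvcl)) f_dvcl)
  if (any(!is.finite(fl)) || any(fl <= 0)) {
    abort("all focal lengths must be positive and finite",
          class = "quietscope_invalid_spec")
  }
  structure(
    list(
      wavelength = wavelength,
      f_dvcl = f_dvcl,
      f_scan = f_scan,
      f_tube = f_tube,
      f_objective = f_objective
    ),
    class = "relay_spec"
  )
}

#' Chirp program for raster scanning
#'
#' Describes how the AOD drive frequency is swept for line scanning: the chirp
#' rate, the line time, the digitizer sample rate that sets pixels per line,
#' and the quantum used when reporting line times.
#'
#' @param chirp_rate Frequency sweep rate, Hz/s.
#' @param line_time Line scan time, s.
#' @param sample_rate Pixel digitizer rate, Hz (default 10 MHz).
#' @param line_time_rounding Reporting quantum for the line time, s
#'   (default 0.1 us). Set to `0` for the continuous (un-quantized) mode.
#' @param bandwidth AOD bandwidth used for the feasibility check, Hz, or
#'   `NULL` to skip the check.
#'
#' @return An object of class `chirp_program`.
#' @export
chirp_program <- function(chirp_rate, line_time,
                          sample_rate = 10e6,
                          line_time_rounding = 0.1e-6,
                          bandwidth = NULL) {
  stopifnot(is.numeric(chirp_rate), is.numeric(line_time))
  if (sample_rate <= 0) {
    abort("sample_rate must be positive", class = "quietscope_invalid_spec")
  }
  if (line_time <= 0) {
    abort("line_time must be positive", class = "quietscope_invalid_spec")
  }
  if (!is.null(bandwidth) &&
      abs(chirp_rate) * line_time > bandwidth * (1 + 1e-9)) {
    abort("chirp_rate x line_time exceeds the AOD bandwidth",
          class = "quietscope_invalid_spec")
  }
  structure(
    list(
      chirp_rate = chirp_rate,
      line_time = line_time,
      sample_rate = sample_rate,
      line_time_rounding = line_time_rounding
    ),
    class = "chirp_program"
  )
}

#' Ultrafast pulse specification
#'
#' @param width_fwhm Intensity full width at half maximum, s.
#' @param shape Pulse shape, `"sech2"` or `"gaussian"`.
#' @param gdd Group delay dispersion, s^2; may be negative.
#'
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(width_fwhm, shape = c("sech2", "gaussian"), gdd = 0) {
  shape <- match.arg(shape)
  if (!is.numeric(width_fwhm) || width_fwhm <= 0) {
    abort("width_fwhm must be positive", class = "quietscope_invalid_spec")
  }
  structure(
    list(width_fwhm = width_fwhm, shape = shape, gdd = gdd),
    class = "pulse_spec"
  )
}

#' @export
print.aod_spec <- function(x, ...) {
  cat("<aod_spec>\n")
  cat(sprintf("  acoustic velocity : %g m/s\n", x$acoustic_velocity))
  cat(sprintf("  bandwidth         : %g MHz\n", x$bandwidth / 1e6))
  cat(sprintf("  center frequency  : %g MHz\n", x$center_frequency / 1e6))
  cat(sprintf("  aperture          : %g mm\n", x$aperture * 1e3))
  cat(sprintf("  beam diameter     : %g mm\n", x$beam_diameter * 1e3))
  invisible(x)
}

#' @export
print.relay_spec <- function(x, ...) {
  cat("<relay_spec>\n")
  cat(sprintf("  wavelength  : %g nm\n", x$wavelength * 1e9))
  cat(sprintf("  f DvCL      : %s\n",
              if (is.null(x$f_dvcl)) "absent (pointing mode)"
              else sprintf("%g mm", x$f_dvcl * 1e3)))
  cat(sprintf("  f scan      : %g mm\n", x$f_scan * 1e3))
  cat(sprintf("  f tube      : %g mm\n", x$f_tube * 1e3))
  cat(sprintf("  f objective : %g mm\n", x$f_objective * 1e3))
  invisible(x)
}
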