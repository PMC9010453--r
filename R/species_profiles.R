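#' Species auditory profile
#'
#' Bundles the two species-specific ingredients of the noise assessment: a
#' hearing-threshold curve (pure-tone audiogram, dB SPL vs frequency) and a
#' tuning-bandwidth function `Bs(f)` (the effective loudness-integration
#' bandwidth, in Hz) modelled as a log-log power law `a * f^b` fitted to
#' literature anchor points.
#'
#' Threshold queries interpolate with a monotone cubic in (log frequency,
#' dB); queries outside the stated hearing range raise an error rather than
#' extrapolating.
#'
#' @param species Species/strain label.
#' @param threshold_freq,threshold_db Audiogram anchor points (Hz, dB SPL).
#' @param bandwidth_a,bandwidth_b Power-law parameters of `Bs(f) = a * f^b`.
#' @param range Hearing range `c(lo, hi)` in Hz over which threshold and
#'   bandwidth are defined; defaults to the threshold anchor span.
#' @param provenance Free-text citation note carried with the profile.
#'
#' @return An object of class `species_profile`.
#' @examples
#' marmoset <- load_species_profile("marmoset")
#' threshold_at(marmoset, 8000)
#' @export
species_profile <- function(species, threshold_freq, threshold_db,
                            bandwidth_a, bandwidth_b,
                            range = NULL, provenance = "") {
  stopifnot(length(threshold_freq) == length(threshold_db),
            length(threshold_freq) >= 2)
  if (is.unsorted(threshold_freq, strictly = TRUE)) {
    abort("threshold frequencies must be strictly increasing",
          class = "quietscope_invalid_spec")
  }
  if (bandwidth_a <= 0) {
    abort("bandwidth power-law scale must be positive",
          class = "quietscope_invalid_spec")
  }
  if (is.null(range)) range <- range(threshold_freq)
  structure(
    list(
      species = species,
      threshold_freq = as.numeric(threshold_freq),
      threshold_db = as.numeric(threshold_db),
      bandwidth_a = bandwidth_a,
      bandwidth_b = bandwidth_b,
      range = as.numeric(range),
      provenance = provenance
    ),
    class = "species_profile"
  )
}

#' Hearing threshold at given frequencies
#'
#' @param profile A [species_profile()].
#' @param frequency Frequencies, Hz; must lie within the profile range.
#' @return Threshold in dB SPL.
#' @export
threshold_at <- function(profile, frequency) {
  stopifnot(inherits(profile, "species_profile"))
  if (any(frequency < profile$range[1] - 1e-9 |
          frequency > profile$range[2] + 1e-9)) {
    abort(sprintf("frequency outside the %s hearing range [%g, %g] Hz",
                  profile$species, profile$range[1], profile$range[2]),
          class = "quietscope_profile_range")
  }
  fn <- splinefun(log(profile$threshold_freq), profile$threshold_db,
                  method = "monoH.FC")
  fn(log(frequency))
}

#' Tuning bandwidth Bs(f)
#'
#' @inheritParams threshold_at
#' @return Bandwidth in Hz.
#' @export
bandwidth_at <- function(profile, frequency) {
  stopifnot(inherits(profile, "species_profile"))
  if (any(frequency < profile$range[1] - 1e-9 |
          frequency > profile$range[2] + 1e-9)) {
    abort(sprintf("frequency outside the %s hearing range",
                  profile$species),
          class = "quietscope_profile_range")
  }
  profile$bandwidth_a * frequency^profile$bandwidth_b
}

#' Load a packaged or user species profile
#'
#' Packaged profiles (`"marmoset"`, `"mouse_cba"`, `"mouse_c57bl6j"`) are
#' power-law/audiogram approximations assembled from the auditory literature;
#' each carries a provenance note and should be re-digitized from the primary
#' sources for publication-grade use. A path to a YAML file in the same
#' layout loads a custom profile.
#'
#' @param name Packaged profile name or path to a profile YAML file.
#' @return A [species_profile()].
#' @export
load_species_profile <- function(name) {
  path <- if (file.exists(name)) {
    name
  } else {
    p <- system.file("extdata", "species", paste0(name, ".yaml"),
                     package = "quietscope")
    if (!nzchar(p)) {
      avail <- sub("\\.yaml$", "",
                   list.files(system.file("extdata", "species",
                                          package = "quietscope")))
      abort(sprintf("unknown species '%s'; packaged profiles: %s",
                    name, paste(avail, collapse = ", ")),
            class = "quietscope_lookup_error")
    }
    p
  }
  y <- yaml::read_yaml(path)
  species_profile(
    species = y$species,
    threshold_freq = as.numeric(y$threshold$frequency_hz),
    threshold_db = as.numeric(y$threshold$level_db),
    bandwidth_a = as.numeric(y$bandwidth$a),
    bandwidth_b = as.numeric(y$bandwidth$b),
    range = as.numeric(y$range_hz),
    provenance = y$provenance %||% ""
  )
}

#' Save a species profile as YAML
#'
#' @param profile A [species_profile()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_species_profile <- function(profile, path) {
  stopifnot(inherits(profile, "species_profile"))
  yaml::write_yaml(
    list(
      species = profile$species,
      range_hz = profile$range,
      threshold = list(frequency_hz = profile$threshold_freq,
                       level_db = profile$threshold_db),
      bandwidth = list(a = profile$bandwidth_a, b = profile$bandwidth_b),
      provenance = profile$provenance
    ),
    path
  )
  invisible(path)
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("<species_profile: %s>\n", x$species))
  cat(sprintf("  hearing range : %g - %g Hz\n", x$range[1], x$range[2]))
  cat(sprintf("  Bs(f)         : %.4g * f^%.3g Hz\n",
              x$bandwidth_a, x$bandwidth_b))
  cat(sprintf("  threshold     : %d anchors\n", length(x$threshold_freq)))
  if (nzchar(x$provenance)) cat(sprintf("  provenance    : %s\n", x$provenance))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
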