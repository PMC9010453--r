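#' Imaging movie container
#'
#' A time-ordered stack of 2-D intensity frames with acquisition metadata and
#' a per-frame trial label.
#'
#' @param frames 3-D numeric array `[row, col, frame]`.
#' @param frame_rate Frames per second.
#' @param trial Integer vector, one trial id per frame; `NULL` for a single
#'   untrialed span.
#' @param pixel_size Pixel size at the sample plane, m (optional metadata).
#'
#' @return An object of class `qs_movie`.
#' @export
qs_movie <- function(frames, frame_rate = 23.5, trial = NULL,
                     pixel_size = 0.585e-6) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (frame_rate <= 0) {
    abort("frame_rate must be positive", class = "quietscope_invalid_spec")
  }
  nt <- dim(frames)[3]
  if (is.null(trial)) trial <- rep(1L, nt)
  if (length(trial) != nt) {
    abort("trial labels must match the frame count",
          class = "quietscope_alignment_error")
  }
  structure(
    list(frames = frames, frame_rate = frame_rate,
         trial = as.integer(trial), pixel_size = pixel_size),
    class = "qs_movie"
  )
}

#' @export
print.qs_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<qs_movie> %d x %d px, %d frames @ %.3g fps, %d trial(s)\n",
              d[1], d[2], d[3], x$frame_rate, length(unique(x$trial))))
  invisible(x)
}

#' ROI mask
#'
#' A set of pixels (1-based row/col) with a label and a kind.
#'
#' @param pixels Two-column matrix or data frame of `(row, col)` pixel
#'   coordinates, 1-based.
#' @param label ROI label.
#' @param kind `"soma"`, `"process"` or `"neuropil_ring"`.
#' @param dim Optional frame dimensions `c(nrow, ncol)` for bounds checking.
#'
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(pixels, label = "roi",
                     kind = c("soma", "process", "neuropil_ring"),
                     dim = NULL) {
  kind <- match.arg(kind)
  px <- as.matrix(as.data.frame(pixels)[, 1:2])
  colnames(px) <- c("row", "col")
  if (nrow(px) == 0) {
    abort("ROI mask is empty", class = "quietscope_geometry_error")
  }
  if (!is.null(dim) &&
      (any(px[, 1] < 1 | px[, 1] > dim[1] | px[, 2] < 1 | px[, 2] > dim[2]))) {
    abort("ROI pixels outside frame bounds",
          class = "quietscope_geometry_error")
  }
  structure(list(pixels = px, label = label, kind = kind),
            class = "roi_mask")
}

#' Neuropil ring around an ROI
#'
#' The ring of pixels within Euclidean distance `width` of the ROI
#' (morphological dilation by a disc of radius `width`) excluding the ROI
#' pixels themselves, clipped to the frame bounds. The ring starts
#' immediately at the ROI boundary.
#'
#' When the full ROI set of the field is known, pass it as `exclude` so the
#' ring samples true neuropil: pixels belonging to any cell ROI are removed
#' from the ring (the standard precaution against a neighbouring soma
#' contaminating the neuropil estimate).
#'
#' @param roi A [roi_mask()].
#' @param width Ring width in pixels (default 5).
#' @param dim Frame dimensions `c(nrow, ncol)`.
#' @param exclude Optional list of [roi_mask()] whose pixels are removed
#'   from the ring.
#'
#' @return A [roi_mask()] of kind `"neuropil_ring"`.
#' @export
neuropil_ring <- function(roi, width = 5, dim, exclude = NULL) {
  stopifnot(inherits(roi, "roi_mask"), width > 0, length(dim) == 2)
  px <- roi$pixels
  r0 <- max(1, min(px[, 1]) - ceiling(width))
  r1 <- min(dim[1], max(px[, 1]) + ceiling(width))
  c0 <- max(1, min(px[, 2]) - ceiling(width))
  c1 <- min(dim[2], max(px[, 2]) + ceiling(width))
  cand <- as.matrix(expand.grid(row = r0:r1, col = c0:c1))
  d2 <- outer(cand[, 1], px[, 1], `-`)^2 + outer(cand[, 2], px[, 2], `-`)^2
  mind2 <- apply(d2, 1, min)
  in_ring <- mind2 <= width^2 & mind2 > 0
  if (!is.null(exclude)) {
    other <- do.call(rbind, purrr::map(exclude, function(r) r$pixels))
    taken <- paste(other[, 1], other[, 2]) # linearized pixel identity
    in_ring <- in_ring & !(paste(cand[, 1], cand[, 2]) %in% taken)
  }
  if (!any(in_ring)) {
    abort("neuropil ring is empty after clipping",
          class = "quietscope_geometry_error")
  }
  roi_mask(cand[in_ring, , drop = FALSE],
           label = paste0(roi$label, "_ring"),
           kind = "neuropil_ring", dim = dim)
}

#' Translate an ROI mask by an integer offset
#'
#' Registration aligns a session to a template built from the data itself,
#' so the corrected movie sits at the session-mean displacement rather than
#' at any absolute position; ROI masks must live in the corrected movie's
#' coordinates (in practice they are drawn on the registered mean image).
#' This helper moves a mask by a whole-pixel offset, dropping pixels that
#' leave the frame.
#'
#' @param roi A [roi_mask()].
#' @param dy,dx Offset in pixels (rounded to integers).
#' @param dim Frame dimensions `c(nrow, ncol)`.
#' @return A translated [roi_mask()].
#' @export
shift_roi_mask <- function(roi, dy, dx, dim) {
  px <- roi$pixels
  px[, 1] <- px[, 1] + round(dy)
  px[, 2] <- px[, 2] + round(dx)
  keep <- px[, 1] >= 1 & px[, 1] <= dim[1] & px[, 2] >= 1 & px[, 2] <= dim[2]
  roi_mask(px[keep, , drop = FALSE], label = roi$label, kind = roi$kind,
           dim = dim)
}

#' Mean-over-pixels fluorescence trace of one ROI
#'
#' @param movie A [qs_movie()].
#' @param roi A [roi_mask()].
#' @return Numeric vector, one value per frame (mean over ROI pixels).
#' @export
extract_trace <- function(movie, roi) {
  stopifnot(inherits(movie, "qs_movie"), inherits(roi, "roi_mask"))
  d <- dim(movie$frames)
  lin <- (roi$pixels[, 2] - 1) * d[1] + roi$pixels[, 1]
  # index the flat array directly: avoids copying the full movie per ROI
  idx <- outer(lin, (seq_len(d[3]) - 1) * (d[1] * d[2]), `+`)
  colMeans(matrix(movie$frames[idx], nrow = length(lin)))
}

#' Neuropil-corrected traces for a set of ROIs
#'
#' For each ROI, extracts the mean fluorescence trace, builds its neuropil
#' ring, and subtracts `factor` times the ring trace.
#'
#' Rings exclude the pixels of every ROI in `rois` (not only the cell's
#' own), so a neighbouring soma never leaks into a neuropil estimate.
#'
#' @param movie A [qs_movie()].
#' @param rois List of [roi_mask()].
#' @param factor Neuropil subtraction factor (default 0.4).
#' @param ring_width Ring width in pixels (default 5).
#'
#' @return A tibble with columns `roi`, `frame`, `trial`, `time`, `value`
#'   (neuropil-corrected fluorescence).
#' @export
extract_traces <- function(movie, rois, factor = 0.4, ring_width = 5) {
  d <- dim(movie$frames)
  purrr::map_dfr(rois, function(roi) {
    f_roi <- extract_trace(movie, roi)
    ring <- neuropil_ring(roi, width = ring_width, dim = d[1:2],
                          exclude = rois)
    f_ring <- extract_trace(movie, ring)
    tibble(
      roi = roi$label,
      frame = seq_len(d[3]),
      trial = movie$trial,
      time = (seq_len(d[3]) - 1) / movie$frame_rate,
      value = neuropil_subtract(f_roi, f_ring, factor)
    )
  })
}

#' Neuropil subtraction
#'
#' `out = f_roi - factor * f_ring`, per frame.
#'
#' @param f_roi,f_ring Equal-length numeric traces.
#' @param factor Contamination factor (default 0.4).
#' @return Corrected trace.
#' @examples
#' neuropil_subtract(10, 5) # 8
#' @export
neuropil_subtract <- function(f_roi, f_ring, factor = 0.4) {
  if (length(f_roi) != length(f_ring)) {
    abort("trace lengths differ", class = "quietscope_alignment_error")
  }
  f_roi - factor * f_ring
}

#' Normalized fluorescence change dF/F
#'
#' `(F - F0) / F0` with the baseline `F0` the mean fluorescence over the
#' pre-stimulus frames. A non-positive baseline flags the trace as unusable
#' (error) rather than silently producing values.
#'
#' @param values Numeric fluorescence trace (one trial span).
#' @param prestim Integer indices of the pre-stimulus frames within
#'   `values`.
#' @return dF/F trace; its mean over `prestim` is 0 by construction.
#' @export
compute_dff <- function(values, prestim) {
  if (length(prestim) == 0 || any(prestim < 1 | prestim > length(values))) {
    abort("pre-stimulus window empty or out of range",
          class = "quietscope_range_error")
  }
  f0 <- mean(values[prestim])
  if (!is.finite(f0) || f0 <= 0) {
    abort("non-positive baseline F0; cell flagged unusable",
          class = "quietscope_baseline_error")
  }
  (values - f0) / f0
}

#' Response amplitude of a dF/F trace
#'
#' Arithmetic mean of dF/F over the stimulus-presentation frames.
#'
#' @param dff Numeric dF/F trace.
#' @param stim Integer indices of the stimulus window.
#' @return Scalar response amplitude (dF/F units).
#' @export
response_amplitude <- function(dff, stim) {
  if (length(stim) == 0 || any(stim < 1 | stim > length(dff))) {
    abort("stimulus window empty or out of range",
          class = "quietscope_range_error")
  }
  mean(dff[stim])
}

#' Frame windows of the trial structure
#'
#' Converts the trial timing of a stimulus grid into frame-index windows at
#' a given frame rate: pre-stimulus frames in `[0, pre)` s and stimulus
#' frames in `[pre, pre + stim)` s of each trial.
#'
#' @param grid A [fra_grid()].
#' @param frame_rate Frames per second.
#' @return List with `prestim` and `stim` integer index vectors (1-based,
#'   relative to trial start) and `frames_per_trial`.
#' @export
trial_windows <- function(grid, frame_rate) {
  tm <- grid$timing
  npre <- floor(tm[["pre"]] * frame_rate + 1e-9)
  nstim <- floor(tm[["stim"]] * frame_rate + 1e-9)
  nft <- floor(sum(tm) * frame_rate + 1e-9)
  if (npre < 1 || nstim < 1) {
    abort("frame rate too low to resolve the trial windows",
          class = "quietscope_range_error")
  }
  list(prestim = seq_len(npre), stim = npre + seq_len(nstim),
       frames_per_trial = nft)
}

#' Per-trial response amplitudes from corrected traces
#'
#' Splits neuropil-corrected traces by trial, computes dF/F against each
#' trial's pre-stimulus baseline, and averages dF/F over the stimulus window
#' to a per-trial response amplitude. Trials whose baseline is non-positive
#' are dropped with a warning.
#'
#' @param traces Tibble from [extract_traces()].
#' @param schedule A [session_schedule()].
#' @param grid A [fra_grid()]; defaults to the grid attached to `schedule`.
#' @param frame_rate Frames per second of the source movie.
#'
#' @return Tibble with `roi`, `trial`, `cycle`, `frequency`, `level`,
#'   `amplitude`.
#' @export
trial_responses <- function(traces, schedule, grid = attr(schedule, "grid"),
                            frame_rate) {
  stopifnot(!is.null(grid))
  win <- trial_windows(grid, frame_rate)
  dropped <- 0L
  out <- traces |>
    dplyr::inner_join(
      dplyr::select(as_tibble(schedule), "trial", "cycle", "frequency",
                    "level"),
      by = "trial") |>
    dplyr::group_by(.data$roi, .data$trial, .data$cycle, .data$frequency,
                    .data$level) |>
    dplyr::summarise(
      amplitude = {
        v <- .data$value
        f0 <- mean(v[win$prestim])
        if (!is.finite(f0) || f0 <= 0) {
          dropped <<- dropped + 1L
          NA_real_
        } else {
          response_amplitude(compute_dff(v, win$prestim), win$stim)
        }
      },
      .groups = "drop"
    )
  if (dropped > 0) {
    warn(sprintf("%d trial(s) dropped: non-positive baseline F0", dropped))
    out <- dplyr::filter(out, !is.na(.data$amplitude))
  }
  out
}

#' Build frequency-response-area matrices
#'
#' Groups per-trial response amplitudes by ROI and grid cell and averages
#' them into FRA matrices; per-trial values are retained.
#'
#' @param responses Tibble from [trial_responses()] (columns `roi`,
#'   `frequency`, `level`, `amplitude`; `trial` optional).
#' @param grid A [fra_grid()].
#'
#' @return An object of class `fra_matrix`: list with `cells` (tibble `roi`,
#'   `frequency`, `level`, `mean`, `n_reps`), `trials` (the input responses),
#'   `frequencies`, `levels`. Grid cells with no trials are kept as `NA` with
#'   an incomplete-session warning.
#' @export
build_fra <- function(responses, grid) {
  stopifnot(inherits(grid, "stimulus_grid"))
  full <- tidyr::expand_grid(
    roi = unique(responses$roi),
    frequency = grid$frequencies,
    level = grid$levels
  )
  cells <- responses |>
    dplyr::group_by(.data$roi, .data$frequency, .data$level) |>
    dplyr::summarise(mean = mean(.data$amplitude),
                     n_reps = dplyr::n(), .groups = "drop")
  cells <- dplyr::left_join(full, cells, by = c("roi", "frequency", "level")) |>
    dplyr::mutate(n_reps = tidyr::replace_na(.data$n_reps, 0L))
  if (any(cells$n_reps == 0)) {
    warn("incomplete session: some grid cells have no trials (masked as NA)")
  }
  structure(
    list(cells = cells, trials = responses,
         frequencies = grid$frequencies, levels = grid$levels),
    class = "fra_matrix"
  )
}

#' @export
print.fra_matrix <- function(x, ...) {
  cat(sprintf("<fra_matrix> %d ROI(s), %d x %d grid, %s reps/cell\n",
              length(unique(x$cells$roi)), length(x$frequencies),
              length(x$levels),
              paste(range(x$cells$n_reps), collapse = "-")))
  invisible(x)
}

#' @describeIn build_fra Long tibble of FRA cells (one row per ROI x
#'   frequency x level).
#' @param x An `fra_matrix`.
#' @param ... Unused.
#' @export
tidy.fra_matrix <- function(x, ...) x$cells

#' @describeIn build_fra One row per ROI: best frequency, best level, peak
#'   mean response and total trial count.
#' @export
glance.fra_matrix <- function(x, ...) {
  bf <- best_frequency_level(x)
  n_tr <- x$trials |>
    dplyr::count(.data$roi, name = "n_trials")
  dplyr::left_join(bf, n_tr, by = "roi")
}

#' Best frequency and best level
#'
#' The grid cell eliciting the maximal mean response per ROI. Ties are broken
#' toward the lowest level, then the lowest frequency.
#'
#' @param fra An `fra_matrix` from [build_fra()].
#' @return Tibble with `roi`, `bf` (Hz), `bl` (dB SPL), `peak` (mean dF/F at
#'   the best cell).
#' @export
best_frequency_level <- function(fra) {
  stopifnot(inherits(fra, "fra_matrix"))
  fra$cells |>
    dplyr::filter(!is.na(.data$mean)) |>
    dplyr::group_by(.data$roi) |>
    dplyr::arrange(.data$level, .data$frequency, .by_group = TRUE) |>
    dplyr::summarise(
      bf = .data$frequency[which.max(.data$mean)],
      bl = .data$level[which.max(.data$mean)],
      peak = max(.data$mean),
      .groups = "drop"
    )
}

#' End-to-end FRA analysis of a session
#'
#' Convenience pipeline: two-stage motion correction, neuropil-corrected
#' trace extraction, per-trial dF/F response amplitudes, and FRA assembly.
#'
#' @param movie A [qs_movie()].
#' @param rois List of [roi_mask()].
#' @param schedule A [session_schedule()] with its grid attached.
#' @param register Run motion correction first (default TRUE).
#' @param neuropil_factor Neuropil subtraction factor.
#'
#' @return List with `fra` (an `fra_matrix`), `map` (the [glance()] BF/BL
#'   table), `traces`, `displacements` (NULL when `register = FALSE`).
#' @export
run_fra_pipeline <- function(movie, rois, schedule, register = TRUE,
                             neuropil_factor = 0.4) {
  grid <- attr(schedule, "grid")
  stopifnot(!is.null(grid))
  disp <- NULL
  if (register) {
    reg <- register_session(movie)
    movie <- reg$movie
    disp <- reg$displacements
  }
  traces <- extract_traces(movie, rois, factor = neuropil_factor)
  resp <- trial_responses(traces, schedule, grid, movie$frame_rate)
  fra <- build_fra(resp, grid)
  list(fra = fra, map = glance(fra), traces = traces, displacements = disp)
}
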