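#' Rigid subpixel shift between a frame and a template
#'
#' Estimates the translation of image content from `template` to `frame` by
#' locating the peak of the circular cross-correlation (computed via FFT),
#' refined to subpixel precision with a separable quadratic fit around the
#' peak. The returned `(dy, dx)` is the displacement of the content: a frame
#' whose content sits 2 rows lower than the template returns `dy = 2`.
#'
#' @param frame,template Numeric matrices of identical dimensions.
#' @return Numeric `c(dy, dx)` in pixels.
#' @examples
#' img <- outer(dnorm(1:32, 16, 3), dnorm(1:32, 16, 3))
#' estimate_rigid_shift(img, img) # c(0, 0)
#' @export
estimate_rigid_shift <- function(frame, template) {
  if (!all(dim(frame) == dim(template))) {
    abort("frame and template must have identical dimensions",
          class = "quietscope_alignment_error")
  }
  if (sd(template) == 0) {
    abort("constant image: cross-correlation is degenerate",
          class = "quietscope_degenerate_correlation")
  }
  t0 <- template - mean(template)
  s <- xcorr_shift(frame, template, Conj(fft(t0)))
  c(dy = s[1], dx = s[2])
}

#' Translate a frame by a subpixel shift
#'
#' Moves image content by `(dy, dx)` pixels using separable Catmull-Rom
#' cubic interpolation with replicated edges (cubic keeps the gain of
#' pixel-scale structures nearly flat across fractional shifts, where linear
#' interpolation would attenuate them). To undo an estimated displacement,
#' apply the negated shift.
#'
#' @param frame Numeric matrix.
#' @param dy,dx Content displacement in pixels (positive = down / right).
#' @return Shifted matrix, same dimensions.
#' @export
shift_frame <- function(frame, dy, dx) {
  out <- cubic_shift_axis(frame, dy)
  t(cubic_shift_axis(t(out), dx))
}

# Catmull-Rom resampling of each column by a scalar shift, clamped indices
cubic_shift_axis <- function(frame, d) {
  if (d == 0) return(frame)
  n <- nrow(frame)
  ys <- seq_len(n) - d
  y0 <- floor(ys)
  t_ <- ys - y0
  idx <- function(k) pmin(pmax(y0 + k, 1), n)
  w_m1 <- 0.5 * (-t_^3 + 2 * t_^2 - t_)
  w_0  <- 0.5 * (3 * t_^3 - 5 * t_^2 + 2)
  w_p1 <- 0.5 * (-3 * t_^3 + 4 * t_^2 + t_)
  w_p2 <- 0.5 * (t_^3 - t_^2)
  frame[idx(-1), , drop = FALSE] * w_m1 +
    frame[idx(0), , drop = FALSE] * w_0 +
    frame[idx(1), , drop = FALSE] * w_p1 +
    frame[idx(2), , drop = FALSE] * w_p2
}

#' Hierarchical two-stage motion correction
#'
#' Registers a session with the two-stage protocol used for trial-structured
#' recordings: (1) all frames within a trial are registered to a template
#' averaged across 10 frames in the middle of that trial; (2) the corrected
#' within-trial average images are registered across trials (to their grand
#' average), and the cross-trial shifts are applied back to every frame of
#' the trial. The rigid translation engine is [estimate_rigid_shift()];
#' corrections are applied with [shift_frame()] (replicate edge fill).
#'
#' @param movie A [qs_movie()] with trial boundaries; every trial must have
#'   at least 10 frames.
#' @param template_frames Number of mid-trial frames averaged into the
#'   within-trial template (default 10).
#'
#' @return A list with `movie` (corrected [qs_movie()]) and `displacements`,
#'   a tibble with per-frame `frame`, `trial`, `dy`, `dx` (total estimated
#'   content displacement; the correction applied is its negation).
#' @export
register_session <- function(movie, template_frames = 10) {
  stopifnot(inherits(movie, "qs_movie"))
  trials <- sort(unique(movie$trial))
  nt <- dim(movie$frames)[3]
  dy <- numeric(nt); dx <- numeric(nt)

  trial_avg <- vector("list", length(trials))
  for (ti in seq_along(trials)) {
    idx <- which(movie$trial == trials[ti])
    if (length(idx) < template_frames) {
      abort("trial shorter than the template window",
            class = "quietscope_protocol_error")
    }
    mid <- idx[floor((length(idx) - template_frames) / 2) +
                 seq_len(template_frames)]
    templ <- apply(movie$frames[, , mid, drop = FALSE], c(1, 2), mean)
    tf <- Conj(fft(templ - mean(templ)))
    avg <- 0
    for (k in idx) {
      fr <- movie$frames[, , k]
      s <- xcorr_shift(fr, templ, tf)
      dy[k] <- s[1]; dx[k] <- s[2]
      avg <- avg + shift_frame(fr, -s[1], -s[2])
    }
    trial_avg[[ti]] <- avg / length(idx)
  }

  grand <- Reduce(`+`, trial_avg) / length(trial_avg)
  for (ti in seq_along(trials)) {
    s <- estimate_rigid_shift(trial_avg[[ti]], grand)
    idx <- which(movie$trial == trials[ti])
    dy[idx] <- dy[idx] + s[1]
    dx[idx] <- dx[idx] + s[2]
  }

  corrected <- movie$frames
  for (k in seq_len(nt)) {
    corrected[, , k] <- shift_frame(movie$frames[, , k], -dy[k], -dx[k])
  }
  list(
    movie = qs_movie(corrected, frame_rate = movie$frame_rate,
                     trial = movie$trial, pixel_size = movie$pixel_size),
    displacements = tibble(frame = seq_len(nt), trial = movie$trial,
                           dy = dy, dx = dx)
  )
}

# cross-correlation shift against a precomputed conjugate template FFT;
# subpixel refinement by evaluating the inverse DFT on an upsampled grid
# around the coarse peak (matrix-multiply DFT, upsampling factor 16)
xcorr_shift <- function(frame, template, templ_fft_conj, upsample = 16L) {
  if (sd(frame) == 0) {
    abort("constant image: cross-correlation is degenerate",
          class = "quietscope_degenerate_correlation")
  }
  f <- frame - mean(frame)
  spec <- fft(f) * templ_fft_conj
  cc <- Re(fft(spec, inverse = TRUE))
  d <- dim(cc)
  peak <- arrayInd(which.max(cc), d)
  wrap <- function(i, n) if (i > n / 2) i - n else i
  cy <- wrap(peak[1], d[1]) - 1
  cx <- wrap(peak[2], d[2]) - 1

  # signed spatial frequencies in fft ordering
  ky <- c(0:floor(d[1] / 2), -(ceiling(d[1] / 2) - 1):-1)
  kx <- c(0:floor(d[2] / 2), -(ceiling(d[2] / 2) - 1):-1)
  step <- 1 / upsample
  gy <- cy + seq(-1, 1, by = step)
  gx <- cx + seq(-1, 1, by = step)
  ey <- exp(2i * pi * outer(gy, ky) / d[1])     # |gy| x ny
  ex <- exp(2i * pi * outer(kx, gx) / d[2])     # nx x |gx|
  fine <- Re(ey %*% spec %*% ex)
  pk <- arrayInd(which.max(fine), dim(fine))
  c(gy[pk[1]], gx[pk[2]])
}
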