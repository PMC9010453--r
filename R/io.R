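#' Write a movie as a multipage TIFF
#'
#' Frames are written as 32-bit pages scaled into `[0, 1]` by a common
#' intensity scale; the scale and acquisition metadata go to a JSON sidecar
#' (`<path>.json`) so that [read_movie_tiff()] restores original values.
#'
#' @param movie A [qs_movie()].
#' @param path Output TIFF path.
#' @param scale Intensity divisor; defaults to the movie maximum.
#' @return The path, invisibly.
#' @export
write_movie_tiff <- function(movie, path, scale = NULL) {
  stopifnot(inherits(movie, "qs_movie"))
  lo <- min(movie$frames)
  if (is.null(scale)) scale <- max(movie$frames) - lo
  if (scale <= 0) scale <- 1
  pages <- purrr::map(seq_len(dim(movie$frames)[3]),
                      function(k) (movie$frames[, , k] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(scale = scale, offset = lo, frame_rate = movie$frame_rate,
         pixel_size = movie$pixel_size, trial = movie$trial),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multipage TIFF as a movie
#'
#' Restores intensity scaling and metadata from the JSON sidecar written by
#' [write_movie_tiff()] when present; explicit arguments override it.
#'
#' @param path TIFF path.
#' @param frame_rate,trial,pixel_size Metadata passed to [qs_movie()] when
#'   no sidecar is found.
#' @return A [qs_movie()].
#' @export
read_movie_tiff <- function(path, frame_rate = 23.5, trial = NULL,
                            pixel_size = 0.585e-6) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    arr[, , k] <- p
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    arr <- arr * meta$scale + meta$offset
    frame_rate <- meta$frame_rate
    pixel_size <- meta$pixel_size
    if (is.null(trial)) trial <- meta$trial
  }
  qs_movie(arr, frame_rate = frame_rate, trial = trial,
           pixel_size = pixel_size)
}

#' Write ROI masks as a label-image TIFF
#'
#' Encodes a set of ROI masks into one 16-bit label image (pixel value = ROI
#' index, 0 = background). Overlapping masks keep the later index.
#'
#' @param rois List of [roi_mask()].
#' @param dim Frame dimensions `c(nrow, ncol)`.
#' @param path Output TIFF path.
#' @return The path, invisibly.
#' @export
write_masks_tiff <- function(rois, dim, path) {
  lab <- matrix(0L, dim[1], dim[2])
  for (i in seq_along(rois)) {
    px <- rois[[i]]$pixels
    lab[(px[, 2] - 1) * dim[1] + px[, 1]] <- i
  }
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read ROI masks from a label-image TIFF
#'
#' @param path TIFF written by [write_masks_tiff()].
#' @param labels Optional character labels, one per ROI index.
#' @return List of [roi_mask()].
#' @export
read_masks_tiff <- function(path, labels = NULL) {
  img <- tiff::readTIFF(path)
  lab <- round(img * 65535)
  ids <- sort(setdiff(unique(as.integer(lab)), 0L))
  purrr::map(ids, function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    roi_mask(w[, c(1, 2)],
             label = if (is.null(labels)) sprintf("roi%03d", i)
                     else labels[i],
             dim = dim(lab))
  })
}

#' Write a PSD or excitation pattern as CSV
#'
#' @param x A `qs_psd` or `qs_excitation` tibble.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_spectrum_csv <- function(x, path) {
  df <- as.data.frame(x)
  value_col <- intersect(c("level_db", "excitation_db"), names(df))[1]
  out <- data.frame(frequency_hz = df$frequency,
                    level_db = df[[value_col]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
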