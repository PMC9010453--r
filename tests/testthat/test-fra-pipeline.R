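test_that("rigid shift estimation recovers integer and subpixel shifts", {
  img <- synthetic_cell_image()
  expect_equal(unname(estimate_rigid_shift(img, img)), c(0, 0),
               tolerance = 1e-6)
  # integer translation (zero-fill shift, independent interpolator)
  sh <- integer_shift(img, 3, -2)
  expect_equal(unname(estimate_rigid_shift(sh, img)), c(3, -2),
               tolerance = 0.1)
  # subpixel translation via the package's own smooth cell image
  sub <- shift_frame(img, 1.5, -0.5)
  got <- estimate_rigid_shift(sub, img)
  expect_equal(unname(got), c(1.5, -0.5), tolerance = 0.25)
  # antisymmetry
  a <- estimate_rigid_shift(sh, img)
  b <- estimate_rigid_shift(img, sh)
  expect_equal(unname(a), -unname(b), tolerance = 0.05)
  expect_error(estimate_rigid_shift(img, matrix(1, 64, 64)),
               class = "quietscope_degenerate_correlation")
})

test_that("two-stage registration is quiet on a motion-free session and idempotent", {
  tiny <- tiny_session(motion = FALSE, noise = FALSE)
  reg <- register_session(tiny$ses$movie)
  expect_lt(max(abs(c(reg$displacements$dy, reg$displacements$dx))), 0.1)
  # applying the protocol twice changes nothing appreciably
  reg2 <- register_session(reg$movie)
  expect_lt(max(abs(c(reg2$displacements$dy, reg2$displacements$dx))), 0.1)
})

test_that("registration recovers simulated heartbeat + drift motion", {
  tiny <- tiny_session(motion = TRUE, noise = TRUE)
  reg <- register_session(tiny$ses$movie)
  d <- dplyr::inner_join(reg$displacements, tiny$ses$displacements,
                         by = "frame", suffix = c(".est", ".true"))
  ey <- d$dy.est - d$dy.true
  ex <- d$dx.est - d$dx.true
  # registration recovers motion up to a constant offset (template choice)
  ey <- ey - mean(ey); ex <- ex - mean(ex)
  expect_lt(sqrt(mean(ey^2 + ex^2) / 2), 0.3)
})

test_that("registration of a globally shifted movie restores the original", {
  tiny <- tiny_session(motion = FALSE, noise = FALSE, n_neurons = 3,
                       cycles = 1)
  mv <- tiny$ses$movie
  shifted <- mv$frames
  for (k in seq_len(dim(shifted)[3])) {
    shifted[, , k] <- integer_shift(mv$frames[, , k], 2, 3)
  }
  sm <- qs_movie(shifted, frame_rate = mv$frame_rate, trial = mv$trial)
  reg <- register_session(sm)
  # estimated displacements are uniform; corrected content matches the
  # shifted-but-consistent session away from edges
  expect_lt(sd(reg$displacements$dy), 0.05)
  expect_lt(sd(reg$displacements$dx), 0.05)
  inner_r <- 8:(dim(shifted)[1] - 8); inner_c <- 8:(dim(shifted)[2] - 8)
  dyn <- diff(range(mv$frames[inner_r, inner_c, 1]))
  err <- abs(reg$movie$frames[inner_r, inner_c, 1] -
               sm$frames[inner_r, inner_c, 1])
  expect_lt(mean(err), 0.01 * dyn + 1e-9)
  expect_error(register_session(qs_movie(array(0, c(8, 8, 5)))),
               class = "quietscope_protocol_error")
})

test_that("neuropil rings are exact Euclidean dilations excluding the ROI", {
  dim <- c(40, 40)
  # 1-pixel ROI with width 5: the 11x11 disc minus its centre
  r1 <- roi_mask(cbind(20, 20), dim = dim)
  ring <- neuropil_ring(r1, width = 5, dim = dim)
  expect_equal(nrow(ring$pixels), sum(outer((-5:5)^2, (-5:5)^2, `+`) <= 25) - 1)
  expect_identical(ring$kind, "neuropil_ring")
  # disjointness for random ROIs
  withr::with_seed(3, {
    for (i in 1:50) {
      cy <- sample(5:35, 1); cx <- sample(5:35, 1)
      px <- expand.grid(row = cy + (-1:1), col = cx + (-1:1))
      roi <- roi_mask(px, dim = dim)
      rg <- neuropil_ring(roi, width = 5, dim = dim)
      overlap <- merge(as.data.frame(roi$pixels), as.data.frame(rg$pixels))
      expect_equal(nrow(overlap), 0)
    }
  })
  # disc ROI ring area matches brute-force enumeration over the frame
  centre <- c(20, 20); rad <- 5; width <- 5
  all_px <- as.matrix(expand.grid(row = 1:40, col = 1:40))
  d2c <- (all_px[, 1] - centre[1])^2 + (all_px[, 2] - centre[2])^2
  disc <- all_px[d2c <= rad^2, ]
  roi <- roi_mask(disc, dim = dim)
  rg <- neuropil_ring(roi, width = width, dim = dim)
  # brute force: min distance to any disc pixel within width, not in disc
  mind2 <- apply(all_px, 1, function(p) {
    min((disc[, 1] - p[1])^2 + (disc[, 2] - p[2])^2)
  })
  expect_equal(nrow(rg$pixels), sum(mind2 > 0 & mind2 <= width^2))
})

test_that("neuropil subtraction and dF/F follow their definitions", {
  expect_equal(neuropil_subtract(10, 5, 0.4), 8)
  expect_equal(neuropil_subtract(c(1, 2), c(3, 4), 0), c(1, 2))
  expect_equal(neuropil_subtract(c(2, 3), c(2, 3), 1), c(0, 0))
  expect_error(neuropil_subtract(1:3, 1:2),
               class = "quietscope_alignment_error")

  expect_equal(compute_dff(rep(5, 10), 1:3), rep(0, 10))
  tr <- c(rep(1, 4), rep(1.2, 4))
  expect_equal(compute_dff(tr, 1:4)[5:8], rep(0.2, 4))
  # prestim mean of dF/F is identically zero
  withr::with_seed(17, {
    for (i in 1:100) {
      v <- runif(30, 0.5, 2)
      expect_equal(mean(compute_dff(v, 1:8)[1:8]), 0, tolerance = 1e-12)
    }
  })
  expect_error(compute_dff(c(-1, -1, 2), 1:2),
               class = "quietscope_baseline_error")
  expect_error(compute_dff(1:5, integer(0)),
               class = "quietscope_range_error")
})

test_that("response amplitude is the stimulus-window mean", {
  dff <- c(rep(0, 5), rep(0.3, 5), rep(0.1, 5))
  expect_equal(response_amplitude(dff, 6:10), 0.3)
  expect_equal(response_amplitude(dff, 7), dff[7])
  withr::with_seed(23, {
    for (i in 1:20) {
      v <- rnorm(40)
      w <- sort(sample(40, 7))
      expect_equal(response_amplitude(v, w), sum(v[w]) / length(w))
    }
  })
  expect_error(response_amplitude(dff, 20:25),
               class = "quietscope_range_error")
})

test_that("FRA assembly averages by grid cell and conserves trials", {
  g <- fra_grid(n_freqs = 4, level_lo = 5, level_hi = 35, level_step = 30)
  s <- session_schedule(g, cycles = 3, seed = 2)
  # constant responses give a uniform FRA
  resp <- tibble::tibble(roi = "a", trial = s$trial, frequency = s$frequency,
                         level = s$level, amplitude = 0.7)
  fra <- build_fra(resp, g)
  expect_true(all(fra$cells$mean == 0.7))
  expect_true(all(fra$cells$n_reps == 3))
  # trial conservation
  expect_equal(sum(fra$cells$n_reps), nrow(s))
  # group-by oracle on random amplitudes
  withr::with_seed(31, resp$amplitude <- rnorm(nrow(resp)))
  fra <- build_fra(resp, g)
  oracle <- aggregate(amplitude ~ frequency + level, data = resp, FUN = mean)
  m <- merge(as.data.frame(fra$cells), oracle,
             by = c("frequency", "level"))
  expect_equal(m$mean, m$amplitude, tolerance = 1e-12)
  # missing cells are masked with a warning
  gap <- !(resp$frequency == g$frequencies[1] & resp$level == g$levels[1])
  expect_warning(fra_gap <- build_fra(resp[gap, ], g), "incomplete")
  masked <- fra_gap$cells[fra_gap$cells$frequency == g$frequencies[1] &
                            fra_gap$cells$level == g$levels[1], ]
  expect_true(is.na(masked$mean))
  expect_identical(masked$n_reps, 0L)
})

test_that("best frequency/level takes the argmax with the documented tie-break", {
  g <- fra_grid(n_freqs = 3, level_lo = 5, level_hi = 35, level_step = 15)
  cells <- as_tibble(g)
  # single peak
  resp <- dplyr::mutate(cells, roi = "a", trial = dplyr::row_number(),
                        amplitude = ifelse(frequency == g$frequencies[2] &
                                             level == 20, 1, 0))
  bf <- best_frequency_level(build_fra(resp, g))
  expect_equal(bf$bf, g$frequencies[2])
  expect_equal(bf$bl, 20)
  expect_equal(bf$peak, 1)
  # uniform FRA resolves to lowest level then lowest frequency
  resp$amplitude <- 1
  bf <- best_frequency_level(build_fra(resp, g))
  expect_equal(bf$bf, g$frequencies[1])
  expect_equal(bf$bl, g$levels[1])
})

test_that("the pipeline is invariant to global gain", {
  tiny <- tiny_session(motion = FALSE, noise = FALSE, n_neurons = 3,
                       cycles = 1)
  mv <- tiny$ses$movie
  res1 <- run_fra_pipeline(mv, tiny$ses$rois, tiny$sched, register = FALSE)
  mv2 <- qs_movie(mv$frames * 3.7, frame_rate = mv$frame_rate,
                  trial = mv$trial)
  res2 <- run_fra_pipeline(mv2, tiny$ses$rois, tiny$sched, register = FALSE)
  expect_equal(res1$fra$cells$mean, res2$fra$cells$mean, tolerance = 1e-9)
  expect_equal(res1$map$bf, res2$map$bf)
  expect_equal(res1$map$bl, res2$map$bl)
})

test_that("ring contamination proportional to the soma leaves dF/F unchanged", {
  # if f_ring is proportional to f_roi, neuropil subtraction is a pure gain
  # change and dF/F is identical
  withr::with_seed(41, f <- runif(60, 1, 2))
  raw <- compute_dff(f, 1:10)
  sub <- compute_dff(neuropil_subtract(f, 0.5 * f, 0.4), 1:10)
  expect_equal(sub, raw, tolerance = 1e-12)
})

test_that("movie and mask TIFF round-trips preserve content", {
  tiny <- tiny_session(motion = FALSE, noise = FALSE, n_neurons = 2,
                       cycles = 1, frame_shape = c(24, 24), frame_rate = 5)
  mv <- tiny$ses$movie
  small <- qs_movie(mv$frames[, , 1:6], frame_rate = mv$frame_rate,
                    trial = rep(1L, 6))
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie_tiff(small, path)
  back <- read_movie_tiff(path, frame_rate = small$frame_rate)
  expect_equal(back$frames, small$frames, tolerance = 1e-6)
  mpath <- withr::local_tempfile(fileext = ".tif")
  write_masks_tiff(tiny$ses$rois, dim(mv$frames)[1:2], mpath)
  rois <- read_masks_tiff(mpath)
  expect_length(rois, 2)
  expect_equal(nrow(rois[[1]]$pixels), nrow(tiny$ses$rois[[1]]$pixels))
})
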