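test_that("cosmic-ray filter statistic and rejection rule behave as specified", {
  # uniform stack: SD = 0, strict inequality, no rejections
  st <- flat_stack(50, value = 1000)
  out <- filter_cosmic_rays(st, window = 10)
  expect_length(out$rejected, 0L)
  expect_equal(dim(out$stack$frames)[3L], 50L)

  # all-dark stack (no pixel above 800): statistic identically zero
  dark <- flat_stack(50, value = 10)
  expect_length(filter_cosmic_rays(dark, window = 10)$rejected, 0L)

  # one injected bright frame among quiet frames is rejected exactly
  set.seed(1)
  a <- array(rpois(8 * 10 * 100, 850), c(8L, 10L, 100L))
  a[, , 40] <- a[, , 40] + 5000
  st <- frame_stack(a, 0:99 / 4)
  out <- filter_cosmic_rays(st, window = 30)
  expect_equal(out$rejected, 40L)
  expect_equal(out$stack$timestamps_h, (0:99 / 4)[-40])

  # warm-up: a bright frame inside the first `window` frames survives
  a2 <- array(900, c(4L, 4L, 40L))
  a2[, , 5] <- 20000
  out2 <- filter_cosmic_rays(frame_stack(a2, 0:39 / 4), window = 30)
  expect_length(out2$rejected, 0L)

  expect_error(filter_cosmic_rays(flat_stack(5), window = 1))
})

test_that("frame binning averages pixelwise and flags empty bins", {
  # 3 frames per 45-min bin with values 1, 2, 3 -> mean 2
  a <- array(rep(1:3, each = 6), c(2L, 3L, 3L))
  st <- frame_stack(a, c(0.1, 0.3, 0.6))
  b <- bin_frames(st, 45)
  expect_equal(dim(b$frames)[3L], 1L)
  expect_true(all(b$frames[, , 1L] == 2))
  expect_equal(b$timestamps_h, 0.375)

  # single frame in a bin passes through
  st1 <- frame_stack(array(7, c(2L, 3L, 1L)), 1.0)
  expect_true(all(bin_frames(st1, 45)$frames == 7))

  # a gap left by rejection becomes a flagged missing bin, not zeros
  st2 <- frame_stack(array(5, c(2L, 2L, 2L)), c(0.1, 1.6))
  b2 <- bin_frames(st2, 45)
  expect_equal(b2$missing, c(FALSE, TRUE, FALSE))
  expect_true(all(is.na(b2$frames[, , 2L])))
})

test_that("running minimum removes single-frame transients, never increases", {
  a <- array(10, c(3L, 3L, 5L))
  a[2, 2, 3] <- 500                       # hot pixel in frame 3 only
  st <- frame_stack(a, 0:4)
  rm <- running_minimum(st)
  expect_equal(dim(rm$frames)[3L], 4L)
  expect_true(all(rm$frames == 10))       # transient gone everywhere
  # monotone increasing pixels: output equals the earlier frame
  inc <- frame_stack(array(rep(1:4, each = 4), c(2L, 2L, 4L)), 0:3)
  expect_equal(as.vector(running_minimum(inc)$frames),
               rep(1:3, each = 4))
  # never increases any pixel
  set.seed(2)
  r <- frame_stack(array(runif(4 * 4 * 6), c(4L, 4L, 6L)), 0:5)
  expect_true(all(running_minimum(r)$frames <= r$frames[, , -6]))
  expect_error(running_minimum(frame_stack(array(1, c(2L, 2L, 1L)), 0)))
})

test_that("ROI extraction subtracts the per-frame background, keeps negatives", {
  a <- array(4, c(10L, 10L, 3L))
  a[6:8, 6:8, ] <- 10
  a[6:8, 6:8, 2] <- 2                      # background brighter than cell
  rois <- roi_set(data.frame(
    label = c("c1", "background"), cell_id = c("c1", NA),
    brain_id = c("b1", NA), subgroup = c("s-LNv", NA),
    row0 = c(6L, 1L), row1 = c(8L, 3L), col0 = c(6L, 1L), col1 = c(8L, 3L)))
  tr <- extract_traces(frame_stack(a, 0:2), rois)
  expect_length(tr, 1L)
  expect_equal(tr[[1L]]$y, c(6, -2, 6))
  bad <- rois
  bad$rois$row1[1L] <- 99L
  expect_error(extract_traces(frame_stack(a, 0:2), bad), "bounds")
})

test_that("photons-per-minute conversion is linear and invertible", {
  t <- seq(0, 2, by = 1)
  tr <- cell_trace(t, c(30, 60, 90), units = "raw")
  out <- to_photons_per_minute(tr, calibration_scale = 1, exposure_min = 15)
  expect_equal(out$y, c(2, 4, 6))
  expect_equal(to_photons_per_minute(tr, 2, 15)$y, 2 * out$y)
  back <- to_photons_per_minute(out, calibration_scale = 15,
                                exposure_min = 1)
  expect_equal(back$y, tr$y)
})

test_that("end-to-end chain on rendered frames recovers the cell waveform", {
  t <- seq(0, 47.25, by = 0.75)
  y <- 60 + 40 * cos(2 * pi * t / 24)
  traces <- list(cell_trace(t, y, cell_id = "cellA"))
  fx <- simulate_frames(traces, poisson_noise = TRUE,
                        cosmic_ray_frames = c(20L, 45L),
                        hot_pixels = data.frame(frame = 10L, row = 40L,
                                                col = 60L, value = 3000),
                        seed = 11)
  out <- preprocess_stack(fx$stack, fx$rois, bin_minutes = 45,
                          window = 10L)
  expect_equal(out$rejected, c(20L, 45L))
  rec <- out$traces[[1L]]
  keep <- !is.na(rec$y)
  # binned timestamps are bin midpoints; map back by bin index
  idx <- floor(rec$t[keep] / 0.75 + 1e-9) + 1L
  expect_gt(cor(rec$y[keep], y[idx]), 0.95)

  # noiseless single-cell render: ROI mean is proportional to the signal
  fx0 <- simulate_frames(traces, poisson_noise = FALSE, seed = 1)
  tr0 <- extract_traces(fx0$stack, fx0$rois)[[1L]]
  expect_gt(cor(tr0$y, y), 0.999)

  # constant signal with no noise renders identical frames
  cst <- simulate_frames(list(cell_trace(t, rep(50, length(t)))),
                         poisson_noise = FALSE, seed = 1)
  expect_equal(cst$stack$frames[, , 1L], cst$stack$frames[, , 30L])
})
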