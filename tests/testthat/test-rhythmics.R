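test_that("wavelet detrending recovers a circadian cosine under a trend", {
  t <- seq(0, 264, by = 0.75)
  truth <- 5 * cos(2 * pi * (t - 6) / 24)
  tr <- cell_trace(t, truth + 0.05 * t + 10)
  d <- dwt_detrend(tr)
  interior <- t > 48 & t < 216
  expect_gt(cor(d$x[interior], truth[interior]), 0.99)
  expect_lt(abs(mean(d$x)), 1e-6 * sd(d$x))
  # near-idempotence: the band selection is a soft filter, not an exact
  # projection, so a second pass attenuates by the in-band gain again;
  # away from the boundary halo the change is a couple of percent RMS
  d2 <- dwt_detrend(cell_trace(d$t, d$x))
  expect_lt(sqrt(mean((d2$x - d$x)[interior]^2)) / sd(d$x), 0.02)
  expect_lt(sqrt(mean((d2$x - d$x)^2)) / sd(d$x), 0.05)
  expect_gt(cor(d2$x[interior], d$x[interior]), 0.999)
  # degenerate flat record
  z <- dwt_detrend(cell_trace(t, rep(3, length(t))))
  expect_true(all(abs(z$x) < 1e-9))
  expect_equal(z$sigma_noise, 0)
  expect_error(dwt_detrend(cell_trace(seq(0, 30, 0.75),
                                      rnorm(41))), "2 days")
})

test_that("noise floor matches an FFT band-pass oracle on white noise", {
  set.seed(42)
  n <- 352
  t <- seq_len(n) * 0.75 - 0.75
  ratios <- replicate(12, {
    x <- rnorm(n)
    d <- dwt_detrend(cell_trace(t, x))
    # brute-force band-pass: FFT mask keeping periods < 4 h
    xf <- fft(x - mean(x))
    freq <- c(0, seq_len(n - 1)) / (n * 0.75)
    freq <- pmin(freq, 1 / 0.75 - freq)     # two-sided, cycles/h
    mask <- freq > 1 / 4
    fine <- Re(fft(xf * mask, inverse = TRUE)) / n
    d$sigma_noise / sd(fine)
    })
  # the finest detail level is a soft half-band filter, so it passes a
  # little less than the ideal <4 h mask; agreement is within 20%
  expect_lt(abs(mean(ratios) - 1), 0.2)
  expect_lt(max(abs(ratios - mean(ratios))), 0.1)
  # circadian band passes little of the white noise variance
  set.seed(7)
  x <- rnorm(n)
  d <- dwt_detrend(cell_trace(t, x))
  expect_lt(sd(d$x), 0.5 * sd(x))
})

test_that("gaps are interpolated and masked", {
  t <- seq(0, 96, by = 0.75)
  y <- 4 * cos(2 * pi * t / 24)
  y[c(30:32, 60)] <- NA
  d <- dwt_detrend(cell_trace(t, y))
  expect_equal(which(d$gap_mask), c(30:32, 60))
  expect_true(all(is.finite(d$x)))
})

test_that("sine fits recover an exact cosine and report peak phase", {
  d <- cosine_trace(96, amp = 5, period = 24, peak_h = 6)
  f <- sine_fit_windows(d)
  expect_true(all(abs(f$period_h - 24) < 0.1))
  expect_true(all(abs(f$amplitude - 5) < 0.05))
  expect_true(all(f$gof > 0.999))
  # phase = peak time relative to window start, in [0, period)
  peak_clock <- (f$midpoint_h - 24 + f$phase_h) %% 24
  expect_true(all(pmin(abs(peak_clock - 6), 24 - abs(peak_clock - 6)) < 0.1))
  expect_equal(f$phase_rad, 2 * pi * f$phase_h / f$period_h)
})

test_that("sine-fit period recovery under noise is within half an hour", {
  errs <- vapply(1:40, function(s) {
    d <- cosine_trace(72, amp = 5, noise_sd = 1, seed = s)
    f <- sine_fit_windows(d, step_h = 24)
    max(abs(f$period_h - 24))
  }, numeric(1L))
  expect_gt(mean(errs < 0.5), 0.9)
})

test_that("flat windows and gappy windows are flagged", {
  d <- cosine_trace(96, amp = 0)
  f <- sine_fit_windows(d)
  expect_true(all(f$degenerate))
  expect_true(all(f$gof == 0))
  dg <- cosine_trace(96)
  dg$gap_mask[1:40] <- TRUE      # first 30 h marked missing
  fg <- sine_fit_windows(dg)
  # windows starting at 0/6/12 h overlap the gap by > 25%; from 18 h on
  # the overlap is exactly 25% and the window is fitted
  expect_equal(which(fg$skipped), 1:3)
  expect_true(all(is.na(fg$period_h[1:3])))
})

test_that("reliably-rhythmic classification applies the printed thresholds", {
  base <- data.frame(midpoint_h = 24, period_h = 24, amplitude = 5,
                     phase_h = 6, phase_rad = pi / 2, gof = 0.90,
                     skipped = FALSE, degenerate = FALSE)
  ok <- classify_rhythmic(base, sigma_noise = 1)
  expect_true(ok$reliably_rhythmic)
  expect_equal(ok$failed_criteria, "")

  # gof boundary: >= 0.82 passes, just below fails
  g1 <- base; g1$gof <- 0.82
  expect_true(classify_rhythmic(g1, 1)$reliably_rhythmic)
  g2 <- base; g2$gof <- 0.8199
  cl <- classify_rhythmic(g2, 1)
  expect_false(cl$reliably_rhythmic)
  expect_equal(cl$failed_criteria, "gof")

  # period bounds are inclusive at 16 and 32 h
  for (p in c(16, 32)) {
    pb <- base; pb$period_h <- p
    expect_true(classify_rhythmic(pb, 1)$reliably_rhythmic)
  }
  p2 <- base; p2$period_h <- 33
  expect_equal(classify_rhythmic(p2, 1)$failed_criteria, "period_range")
  p3 <- base; p3$period_h <- 15.9
  expect_false(classify_rhythmic(p3, 1)$reliably_rhythmic)

  # amplitude must rise strictly above the noise floor
  a1 <- base; a1$amplitude <- 1
  expect_equal(classify_rhythmic(a1, 1)$failed_criteria, "amplitude_floor")
  expect_true(classify_rhythmic(a1, 0.999)$reliably_rhythmic)

  # monotone: raising gof or amplitude never un-rhythms a window
  set.seed(1)
  for (i in 1:20) {
    w <- base
    w$gof <- runif(1, 0.5, 1); w$amplitude <- runif(1, 0, 3)
    before <- classify_rhythmic(w, 1)$reliably_rhythmic
    w2 <- w
    w2$gof <- min(1, w$gof + runif(1, 0, 0.2))
    w2$amplitude <- w$amplitude + runif(1, 0, 2)
    after <- classify_rhythmic(w2, 1)$reliably_rhythmic
    expect_true(!before || after)
  }
})

test_that("Lomb-Scargle calls rhythmic cells and rejects noise", {
  t <- seq(0, 96 - 0.75, by = 0.75)
  rhythmic <- lapply(1:10, function(i) {
    set.seed(i)
    as_detrended_trace(t, 5 * cos(2 * pi * (t - i) / 24) +
                         rnorm(length(t), 0, 1))
  })
  calls <- vapply(rhythmic, function(d)
    attr(lomb_scargle_rhythmic(d), "cell_rhythmic"), logical(1L))
  expect_true(all(calls))
  expect_equal(percent_rhythmic(rhythmic), 100)

  # constant trace is never rhythmic
  flat <- as_detrended_trace(t, rep(0, length(t)))
  expect_false(attr(lomb_scargle_rhythmic(flat), "cell_rhythmic"))

  # white-noise false-positive rate is near the nominal level per segment
  set.seed(99)
  faps <- replicate(150, {
    d <- as_detrended_trace(t, rnorm(length(t)))
    lomb_scargle_rhythmic(d)$rhythmic
  })
  expect_lt(mean(faps), 0.12)
})

test_that("delay embedding recovers phase progression and damping", {
  t <- seq(0, 120, by = 0.75)
  d <- as_detrended_trace(t, 4 * cos(2 * pi * t / 24))
  e <- embed_phase(d, lag_h = 6)
  interior <- e$t_h >= 24 & e$t_h <= 96
  fit <- stats::lm(phase_rad ~ t_h, data = e[interior, ])
  expect_lt(abs(coef(fit)[2L] - 2 * pi / 24) / (2 * pi / 24), 0.01)
  # damped cosine: smoothed radius decreases cycle over cycle
  dd <- as_detrended_trace(t, 4 * exp(-t / 60) * cos(2 * pi * t / 24))
  ed <- embed_phase(dd)
  i1 <- which.min(abs(ed$t_h - 36)); i2 <- which.min(abs(ed$t_h - 84))
  expect_lt(ed$amplitude[i2], ed$amplitude[i1])
  # low-radius samples are flagged invalid
  dn <- as_detrended_trace(t, 0.1 * cos(2 * pi * t / 24),
                           sigma_noise = 1)
  expect_true(all(!embed_phase(dn)$valid))
  expect_warning(embed_phase(d, lag_h = 6.1), "multiple")
})

test_that("embedded phase agrees with sine-fit phase on clean oscillators", {
  diffs <- unlist(lapply(1:6, function(i) {
    d <- cosine_trace(120, amp = 5, period = 23 + i / 3, peak_h = 2 * i,
                      noise_sd = 0.3, seed = i)
    f <- sine_fit_windows(d, step_h = 12)
    e <- embed_phase(d)
    vapply(seq_len(nrow(f)), function(j) {
      mid <- f$midpoint_h[j]
      th_sf <- 2 * pi * (mid - (mid - 24) - f$phase_h[j]) / f$period_h[j]
      th_em <- e$phase_rad[which.min(abs(e$t_h - mid))]
      dd <- (th_em - th_sf + pi) %% (2 * pi) - pi
      abs(dd) * f$period_h[j] / (2 * pi)
    }, numeric(1L))
  }))
  expect_lt(median(diffs), 0.5)
})
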