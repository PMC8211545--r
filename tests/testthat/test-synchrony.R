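ls3 <- c(0, 24, 48)

test_that("order parameter hits its closed-form anchors", {
  t <- seq(0, 72 - 0.75, by = 0.75)
  same <- lapply(1:8, function(i)
    as_detrended_trace(t, cos(2 * pi * t / 24), cell_id = paste0("c", i)))
  expect_equal(order_parameter(same, ls3)$R, rep(1, 3))
  anti <- list(as_detrended_trace(t, cos(2 * pi * t / 24)),
               as_detrended_trace(t, -cos(2 * pi * t / 24)))
  expect_equal(order_parameter(anti, ls3)$R, rep(0, 3))
  # independent noise: E[R] ~ 1/N
  set.seed(5)
  r <- replicate(60, {
    cells <- lapply(1:20, function(i) as_detrended_trace(t, rnorm(96)))
    mean(order_parameter(cells, ls3)$R)
  })
  expect_lt(abs(mean(r) - 1 / 20), 0.3 / 20)
})

test_that("order parameter is invariant to common scaling, degrades with jitter", {
  t <- seq(0, 72 - 0.75, by = 0.75)
  set.seed(3)
  cells <- lapply(1:10, function(i)
    as_detrended_trace(t, (2 + i / 5) * cos(2 * pi * (t - i / 4) / 24)))
  r1 <- order_parameter(cells, ls3)$R
  scaled <- lapply(cells, function(d)
    as_detrended_trace(d$t, 7.3 * d$x))
  expect_equal(order_parameter(scaled, ls3)$R, r1)

  mean_r_at_jitter <- vapply(c(0, 1, 2, 4), function(sd_h) {
    mean(replicate(25, {
      cells <- lapply(1:10, function(i)
        as_detrended_trace(t, cos(2 * pi * (t - rnorm(1, 0, sd_h)) / 24)))
      mean(order_parameter(cells, ls3)$R)
    }))
  }, numeric(1L))
  expect_true(all(diff(mean_r_at_jitter) < 0))
})

test_that("zero-variance cells are excluded with a warning; tiny segments missing", {
  t <- seq(0, 24 - 0.75, by = 0.75)
  cells <- c(lapply(1:3, function(i)
    as_detrended_trace(t, cos(2 * pi * t / 24))),
    list(as_detrended_trace(t, rep(0, length(t)))))
  expect_warning(rs <- order_parameter(cells, 0), "zero-variance")
  expect_equal(rs$n_cells, 3L)
  expect_equal(rs$R, 1)
  flat2 <- lapply(1:3, function(i) as_detrended_trace(t, rep(0, 32)))
  expect_warning(rs2 <- order_parameter(flat2, 0))
  expect_true(is.na(rs2$R))
})

test_that("randomization bands are nested, seeded, and sign-symmetric", {
  t <- seq(0, 72 - 0.75, by = 0.75)
  set.seed(11)
  mk <- function(jit) lapply(1:12, function(i)
    as_detrended_trace(t, cos(2 * pi * (t - rnorm(1, 0, jit)) / 24) +
                         rnorm(length(t), 0, 0.2)))
  a <- mk(0.2); b <- mk(6)
  r1 <- delta_r_bands(a, b, ls3, n_rand = 200, seed = 9)
  expect_true(all(r1$lo99 <= r1$lo95 + 1e-12))
  expect_true(all(r1$hi99 >= r1$hi95 - 1e-12))
  r2 <- delta_r_bands(a, b, ls3, n_rand = 200, seed = 9)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # swapping arms negates the observed difference and mirrors the bands
  r3 <- delta_r_bands(b, a, ls3, n_rand = 200, seed = 9)
  expect_equal(r3$dR, -r1$dR)
  expect_lt(max(abs(r3$lo95 + r1$hi95)), 0.15)
  # strongly desynchronized test arm falls below the lower band
  expect_true(any(r1$dR < r1$lo95))
  expect_equal(attr(r1, "n_subset"), 12L)
  expect_error(delta_r_bands(a[1:1], b, ls3), "2 cells")
})

test_that("circular summary concentrates, rotates, and handles empties", {
  fits <- lapply(1:10, function(i) {
    f <- data.frame(midpoint_h = c(24, 30), period_h = 24, amplitude = 5,
                    phase_h = c(6, 6), phase_rad = pi / 2, gof = 0.95,
                    skipped = FALSE, degenerate = FALSE)
    attr(f, "window_h") <- 48
    classify_rhythmic(f, sigma_noise = 1)
  })
  s <- circular_summary(fits, reference = 0)
  expect_equal(nrow(s), 2L)
  expect_equal(s$n, c(10L, 10L))
  expect_equal(s$rho, c(1, 1), tolerance = 1e-12)
  expect_lt(s$rayleigh_p[1L], 1e-4)
  expect_equal(s$alpha_radius, rep(sqrt(-log(0.05) / 10), 2L))

  # equivariance: rotating every phase rotates the mean by the same amount
  rot <- lapply(fits, function(f) { f$phase_h <- f$phase_h + 3; f })
  s2 <- circular_summary(rot, reference = 0)
  expect_equal((s2$mean_zt_h - s$mean_zt_h) %% 24, c(3, 3))
  # and shifting the reference un-rotates it
  s3 <- circular_summary(rot, reference = 3)
  expect_equal(s3$mean_zt_h, s$mean_zt_h)

  # no qualifying cells -> absent, not zero
  none <- lapply(fits, function(f) { f$reliably_rhythmic <- FALSE; f })
  expect_equal(nrow(circular_summary(none)), 0L)
})

test_that("Rayleigh p approximation matches simulation; uniform phases are null", {
  # rejection rate under uniformity is ~alpha
  set.seed(21)
  rej <- replicate(400, {
    th <- runif(40, 0, 2 * pi)
    rho <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
    rayleigh_p(40, rho) < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.03)
  # p for n = 8, rho = 0.75 against brute-force Monte-Carlo null
  set.seed(22)
  null_rho <- replicate(40000, {
    th <- runif(8, 0, 2 * pi)
    sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  })
  p_mc <- mean(null_rho >= 0.75)
  expect_lt(abs(rayleigh_p(8, 0.75) - p_mc) / p_mc, 0.1)
})

test_that("phase ensemble export reports relative angles and radii", {
  t <- seq(0, 120, by = 0.75)
  mk <- function(off, damp = Inf) {
    d <- as_detrended_trace(t, 4 * exp(-t / damp) *
                              cos(2 * pi * (t - off) / 24))
    embed_phase(d)
  }
  embeds <- list(a1 = mk(0), a2 = mk(0), b1 = mk(3))
  groups <- c(a1 = "ctrl", a2 = "ctrl", b1 = "test")
  tab <- phase_ensemble_export(embeds, groups, reference_group = "ctrl")
  sync <- subset(tab, cell_id %in% c("a1", "a2"))
  expect_true(all(abs(sync$rel_phase_rad) < 1e-6))
  lag <- subset(tab, cell_id == "b1" & t_h > 30 & t_h < 90)
  expect_equal(mean(lag$rel_phase_rad), -2 * pi * 3 / 24, tolerance = 0.1)
  # damping cell: radius decreases
  tabd <- phase_ensemble_export(list(a1 = mk(0), d1 = mk(0, damp = 50)),
                                c(a1 = "ctrl", d1 = "ctrl"), "ctrl")
  rd <- subset(tabd, cell_id == "d1" & t_h > 24 & t_h < 96)
  expect_lt(tail(rd$radius, 1), head(rd$radius, 1))
})
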