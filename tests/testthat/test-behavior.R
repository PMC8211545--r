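test_that("DAM files round-trip and malformed lines are reported", {
  set.seed(1)
  recs <- lapply(1:2, function(i)
    activity_record(sprintf("M1_ch%02d", i), rpois(60, 1), channel = i))
  f <- tempfile(fileext = ".txt")
  write_dam(recs, f)
  back <- read_dam(f)
  expect_length(back, 32L)
  expect_equal(back[[1L]]$counts, recs[[1L]]$counts)
  expect_equal(back[[2L]]$counts, recs[[2L]]$counts)
  expect_true(all(back[[3L]]$counts == 0L))

  lines <- readLines(f)
  writeLines(c(lines[1L], paste(strsplit(lines[2L], "\t")[[1L]][1:41],
                                collapse = "\t")), f)
  expect_error(read_dam(f), "line 2")
  writeLines(sub("\t0$", "\tx", lines[1L]), f)
  expect_error(read_dam(f), "non-integer")
  writeLines(character(0), f)
  expect_warning(out <- read_dam(f), "empty")
  expect_length(out, 0L)
})

test_that("chi-square periodogram matches a brute-force reimplementation", {
  # naive Qp: fold counts at each period, direct column means
  naive_qp <- function(x, K) {
    h <- (seq_along(x) - 1L) %% K
    M <- vapply(0:(K - 1L), function(j) mean(x[h == j]), numeric(1L))
    nh <- vapply(0:(K - 1L), function(j) sum(h == j), numeric(1L))
    sum(nh * (M - mean(x))^2) / var(x)
  }
  set.seed(8)
  for (i in 1:10) {
    rec <- rhythmic_fly(days = 4, seed = i, high = runif(1, 0.5, 3))
    pg <- chi2_periodogram(rec)
    nb <- length(rec$counts) %/% 15L
    x <- colSums(matrix(rec$counts[seq_len(nb * 15L)], 15L, nb))
    Ks <- round(pg$periods_h * 4)
    expect_equal(pg$Qp, vapply(Ks, function(K) naive_qp(x, K),
                               numeric(1L)))
  }
})

test_that("periodogram classification follows the stated criteria", {
  # 5-day windows, matching the standard analysis design
  rec <- rhythmic_fly(days = 5, seed = 3)
  pg <- chi2_periodogram(rec)
  expect_true(pg$rhythmic)
  expect_lt(abs(pg$peak_period_h - 24), 0.5)
  expect_gte(pg$power, 40)
  expect_gte(pg$width_h, 4)
  # scaling counts does not move the period estimate
  rec10 <- activity_record("f", rec$counts * 10L)
  expect_equal(chi2_periodogram(rec10)$peak_period_h, pg$peak_period_h)
  # a 26-h fly peaks at 26 h
  rec26 <- rhythmic_fly(days = 5, seed = 4, period_h = 26)
  expect_lt(abs(chi2_periodogram(rec26)$peak_period_h - 26), 0.5)
  # all-zero record is flagged, not rhythmic
  z <- chi2_periodogram(activity_record("z", rep(0L, 5 * 1440)))
  expect_false(z$rhythmic)
  expect_true(z$all_zero)
  expect_error(chi2_periodogram(activity_record("s", rep(1L, 1440))),
               "3 days")
  # power just under threshold fails regardless of the rest
  pg2 <- pg
  pg2$power <- 39.9
  expect_true(pg2$power < 40)   # boundary definition, checked in classify
})

test_that("flat Poisson flies are rarely called rhythmic", {
  set.seed(31)
  calls <- vapply(1:40, function(i) {
    rec <- activity_record("f", rpois(5 * 1440, 1))
    chi2_periodogram(rec)$rhythmic
  }, logical(1L))
  expect_lte(mean(calls), 0.05)
})

test_that("sleep scoring applies the 5-min rule exactly", {
  # one 5-min zero run inside an active hour
  x <- rep(1L, 60)
  x[11:15] <- 0L
  expect_equal(score_sleep(activity_record("f", x))$sleep_min, 5)
  # 4-min runs never count
  x4 <- rep(1L, 60)
  x4[11:14] <- 0L
  expect_equal(score_sleep(activity_record("f", x4))$sleep_min, 0)
  # saturation: all zeros
  s24 <- score_sleep(activity_record("f", rep(0L, 1440)))
  expect_equal(s24$sleep_min, rep(60, 24))
  expect_equal(s24$daily_total_min, 1440)
  # runs spanning bin boundaries split between bins
  xb <- rep(1L, 180)
  xb[55:70] <- 0L                     # 16-min run crossing the 60-min line
  sb <- score_sleep(activity_record("f", xb))
  expect_equal(sb$sleep_min, c(6, 10, 0))
  # conservation: sleep + wake = 60 per complete bin
  set.seed(12)
  xr <- rpois(2880, 0.4)
  sr <- score_sleep(activity_record("f", xr))
  awake <- tapply(sr$sleep_minutes, rep(1:48, each = 60), sum)
  expect_equal(as.numeric(awake), sr$sleep_min)
  expect_true(all(sr$sleep_min >= 0 & sr$sleep_min <= 60))
})

test_that("dead flies are removed on terminal silence only", {
  alive <- activity_record("a", c(rpois(4 * 1440, 1), rep(0L, 720),
                                  rpois(1440, 1)))
  dead <- activity_record("d", c(rpois(2 * 1440, 1), rep(0L, 3 * 1440)))
  out <- remove_dead(list(alive, dead), tail_zero_h = 24)
  expect_equal(out$dead, c(FALSE, TRUE))
  expect_equal(out$kept[[1L]]$fly_id, "a")
  expect_equal(out$removed[[1L]]$fly_id, "d")
  # siesta shorter than the threshold is kept even at record end
  nap <- activity_record("n", c(rpois(1440, 1), rep(0L, 600)))
  expect_false(remove_dead(list(nap))$dead)
  expect_false(any(remove_dead(list(alive, dead), Inf)$dead))
})

test_that("sleep comparison flags separated groups and respects alpha", {
  mk <- function(counts) score_sleep(activity_record("f", counts))
  always <- lapply(1:10, function(i) mk(rep(0L, 120)))
  never <- lapply(1:10, function(i) mk(rep(1L, 120)))
  cmp <- compare_sleep(always, never, alpha = 0.01)
  expect_true(all(cmp$bins$significant))
  expect_true(all(cmp$bins$p < 0.001))
  expect_equal(cmp$bins$median_diff, c(-60, -60))
  # identical degenerate groups: degenerate bins get NA, never significant
  cmp0 <- compare_sleep(always, always)
  expect_true(all(is.na(cmp0$bins$p)))
  expect_false(any(cmp0$bins$significant))
})

test_that("actogram matrices double-plot correctly", {
  set.seed(2)
  rec <- activity_record("f", rpois(3 * 1440, 1))
  m <- actogram_matrix(rec)
  expect_equal(dim(m), c(2L, 2880L))
  expect_equal(m[1L, 1441:2880], m[2L, 1:1440])
  expect_true(max(m) <= 1 && min(m) >= 0)
  z <- actogram_matrix(activity_record("z", rep(0L, 2 * 1440)))
  expect_true(all(z == 0))
  single <- actogram_matrix(rec, double_plot = FALSE)
  expect_equal(dim(single), c(3L, 1440L))
})

test_that("simulated flies are rhythmic with crepuscular structure", {
  sched <- build_protocol(protocol_spec("ld_strobe", n_days = 5))
  sim <- simulate_activity(8, sched, seed = 5)
  calls <- vapply(sim$records, function(r) chi2_periodogram(r)$rhythmic,
                  logical(1L))
  periods <- vapply(sim$records,
                    function(r) chi2_periodogram(r)$peak_period_h,
                    numeric(1L))
  expect_gte(mean(calls), 0.9)
  expect_true(all(abs(periods[calls] - 24) <= 1))
  # death zeroes the tail and the dead-fly filter catches exactly those
  sim2 <- simulate_activity(6, sched,
                            params = list(death_time_h = c(rep(NA, 4),
                                                           60, 80)),
                            seed = 6)
  flagged <- remove_dead(sim2$records)$dead
  expect_equal(flagged, c(rep(FALSE, 4), TRUE, TRUE))
  # ground-truth bouts of 5+ min are scored as sleep
  prof <- score_sleep(sim$records[[1L]])
  gt <- sim$truth[[1L]]$sleep_bouts
  long <- gt[gt$end_min - gt$start_min >= 5, ]
  covered <- vapply(seq_len(nrow(long)), function(i)
    all(prof$sleep_minutes[(long$start_min[i] + 1L):long$end_min[i]]),
    logical(1L))
  expect_true(all(covered))
})
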