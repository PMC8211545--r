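#' Simulate fly locomotor activity under a light schedule
#'
#' Generates per-minute infrared beam-crossing counts for `n_flies` from
#' an inhomogeneous Poisson process whose rate carries crepuscular
#' (morning and evening) activity peaks phase-locked to each day's
#' (possibly shifted) lights-on. Consolidated sleep bouts - intervals
#' during which the rate is forced to zero - alternate with wake bouts;
#' bout durations are exponential with longer sleep at night. An
#' optional per-fly death time zeroes all later counts.
#'
#' @param n_flies Number of flies.
#' @param schedule A `light_schedule`.
#' @param params List of rate parameters: `base_rate` (night floor,
#'   counts/min), `day_rate` (daytime plateau) and `peak_rate`
#'   (crepuscular bump height), `peak_width_h`, `morning_zt`/
#'   `evening_zt` (bump centres, h after lights-on), `onset_jitter_h`
#'   (step SD of the per-fly random-walk drift of daily activity
#'   timing, emulating day-to-day onset variability),
#'   `wake_mean_day`/`wake_mean_night` and
#'   `sleep_mean_day`/`sleep_mean_night` (mean bout lengths, min),
#'   `death_time_h` (per-fly vector or single value, `NA` = alive).
#' @param seed Integer seed.
#' @return A list with `records` (list of `activity_record`: `fly_id`,
#'   `t_min`, `counts`) and `truth` (per-fly list of ground-truth sleep
#'   bout data.frames with `start_min`, `end_min`, plus `death_time_h`).
#' @export
simulate_activity <- function(n_flies, schedule, params = list(), seed = 1L) {
  stopifnot(n_flies >= 1L, inherits(schedule, "light_schedule"))
  p <- utils::modifyList(list(
    base_rate = 0.1, day_rate = 3, peak_rate = 3, peak_width_h = 2,
    morning_zt = 0.5, evening_zt = 11.5, onset_jitter_h = 0.75,
    wake_mean_day = 35, wake_mean_night = 25,
    sleep_mean_day = 12, sleep_mean_night = 35,
    death_time_h = NA_real_), params)
  set.seed(seed)
  n_min <- floor(schedule$total_h * 60 + 1e-9)
  t_min <- seq_len(n_min) - 1L
  t_h <- t_min / 60
  on <- lights_on_times(schedule)
  day_of <- pmin(floor(t_h / 24 + 1e-9), nrow(on) - 1L)
  zt0 <- (t_h - on$lights_on_h[day_of + 1L]) %% 24
  death <- rep_len(p$death_time_h, n_flies)

  records <- vector("list", n_flies)
  truth <- vector("list", n_flies)
  for (f in seq_len(n_flies)) {
    jit <- cumsum(stats::rnorm(max(day_of) + 1L, 0, p$onset_jitter_h))
    zt <- (zt0 - jit[day_of + 1L]) %% 24
    rate <- p$base_rate +
      (p$day_rate - p$base_rate) *
        stats::plogis((6 - circ_diff_h(zt, 6)) / 0.5) +
      p$peak_rate *
      (exp(-0.5 * (circ_diff_h(zt, p$morning_zt) / p$peak_width_h)^2) +
       exp(-0.5 * (circ_diff_h(zt, p$evening_zt) / p$peak_width_h)^2))
    night <- zt >= 12
    asleep <- logical(n_min)
    bouts <- list()
    t <- 0L
    sleeping <- FALSE
    while (t < n_min) {
      isnight <- night[t + 1L]
      if (sleeping) {
        len <- max(1L, stats::rpois(1L, if (isnight) p$sleep_mean_night
                                    else p$sleep_mean_day))
        to <- min(n_min, t + len)
        asleep[(t + 1L):to] <- TRUE
        bouts[[length(bouts) + 1L]] <- c(t, to)
        t <- to
      } else {
        len <- max(1L, stats::rpois(1L, if (isnight) p$wake_mean_night
                                    else p$wake_mean_day))
        t <- min(n_min, t + len)
      }
      sleeping <- !sleeping
    }
    counts <- stats::rpois(n_min, rate)
    counts[asleep] <- 0L
    if (!is.na(death[f])) counts[t_h >= death[f]] <- 0L
    bt <- if (length(bouts))
      data.frame(start_min = vapply(bouts, `[`, 0, 1L),
                 end_min = vapply(bouts, `[`, 0, 2L))
    else data.frame(start_min = numeric(0), end_min = numeric(0))
    records[[f]] <- activity_record(sprintf("fly%02d", f), counts)
    truth[[f]] <- list(sleep_bouts = bt, death_time_h = death[f])
  }
  list(records = records, truth = truth)
}

# hour difference on the 24-h circle
circ_diff_h <- function(a, b) {
  d <- (a - b) %% 24
  pmin(d, 24 - d)
}

#' Per-fly activity record
#'
#' @param fly_id Identifier.
#' @param counts Non-negative integer beam crossings on a uniform 1-min
#'   grid starting at minute 0.
#' @param monitor,channel Optional DAM monitor/channel labels.
#' @return An object of class `activity_record`.
#' @export
activity_record <- function(fly_id, counts, monitor = "M1", channel = 1L) {
  counts <- as.integer(counts)
  if (any(is.na(counts)) || any(counts < 0))
    stop("`counts` must be non-negative integers")
  structure(list(fly_id = fly_id, monitor = monitor,
                 channel = as.integer(channel),
                 t_min = seq_along(counts) - 1L, counts = counts),
            class = "activity_record")
}

#' @export
print.activity_record <- function(x, ...) {
  cat(sprintf("<activity_record> %s (%s ch%d), %d min, %d crossings\n",
              x$fly_id, x$monitor, x$channel, length(x$counts),
              sum(x$counts)))
  invisible(x)
}
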