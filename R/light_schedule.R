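#' Light-schedule protocols
#'
#' A `light_schedule` is an explicit, contiguous sequence of light/dark
#' intervals covering an experiment, in continuous hours from experiment
#' start. Day `d` spans `[24 d, 24 (d + 1))`; intervals are half-open
#' `[start_h, end_h)`. Schedules are built from a [protocol_spec()] with
#' [build_protocol()] and can be phase-shifted with [apply_wls()].
#'
#' @name light_schedule
NULL

#' Specify a light protocol
#'
#' Describes one of the entrainment protocols used for ex vivo brain
#' imaging and in vivo behavior: standard 12/12 LD, strobed LD (one short
#' light pulse at the top of each of the 12 daytime hours, e.g. 15 min
#' light / 45 min dark, then 12 h night darkness), skeleton photoperiod
#' (pulses only at dawn and dusk), constant light (the hourly pulse/dark
#' cycle continues through the night hours), or constant darkness.
#'
#' @param kind One of `"standard_ld"`, `"ld_strobe"`, `"spp"`, `"ll"`,
#'   `"dd"`.
#' @param n_days Number of days under the protocol proper (before any DD
#'   tail).
#' @param pulse_min Pulse duration in minutes for `ld_strobe`, `spp` and
#'   `ll` (5, 15 or 30 in the source experiments; any value `< 60` is
#'   accepted). Ignored for `standard_ld` and `dd`.
#' @param dd_tail_days Days of constant darkness appended after the lit
#'   protocol.
#' @param wls Optional weekend-light-shift description: a list with
#'   elements `delay_h` (phase-shift magnitude, hours, > 0),
#'   `delay_start_day` (0-based day index whose evening starts the delay)
#'   and `advance_day` (0-based day index whose morning restores the
#'   original phase).
#' @return An object of class `protocol_spec`.
#' @seealso [build_protocol()]
#' @export
protocol_spec <- function(kind = c("ld_strobe", "standard_ld", "spp", "ll", "dd"),
                          n_days = 8L, pulse_min = 15, dd_tail_days = 0L,
                          wls = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(n_days) || length(n_days) != 1L || n_days < 1 ||
      n_days != round(n_days))
    stop("`n_days` must be a positive whole number")
  if (!is.numeric(pulse_min) || pulse_min <= 0 || pulse_min >= 60)
    stop("`pulse_min` must be in (0, 60) minutes")
  if (dd_tail_days < 0 || dd_tail_days != round(dd_tail_days))
    stop("`dd_tail_days` must be a non-negative whole number")
  if (!is.null(wls)) {
    if (!kind %in% c("ld_strobe", "standard_ld"))
      stop("`wls` is only supported for kind = 'ld_strobe' or 'standard_ld'")
    stopifnot(is.list(wls))
    need <- c("delay_h", "delay_start_day", "advance_day")
    if (!all(need %in% names(wls)))
      stop("`wls` must have elements delay_h, delay_start_day, advance_day")
    if (wls$delay_h < 0) stop("`wls$delay_h` must be >= 0")
    if (wls$delay_start_day < 0 || wls$delay_start_day >= n_days ||
        wls$advance_day < 0 || wls$advance_day >= n_days)
      stop("wls day indices must lie in [0, n_days)")
    if (wls$delay_start_day >= wls$advance_day)
      stop("`wls$delay_start_day` must precede `wls$advance_day`")
  }
  structure(list(kind = kind, n_days = as.integer(n_days),
                 pulse_min = pulse_min,
                 dd_tail_days = as.integer(dd_tail_days), wls = wls),
            class = "protocol_spec")
}

new_light_schedule <- function(intervals, day_length_h = 24) {
  stopifnot(is.data.frame(intervals),
            all(c("start_h", "end_h", "state", "epoch_label") %in%
                  names(intervals)))
  o <- order(intervals$start_h)
  intervals <- intervals[o, , drop = FALSE]
  rownames(intervals) <- NULL
  validate_intervals(intervals)
  structure(list(intervals = intervals, day_length_h = day_length_h,
                 total_h = intervals$end_h[nrow(intervals)]),
            class = "light_schedule")
}

validate_intervals <- function(iv) {
  if (nrow(iv) == 0L) stop("schedule has no intervals")
  if (any(iv$end_h <= iv$start_h))
    stop("all intervals must have positive duration")
  if (nrow(iv) > 1L) {
    gap <- iv$start_h[-1L] - iv$end_h[-nrow(iv)]
    if (any(abs(gap) > 1e-9))
      stop("intervals must be contiguous and non-overlapping")
  }
  if (abs(iv$start_h[1L]) > 1e-9) stop("schedule must start at t = 0")
  if (!all(iv$state %in% c("light", "dark")))
    stop("interval state must be 'light' or 'dark'")
  invisible(iv)
}

# Merge adjacent intervals with identical state and epoch label.
coalesce_intervals <- function(iv) {
  if (nrow(iv) <= 1L) return(iv)
  keep <- c(TRUE, iv$state[-1L] != iv$state[-nrow(iv)] |
              iv$epoch_label[-1L] != iv$epoch_label[-nrow(iv)])
  grp <- cumsum(keep)
  out <- data.frame(
    start_h = tapply(iv$start_h, grp, min),
    end_h = tapply(iv$end_h, grp, max),
    state = iv$state[keep],
    epoch_label = iv$epoch_label[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build a light schedule from a protocol specification
#'
#' Expands a [protocol_spec()] into an explicit interval sequence. For
#' `ld_strobe`, each of the 12 daytime hours of each day carries exactly
#' one pulse of `pulse_min` minutes at the top of the hour followed by
#' darkness; the 12 night hours are dark. For `spp`, only two pulses cap
#' each 12-h day: the dawn pulse starts at lights-on and the dusk pulse
#' ends at the dark transition. For `ll` the hourly pulse/dark cycle
#' continues through the night hours (there is no 12-h night). For
#' `standard_ld`, 12 h of continuous light then 12 h dark. For `dd`,
#' darkness throughout. A DD tail and an optional weekend light shift
#' (see [apply_wls()]) are applied afterwards.
#'
#' @param spec A [protocol_spec()].
#' @return A `light_schedule`.
#' @examples
#' sched <- build_protocol(protocol_spec("ld_strobe", n_days = 3))
#' lights_on_times(sched)
#' @export
build_protocol <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  pulse_h <- spec$pulse_min / 60
  day_iv <- function(day, label) {
    t0 <- 24 * day
    switch(spec$kind,
      standard_ld = data.frame(
        start_h = t0 + c(0, 12), end_h = t0 + c(12, 24),
        state = c("light", "dark"), epoch_label = label,
        stringsAsFactors = FALSE),
      ld_strobe = {
        hrs <- 0:11
        data.frame(
          start_h = t0 + c(as.vector(rbind(hrs, hrs + pulse_h)), 12),
          end_h = t0 + c(as.vector(rbind(hrs + pulse_h, hrs + 1)), 24),
          state = c(rep(c("light", "dark"), 12L), "dark"),
          epoch_label = label, stringsAsFactors = FALSE)
      },
      spp = data.frame(
        start_h = t0 + c(0, pulse_h, 12 - pulse_h, 12),
        end_h = t0 + c(pulse_h, 12 - pulse_h, 12, 24),
        state = c("light", "dark", "light", "dark"),
        epoch_label = label, stringsAsFactors = FALSE),
      ll = {
        hrs <- 0:23
        data.frame(
          start_h = t0 + as.vector(rbind(hrs, hrs + pulse_h)),
          end_h = t0 + as.vector(rbind(hrs + pulse_h, hrs + 1)),
          state = rep(c("light", "dark"), 24L),
          epoch_label = label, stringsAsFactors = FALSE)
      },
      dd = data.frame(
        start_h = t0, end_h = t0 + 24, state = "dark",
        epoch_label = label, stringsAsFactors = FALSE))
  }
  label <- switch(spec$kind, dd = "DD", ll = "LL", "weekday")
  iv <- do.call(rbind, lapply(seq_len(spec$n_days) - 1L, day_iv, label = label))
  if (spec$dd_tail_days > 0L) {
    t0 <- 24 * spec$n_days
    iv <- rbind(iv, data.frame(
      start_h = t0 + 24 * (seq_len(spec$dd_tail_days) - 1L),
      end_h = t0 + 24 * seq_len(spec$dd_tail_days),
      state = "dark", epoch_label = "DD", stringsAsFactors = FALSE))
  }
  sched <- new_light_schedule(iv)
  if (!is.null(spec$wls))
    sched <- apply_wls(sched, spec$wls$delay_h, spec$wls$delay_start_day,
                       spec$wls$advance_day)
  sched
}

#' Apply a weekend light shift to a schedule
#'
#' Translates every light interval from the lights-off transition on the
#' evening of `delay_start_day` up to (not including) the morning of
#' `advance_day` later by `delay_h` hours, then restores the original
#' phase from `advance_day` on (a phase advance of the same magnitude).
#' This reproduces the weekend-light-shift manipulation: a 3-h phase
#' delay Friday evening held through the weekend, then a 3-h advance
#' Monday morning. Shifted intervals are labelled
#' `"weekend_delayed"`.
#'
#' The documented convention (the source protocol does not give
#' minute-level mechanics) is that the delay begins at the dusk
#' transition of `delay_start_day`: that night is lengthened at its
#' start, and every subsequent pulse up to the advance morning moves
#' `delay_h` later. On `advance_day` the first (delayed) lights-on is
#' simply dropped back to the original phase, shortening that night.
#'
#' @param schedule A `light_schedule`.
#' @param delay_h Phase-delay magnitude in hours (0 returns the input
#'   unchanged).
#' @param delay_start_day 0-based index of the day whose evening starts
#'   the delay.
#' @param advance_day 0-based index of the day whose morning restores the
#'   original phase.
#' @return A `light_schedule` with shifted intervals.
#' @export
apply_wls <- function(schedule, delay_h, delay_start_day, advance_day) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (delay_h < 0) stop("`delay_h` must be >= 0")
  if (delay_h == 0) return(schedule)
  n_days <- floor(schedule$total_h / 24 + 1e-9)
  if (delay_start_day < 0 || advance_day > n_days)
    stop("wls day indices outside schedule")
  if (delay_start_day >= advance_day)
    stop("`delay_start_day` must precede `advance_day`")
  iv <- schedule$intervals
  # dusk of delay_start_day = end of that day's last light interval
  day_of <- floor(iv$start_h / 24 + 1e-9)
  lit <- iv$state == "light"
  dusk_idx <- which(lit & day_of == delay_start_day)
  if (length(dusk_idx) == 0L)
    stop("`delay_start_day` has no light interval to delay from")
  t_dusk <- max(iv$end_h[dusk_idx])
  t_advance <- 24 * advance_day
  shift_sel <- lit & iv$start_h >= t_dusk - 1e-9 & iv$start_h < t_advance - 1e-9
  if (!any(shift_sel)) return(schedule)
  new_light <- iv[shift_sel, , drop = FALSE]
  new_light$start_h <- new_light$start_h + delay_h
  new_light$end_h <- new_light$end_h + delay_h
  new_light$epoch_label <- "weekend_delayed"
  if (any(new_light$end_h > schedule$total_h + 1e-9))
    stop("shifted light intervals fall outside the schedule duration")
  keep_light <- iv[lit & !shift_sel, , drop = FALSE]
  all_light <- rbind(keep_light, new_light)
  all_light <- all_light[order(all_light$start_h), , drop = FALSE]
  if (nrow(all_light) > 1L &&
      any(all_light$start_h[-1L] < all_light$end_h[-nrow(all_light)] - 1e-9))
    stop("shift would make light intervals overlap")
  # rebuild dark gaps between light intervals
  pieces <- list()
  cursor <- 0
  dark_label <- function(t0) {
    if (t0 >= t_dusk - 1e-9 && t0 < t_advance + delay_h - 1e-9)
      "weekend_delayed"
    else {
      j <- findInterval(t0 + 1e-9, iv$start_h)
      iv$epoch_label[max(1L, j)]
    }
  }
  for (i in seq_len(nrow(all_light))) {
    s <- all_light$start_h[i]
    if (s > cursor + 1e-9)
      pieces[[length(pieces) + 1L]] <- data.frame(
        start_h = cursor, end_h = s, state = "dark",
        epoch_label = dark_label(cursor), stringsAsFactors = FALSE)
    pieces[[length(pieces) + 1L]] <- all_light[i, , drop = FALSE]
    cursor <- all_light$end_h[i]
  }
  if (cursor < schedule$total_h - 1e-9)
    pieces[[length(pieces) + 1L]] <- data.frame(
      start_h = cursor, end_h = schedule$total_h, state = "dark",
      epoch_label = dark_label(cursor), stringsAsFactors = FALSE)
  new_light_schedule(do.call(rbind, pieces), schedule$day_length_h)
}

#' Query the light state at a time point
#'
#' @param schedule A `light_schedule`.
#' @param t Time in hours from experiment start (vectorized). Intervals
#'   are half-open `[start, end)`; the final boundary `t = total
#'   duration` maps to the last interval.
#' @return Character vector, `"light"` or `"dark"`.
#' @export
light_state <- function(schedule, t) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (any(t < -1e-9 | t > schedule$total_h + 1e-9))
    stop("`t` outside schedule duration")
  iv <- schedule$intervals
  j <- findInterval(pmin(t, schedule$total_h - 1e-12), iv$start_h,
                    rightmost.closed = FALSE)
  j[j < 1L] <- 1L
  iv$state[j]
}

#' Per-day lights-on times
#'
#' Returns, for each simulated day, the start of that day's first light
#' interval (the lights-on transition bounding the 24-h analysis
#' segments). For DD days the value is extrapolated from the last lit
#' day's lights-on phase at 24-h spacing and flagged.
#'
#' @param schedule A `light_schedule`.
#' @return A data.frame with columns `day` (0-based), `lights_on_h` and
#'   `extrapolated`.
#' @export
lights_on_times <- function(schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  n_days <- ceiling(schedule$total_h / 24 - 1e-9)
  if (n_days < 1L) stop("schedule must span at least one day")
  iv <- schedule$intervals
  lit <- iv[iv$state == "light", , drop = FALSE]
  on_h <- rep(NA_real_, n_days)
  for (d in seq_len(n_days) - 1L) {
    sel <- lit$start_h >= 24 * d - 1e-9 & lit$start_h < 24 * (d + 1) - 1e-9
    if (any(sel)) on_h[d + 1L] <- min(lit$start_h[sel])
  }
  extrap <- is.na(on_h)
  if (all(extrap)) {               # pure DD: anchor at day starts
    on_h <- 24 * (seq_len(n_days) - 1L)
  } else if (any(extrap)) {
    for (d in which(extrap)) {
      prev <- which(!is.na(on_h[seq_len(d - 1L)]))
      if (length(prev)) {
        p <- max(prev)
        on_h[d] <- on_h[p] + 24 * (d - p)
      }
    }
    # leading DD days (lit day comes later): extrapolate backwards
    for (d in rev(which(is.na(on_h)))) on_h[d] <- on_h[d + 1L] - 24
  }
  data.frame(day = seq_len(n_days) - 1L, lights_on_h = on_h,
             extrapolated = extrap)
}

#' Total hours of light in a schedule
#' @param schedule A `light_schedule`.
#' @return Hours of light summed over all light intervals.
#' @export
light_hours <- function(schedule) {
  iv <- schedule$intervals
  sum((iv$end_h - iv$start_h)[iv$state == "light"])
}

#' @export
print.light_schedule <- function(x, ...) {
  iv <- x$intervals
  cat(sprintf("<light_schedule> %.1f h (%.1f days), %d intervals, %.1f h light\n",
              x$total_h, x$total_h / 24, nrow(iv), light_hours(x)))
  epochs <- unique(iv$epoch_label)
  cat("  epochs:", paste(epochs, collapse = ", "), "\n")
  invisible(x)
}

#' Read/write light schedules and protocol configs
#'
#' `write_schedule_csv()`/`read_schedule_csv()` round-trip the interval
#' table (`start_h, end_h, state, epoch_label`). `read_protocol_config()`
#' parses a plain-text `key = value` file with keys `kind`, `n_days`,
#' `pulse_min`, `dd_tail_days`, `wls.delay_h`, `wls.delay_start_day`,
#' `wls.advance_day` into a [protocol_spec()].
#'
#' @param schedule A `light_schedule`.
#' @param path File path.
#' @return `read_schedule_csv()` a `light_schedule`;
#'   `read_protocol_config()` a `protocol_spec`.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule$intervals, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  new_light_schedule(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname write_schedule_csv
#' @export
read_protocol_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  get <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  wls <- NULL
  if (!is.na(match("wls.delay_h", keys)))
    wls <- list(delay_h = as.numeric(get("wls.delay_h")),
                delay_start_day = as.integer(get("wls.delay_start_day")),
                advance_day = as.integer(get("wls.advance_day")))
  protocol_spec(kind = get("kind", "ld_strobe"),
                n_days = as.integer(get("n_days", "8")),
                pulse_min = as.numeric(get("pulse_min", "15")),
                dd_tail_days = as.integer(get("dd_tail_days", "0")),
                wls = wls)
}
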