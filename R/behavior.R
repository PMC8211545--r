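#' Read and write DAM monitor files
#'
#' Tab-separated Drosophila Activity Monitor text: one line per minute
#' with fields `index`, `date` (`d Mon yy`), `time` (`HH:MM:SS`), a
#' status code, six reserved fields, then 32 channel counts (42 columns
#' in total). `read_dam()` returns one [activity_record()] per channel;
#' channels that never register a crossing are still returned. The
#' write/read round trip is lossless for up to 32 flies.
#'
#' @param path File path.
#' @param monitor Monitor label attached to the records.
#' @return `read_dam()`: list of `activity_record` (empty, with a
#'   warning, for an empty file).
#' @export
read_dam <- function(path, monitor = "M1") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty DAM file: ", path)
    return(list())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf != 42L))
    stop("malformed DAM line ", which(nf != 42L)[1L], ": expected 42 ",
         "tab-separated fields, got ", nf[nf != 42L][1L])
  counts <- t(vapply(parts, function(p) {
    v <- suppressWarnings(as.integer(p[11:42]))
    if (anyNA(v))
      stop("non-integer count on DAM line ", p[1L])
    v
  }, integer(32L)))
  lapply(seq_len(32L), function(ch)
    activity_record(sprintf("%s_ch%02d", monitor, ch), counts[, ch],
                    monitor = monitor, channel = ch))
}

#' @rdname read_dam
#' @param records List of up to 32 `activity_record` objects on one
#'   common minute grid.
#' @param start Start time of the recording (`POSIXct`-coercible), used
#'   only to render the date/time columns.
#' @export
write_dam <- function(records, path, start = "2020-01-01 00:00:00") {
  stopifnot(length(records) >= 1L, length(records) <= 32L)
  n <- length(records[[1L]]$counts)
  for (r in records) stopifnot(length(r$counts) == n)
  mat <- matrix(0L, n, 32L)
  for (i in seq_along(records)) mat[, i] <- records[[i]]$counts
  tt <- as.POSIXct(start, tz = "UTC") + 60 * (seq_len(n) - 1L)
  lines <- paste(seq_len(n), format(tt, "%e %b %y"),
                 format(tt, "%H:%M:%S"), 1L,
                 0L, 0L, 0L, 0L, 0L, 0L,
                 apply(mat, 1L, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Chi-square periodogram rhythmicity
#'
#' Sokolove-Bushell chi-square periodogram on binned activity counts,
#' with the standard fly-circadian acceptance criteria: a fly is
#' rhythmic when the peak's power (Qp minus the significance line at the
#' peak period) is at least `power_min`, the contiguous run of
#' super-threshold periods around the peak spans at least `width_min_h`
#' hours, and the peak period lies within `period_range` (24 +/- 8 h).
#' Candidate periods are integer multiples of the bin width; for period
#' P = K bins, `Qp = sum_h n_h (M_h - M)^2 / s^2` over the K folded
#' column means `M_h` (column sizes `n_h`), which is chi-square with
#' K - 1 degrees of freedom under the null; the significance line is
#' the `1 - alpha` chi-square quantile.
#'
#' @param rec An [activity_record()] spanning at least 3 days.
#' @param bin_min Counting bin, minutes (default 15).
#' @param period_range Periods tested, hours.
#' @param alpha Significance level of the line (default 0.05).
#' @param power_min,width_min_h Classification thresholds.
#' @return A list of class `periodogram_result`: `periods_h`, `Qp`,
#'   `sig_line`, `peak_period_h`, `power`, `width_h`, `rhythmic`,
#'   `all_zero`.
#' @export
chi2_periodogram <- function(rec, bin_min = 15, period_range = c(16, 32),
                             alpha = 0.05, power_min = 40,
                             width_min_h = 4) {
  stopifnot(inherits(rec, "activity_record"))
  n_min <- length(rec$counts)
  if (n_min < 3 * 1440) stop("need at least 3 days of data")
  nb <- n_min %/% bin_min
  x <- colSums(matrix(rec$counts[seq_len(nb * bin_min)], bin_min, nb))
  if (all(x == 0)) {
    res <- list(periods_h = numeric(0), Qp = numeric(0),
                sig_line = numeric(0), peak_period_h = NA_real_,
                power = NA_real_, width_h = 0, rhythmic = FALSE,
                all_zero = TRUE)
    class(res) <- "periodogram_result"
    return(res)
  }
  Ks <- seq(ceiling(period_range[1L] * 60 / bin_min),
            floor(period_range[2L] * 60 / bin_min))
  s2 <- stats::var(x)
  xm <- mean(x)
  Qp <- vapply(Ks, function(K) {
    h <- (seq_along(x) - 1L) %% K
    M <- tapply(x, h, mean)
    nh <- tabulate(h + 1L, nbins = K)
    sum(nh * (M - xm)^2) / s2
  }, numeric(1L))
  periods_h <- Ks * bin_min / 60
  sig_line <- stats::qchisq(1 - alpha, df = Ks - 1L)
  excess <- Qp - sig_line
  pk <- which.max(excess)
  above <- excess > 0
  lo <- pk; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- pk; while (hi < length(above) && above[hi + 1L]) hi <- hi + 1L
  width_h <- if (above[pk]) periods_h[hi] - periods_h[lo] + bin_min / 60
             else 0
  power <- excess[pk]
  peak <- periods_h[pk]
  res <- list(periods_h = periods_h, Qp = Qp, sig_line = sig_line,
              peak_period_h = peak, power = power, width_h = width_h,
              rhythmic = power >= power_min && width_h >= width_min_h &&
                peak >= period_range[1L] && peak <= period_range[2L],
              all_zero = FALSE)
  class(res) <- "periodogram_result"
  res
}

#' @export
print.periodogram_result <- function(x, ...) {
  if (x$all_zero) {
    cat("<periodogram_result> all-zero record, not rhythmic\n")
  } else {
    cat(sprintf(
      "<periodogram_result> peak %.2f h, power %.1f, width %.2f h -> %s\n",
      x$peak_period_h, x$power, x$width_h,
      if (x$rhythmic) "rhythmic" else "not rhythmic"))
  }
  invisible(x)
}

#' Score fly sleep with the 5-min inactivity rule
#'
#' Any maximal run of zero activity lasting `min_run` (default 5)
#' minutes or more is sleep; every minute of such a run counts,
#' including the first five. Sleep minutes are summed into 60-min bins
#' (runs spanning a bin boundary contribute their minutes to each bin),
#' and per-day totals computed.
#'
#' @param rec An [activity_record()] at 1-min resolution.
#' @param min_run Minimum inactivity run length in minutes.
#' @return A list of class `sleep_profile`: `fly_id`, `bin_start_h`,
#'   `sleep_min` (per 60-min bin, in `[0, 60]`), `daily_total_min`,
#'   `sleep_minutes` (per-minute logical), `dead` (filled by
#'   [remove_dead()], `NA` until then).
#' @export
score_sleep <- function(rec, min_run = 5L) {
  stopifnot(inherits(rec, "activity_record"))
  z <- rec$counts == 0L
  r <- rle(z)
  r$values <- r$values & r$lengths >= min_run
  asleep <- inverse.rle(r)
  n <- length(asleep)
  nb <- ceiling(n / 60)
  bin <- rep(seq_len(nb), each = 60L)[seq_len(n)]
  sleep_min <- as.numeric(tapply(asleep, bin, sum))
  day <- rep(seq_len(ceiling(n / 1440)), each = 1440L)[seq_len(n)]
  daily <- as.numeric(tapply(asleep, day, sum))
  structure(list(fly_id = rec$fly_id, bin_start_h = (seq_len(nb) - 1L),
                 sleep_min = sleep_min, daily_total_min = daily,
                 sleep_minutes = asleep, dead = NA),
            class = "sleep_profile")
}

#' Remove dead flies
#'
#' A fly is considered dead when its record ends with an unbroken run of
#' zero activity spanning at least `tail_zero_h` hours (an automated
#' stand-in for manual curation of flies that died mid-experiment and
#' would otherwise over-count sleep).
#'
#' @param records List of [activity_record()] objects.
#' @param tail_zero_h Terminal-silence threshold, hours (`Inf` removes
#'   nothing).
#' @return List with `kept` and `removed` (both lists of records), plus
#'   `dead` (logical vector in input order).
#' @export
remove_dead <- function(records, tail_zero_h = 24) {
  stopifnot(is.list(records))
  dead <- vapply(records, function(rec) {
    if (!is.finite(tail_zero_h)) return(FALSE)
    z <- rec$counts == 0L
    if (!z[length(z)]) return(FALSE)
    r <- rle(z)
    tail_run <- r$lengths[length(r$lengths)]
    tail_run >= tail_zero_h * 60
  }, logical(1L))
  list(kept = records[!dead], removed = records[dead], dead = dead)
}

#' Per-bin and per-day sleep comparisons between two groups
#'
#' Wilcoxon rank-sum tests on per-fly sleep minutes in each 60-min bin
#' and on per-fly daily totals (sleep distributions are non-normal, with
#' floor and ceiling effects). A bin or day is significant when p <
#' `alpha` (default 0.01). Bins where every fly in both groups has the
#' identical value are degenerate and get `p = NA`.
#'
#' @param ctrl_profiles,test_profiles Lists of [score_sleep()] profiles.
#' @param alpha Significance level.
#' @return List with data.frames `bins` (`bin_start_h`, `median_ctrl`,
#'   `median_test`, `median_diff`, `p`, `significant`) and `days`
#'   (same per day).
#' @export
compare_sleep <- function(ctrl_profiles, test_profiles, alpha = 0.01) {
  stopifnot(length(ctrl_profiles) >= 2L, length(test_profiles) >= 2L)
  bin_mat <- function(profiles, field) {
    nb <- length(ctrl_profiles[[1L]][[field]])
    matrix(vapply(profiles, function(p) p[[field]], numeric(nb)),
           nrow = nb)
  }
  test_one <- function(a, b) {
    if (length(unique(c(a, b))) == 1L) return(NA_real_)
    stats::wilcox.test(a, b, exact = FALSE)$p.value
  }
  run <- function(field, label) {
    A <- bin_mat(ctrl_profiles, field)
    B <- bin_mat(test_profiles, field)
    p <- vapply(seq_len(nrow(A)), function(i) test_one(A[i, ], B[i, ]),
                numeric(1L))
    data.frame(
      idx = seq_len(nrow(A)) - 1L,
      median_ctrl = apply(A, 1L, stats::median),
      median_test = apply(B, 1L, stats::median),
      median_diff = apply(B, 1L, stats::median) -
        apply(A, 1L, stats::median),
      p = p,
      significant = !is.na(p) & p < alpha)
  }
  bins <- run("sleep_min", "bin")
  names(bins)[1L] <- "bin_start_h"
  days <- run("daily_total_min", "day")
  names(days)[1L] <- "day"
  list(bins = bins, days = days, alpha = alpha)
}

#' Double-plotted actogram matrix
#'
#' Rows of 48 h (day `d` concatenated with day `d + 1`), per-fly
#' max-normalized to `[0, 1]` at 1-min resolution.
#'
#' @param rec An [activity_record()] spanning at least 2 days.
#' @param double_plot If `FALSE`, returns single-plotted 24-h rows.
#' @return Numeric matrix (`n_days - 1` rows x 2880 columns when
#'   double-plotted).
#' @export
actogram_matrix <- function(rec, double_plot = TRUE) {
  stopifnot(inherits(rec, "activity_record"))
  n_days <- length(rec$counts) %/% 1440L
  if (n_days < 2L) stop("need at least 2 full days")
  x <- rec$counts[seq_len(n_days * 1440L)]
  mx <- max(x)
  if (mx > 0) x <- x / mx
  daymat <- matrix(x, nrow = n_days, ncol = 1440L, byrow = TRUE)
  if (!double_plot) return(daymat)
  cbind(daymat[-n_days, , drop = FALSE], daymat[-1L, , drop = FALSE])
}
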