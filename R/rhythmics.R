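#' Wavelet detrending of a bioluminescence trace
#'
#' Decomposes a trace with a translation-invariant wavelet transform
#' ([modwt_mra()]) and keeps as the circadian-band signal the sum of the
#' detail levels whose nominal period band lies within `band` (levels 4
#' and 5 at the standard 0.75-h cadence, i.e. 12-48 h); the trend and
#' sub-circadian components are discarded and the result is centered.
#' The noise floor `sigma_noise` is the SD of the finest detail level
#' (periods of about 1.5-3 h at this cadence, entirely below 4 h).
#' Gaps (`NA` samples) are filled by linear interpolation and logged in
#' `gap_mask`.
#'
#' @param trace A `cell_trace` (uniform grid, at least 2 days).
#' @param band Circadian period band in hours, default `c(12, 48)`.
#' @param trim_h Hours to drop from the start of the record before
#'   analysis; the pipeline applies the standard 12-h culture-transient
#'   trim via [trim_initial()] beforehand, so the default here is 0.
#' @return An object of class `detrended_trace`: `t`, `x` (detrended,
#'   photons/min), `sigma_noise`, `band`, `gap_mask`, plus the trace's
#'   labels.
#' @export
dwt_detrend <- function(trace, band = c(12, 48), trim_h = 0) {
  stopifnot(inherits(trace, "cell_trace"))
  keep <- trace$t >= trace$t[1L] + trim_h
  t <- trace$t[keep]; y <- trace$y[keep]
  if (length(t) < 2L) stop("record too short after trimming")
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6) stop("non-uniform sampling")
  dt <- dt[1L]
  if ((t[length(t)] - t[1L]) < 48 - 1e-9)
    stop("record must span at least 2 days")
  gap_mask <- is.na(y)
  if (all(gap_mask)) stop("record is entirely missing")
  if (any(gap_mask))
    y <- stats::approx(t[!gap_mask], y[!gap_mask], xout = t,
                       rule = 2)$y
  # detail level j spans periods [2^j dt, 2^(j+1) dt]
  levels_all <- seq_len(max(5L, ceiling(log2(band[2L] / dt))))
  lo <- 2^levels_all * dt
  hi <- 2^(levels_all + 1L) * dt
  circ_levels <- levels_all[lo >= band[1L] - 1e-9 & hi <= band[2L] + 1e-9]
  if (length(circ_levels) == 0L)
    stop("no wavelet level falls inside the requested band")
  noise_levels <- levels_all[hi <= 4 + 1e-9]
  J <- max(circ_levels)
  mra <- modwt_mra(y, J)
  x <- rowSums(mra$details[, circ_levels, drop = FALSE])
  x <- x - mean(x)
  sigma_noise <- if (length(noise_levels))
    stats::sd(rowSums(mra$details[, noise_levels, drop = FALSE]))
  else 0
  structure(list(t = t, x = x, sigma_noise = sigma_noise, band = band,
                 gap_mask = gap_mask, cell_id = trace$cell_id,
                 brain_id = trace$brain_id, subgroup = trace$subgroup,
                 reporter = trace$reporter),
            class = "detrended_trace")
}

#' Construct a detrended trace directly
#'
#' Wraps an already-detrended (zero-mean, circadian-band) series in the
#' container produced by [dwt_detrend()], for externally detrended data
#' and controlled test inputs.
#'
#' @param t Uniform time grid, hours.
#' @param x Detrended signal.
#' @param sigma_noise Noise floor (SD of the sub-4-h component).
#' @param band Nominal period band, hours.
#' @param cell_id,brain_id,subgroup,reporter Labels.
#' @return A `detrended_trace`.
#' @export
as_detrended_trace <- function(t, x, sigma_noise = 0, band = c(12, 48),
                               cell_id = "cell1", brain_id = "brain1",
                               subgroup = "s-LNv", reporter = "PER") {
  stopifnot(length(t) == length(x), length(t) >= 2L)
  structure(list(t = as.numeric(t), x = as.numeric(x),
                 sigma_noise = sigma_noise, band = band,
                 gap_mask = rep(FALSE, length(t)), cell_id = cell_id,
                 brain_id = brain_id, subgroup = subgroup,
                 reporter = reporter),
            class = "detrended_trace")
}

#' @export
print.detrended_trace <- function(x, ...) {
  cat(sprintf(
    "<detrended_trace> %s/%s, %d samples, band %g-%g h, sigma_noise %.3g\n",
    x$brain_id, x$cell_id, length(x$t), x$band[1L], x$band[2L],
    x$sigma_noise))
  invisible(x)
}

#' Sliding-window sine fits
#'
#' Least-squares fit of \eqn{x(t) \approx \hat A \cos(2\pi (t -
#' \hat\phi)/\hat\tau)} in 2-d sliding windows over a detrended trace.
#' The period is searched on a grid over `period_range` (step
#' `grid_step`, ties broken toward 24 h) and refined by local
#' optimization; amplitude and phase are solved in closed form per
#' candidate period. The goodness of sine fit `gof` is the Pearson
#' correlation between the fitted sinusoid and the data in the window.
#' Windows with more than `max_missing` missing samples are skipped and
#' flagged; a degenerate (flat) window reports `gof = 0` with a flag.
#'
#' @param d A `detrended_trace`.
#' @param window_h Window length, hours (default 48).
#' @param step_h Window step, hours (default 6).
#' @param period_range Period search range, hours.
#' @param grid_step Period grid step, hours (<= 0.1).
#' @param max_missing Maximum tolerated fraction of missing samples per
#'   window.
#' @return A data.frame of class `sine_fit_windows`: `midpoint_h`,
#'   `period_h`, `amplitude`, `phase_h` (time of waveform peak relative
#'   to window start, in `[0, period_h)`), `phase_rad`, `gof`, `skipped`,
#'   `degenerate`.
#' @export
sine_fit_windows <- function(d, window_h = 48, step_h = 6,
                             period_range = c(16, 32), grid_step = 0.1,
                             max_missing = 0.25) {
  stopifnot(inherits(d, "detrended_trace"))
  t <- d$t; x <- d$x
  if (t[length(t)] - t[1L] < window_h - 1e-9)
    stop("window does not fit inside the record")
  starts <- seq(t[1L], t[length(t)] - window_h + 1e-9, by = step_h)
  taus <- seq(period_range[1L], period_range[2L], by = grid_step)
  rows <- lapply(starts, function(t0) {
    sel <- which(t >= t0 - 1e-9 & t < t0 + window_h - 1e-9)
    miss <- d$gap_mask[sel]
    base <- data.frame(midpoint_h = t0 + window_h / 2,
                       period_h = NA_real_, amplitude = NA_real_,
                       phase_h = NA_real_, phase_rad = NA_real_,
                       gof = NA_real_, skipped = FALSE, degenerate = FALSE)
    if (mean(miss) > max_missing) {
      base$skipped <- TRUE
      return(base)
    }
    tw <- t[sel] - t0
    xw <- x[sel]
    if (stats::sd(xw) < 1e-12) {
      base$period_h <- 24; base$amplitude <- 0
      base$phase_h <- 0; base$phase_rad <- 0
      base$gof <- 0; base$degenerate <- TRUE
      return(base)
    }
    sse_for <- function(tau) {
      w <- 2 * pi / tau
      cw <- cos(w * tw); sw <- sin(w * tw)
      cc <- sum(cw * cw); ss <- sum(sw * sw); cs <- sum(cw * sw)
      xc <- sum(xw * cw); xs <- sum(xw * sw)
      det <- cc * ss - cs * cs
      if (abs(det) < 1e-12) return(list(sse = sum(xw^2), a = 0, b = 0))
      a <- (xc * ss - xs * cs) / det
      b <- (xs * cc - xc * cs) / det
      list(sse = sum(xw^2) - (a * xc + b * xs), a = a, b = b)
    }
    sse <- vapply(taus, function(tau) sse_for(tau)$sse, numeric(1L))
    best <- which(sse <= min(sse) + 1e-12)
    tau0 <- taus[best[which.min(abs(taus[best] - 24))]]
    opt <- stats::optimize(function(tau) sse_for(tau)$sse,
                           lower = max(period_range[1L], tau0 - grid_step),
                           upper = min(period_range[2L], tau0 + grid_step))
    tau_hat <- opt$minimum
    fit <- sse_for(tau_hat)
    w <- 2 * pi / tau_hat
    amp <- sqrt(fit$a^2 + fit$b^2)
    phase_h <- (atan2(fit$b, fit$a) / w) %% tau_hat
    fitted <- fit$a * cos(w * tw) + fit$b * sin(w * tw)
    gof <- if (stats::sd(fitted) < 1e-12) 0 else stats::cor(fitted, xw)
    base$period_h <- tau_hat; base$amplitude <- amp
    base$phase_h <- phase_h
    base$phase_rad <- 2 * pi * phase_h / tau_hat
    base$gof <- gof
    base$degenerate <- stats::sd(fitted) < 1e-12
    base
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sine_fit_windows", class(out))
  attr(out, "cell_id") <- d$cell_id
  attr(out, "subgroup") <- d$subgroup
  attr(out, "window_h") <- window_h
  out
}

#' Reliably-rhythmic classification
#'
#' A window is reliably rhythmic when its fitted period lies in
#' `period_range` (24 +/- 8 h, inclusive), its amplitude rises strictly
#' above the baseline noise value `sigma_noise` (the SD of the sub-4-h
#' wavelet component), and its goodness of sine fit is at least
#' `gof_min` (0.82). Skipped windows are never rhythmic.
#'
#' @param fits A [sine_fit_windows()] table.
#' @param sigma_noise Noise floor from [dwt_detrend()].
#' @param period_range Inclusive period bounds, hours.
#' @param gof_min Minimum goodness of sine fit (inclusive).
#' @return The input with columns `reliably_rhythmic` (logical) and
#'   `failed_criteria` (comma-separated subset of `period_range`,
#'   `amplitude_floor`, `gof`; empty when rhythmic).
#' @export
classify_rhythmic <- function(fits, sigma_noise, period_range = c(16, 32),
                              gof_min = 0.82) {
  stopifnot(nrow(fits) >= 1L)
  fail_period <- is.na(fits$period_h) | fits$period_h < period_range[1L] |
    fits$period_h > period_range[2L]
  fail_amp <- is.na(fits$amplitude) | !(fits$amplitude > sigma_noise)
  fail_gof <- is.na(fits$gof) | fits$gof < gof_min
  failed <- mapply(function(p, a, g) {
    paste(c(if (p) "period_range", if (a) "amplitude_floor",
            if (g) "gof"), collapse = ",")
  }, fail_period, fail_amp, fail_gof)
  fits$reliably_rhythmic <- !nzchar(failed)
  fits$failed_criteria <- failed
  fits
}

#' Lomb-Scargle rhythmicity on trace segments
#'
#' Computes the variance-normalized Lomb-Scargle periodogram over
#' periods in `period_range` on consecutive `segment_days`-long segments
#' of a detrended trace. A segment is rhythmic when the false-alarm
#' probability of its peak power, `1 - (1 - exp(-z))^M` with `M`
#' independent frequencies spanned by the searched band, falls below
#' `alpha`. A cell is called rhythmic when at least half of its segments
#' are.
#'
#' @param x A `detrended_trace` or a `cell_trace` (detrended
#'   internally), or a list of either (for `percent_rhythmic`).
#' @param segment_days Segment length in days (default 4).
#' @param alpha False-alarm threshold.
#' @param period_range Periods searched, hours.
#' @return `lomb_scargle_rhythmic()`: a data.frame with one row per
#'   segment (`segment`, `peak_period_h`, `power`, `fap`, `rhythmic`)
#'   plus attribute `cell_rhythmic`. `percent_rhythmic()`: percentage of
#'   rhythmic cells in a list.
#' @export
lomb_scargle_rhythmic <- function(x, segment_days = 4, alpha = 0.05,
                                  period_range = c(16, 32)) {
  if (inherits(x, "cell_trace")) x <- dwt_detrend(x)
  stopifnot(inherits(x, "detrended_trace"))
  t <- x$t; v <- x$x
  seg_h <- segment_days * 24
  dt <- t[2L] - t[1L]
  span <- t[length(t)] - t[1L] + dt      # coverage in whole samples
  if (span < seg_h - 1e-9)
    stop("segment does not fit in record")
  n_seg <- floor(span / seg_h + 1e-9)
  rows <- lapply(seq_len(n_seg), function(s) {
    sel <- t >= t[1L] + (s - 1) * seg_h - 1e-9 & t < t[1L] + s * seg_h - 1e-9
    ts <- t[sel]; xs <- v[sel]
    Tspan <- max(ts) - min(ts)
    if (stats::sd(xs) < 1e-12)
      return(data.frame(segment = s, peak_period_h = NA_real_, power = 0,
                        fap = 1, rhythmic = FALSE))
    freqs <- seq(1 / period_range[2L], 1 / period_range[1L],
                 by = 1 / (2 * Tspan))
    pw <- ls_power(ts, xs, freqs)
    z <- max(pw)
    M <- max(1, round(Tspan * (1 / period_range[1L] - 1 / period_range[2L])))
    fap <- 1 - (1 - exp(-z))^M
    data.frame(segment = s, peak_period_h = 1 / freqs[which.max(pw)],
               power = z, fap = fap, rhythmic = fap < alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "cell_rhythmic") <- mean(out$rhythmic) >= 0.5
  out
}

# classical Lomb-Scargle normalized power at given frequencies (1/h)
ls_power <- function(t, x, freqs) {
  x <- x - mean(x)
  s2 <- stats::var(x)
  vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2)) / (2 * s2)
  }, numeric(1L))
}

#' @rdname lomb_scargle_rhythmic
#' @export
percent_rhythmic <- function(x, segment_days = 4, alpha = 0.05,
                             period_range = c(16, 32)) {
  stopifnot(is.list(x), length(x) >= 1L)
  calls <- vapply(x, function(tr)
    attr(lomb_scargle_rhythmic(tr, segment_days, alpha, period_range),
         "cell_rhythmic"), logical(1L))
  100 * mean(calls)
}

#' Time-delay-embedded phase estimates
#'
#' Embeds a detrended trace in two dimensions via a `lag_h` lag
#' (a quarter period for a circa-24-h oscillation), so that the
#' trajectory `(x(t), x(t - lag))`, after centering each coordinate by a
#' 24-h running mean, circles the origin. The phase is the unwrapped
#' polar angle (zero at the waveform peak, increasing with time); the
#' amplitude is the radius smoothed over 3 h. Samples whose radius falls
#' below the trace's noise floor are flagged invalid.
#'
#' @param d A `detrended_trace`.
#' @param lag_h Embedding lag in hours (rounded to the nearest sample
#'   with a warning if not a multiple of the cadence).
#' @return A data.frame with `t_h`, `phase_rad` (unwrapped),
#'   `amplitude`, `valid`.
#' @export
embed_phase <- function(d, lag_h = 6) {
  stopifnot(inherits(d, "detrended_trace"))
  dt <- d$t[2L] - d$t[1L]
  if (d$t[length(d$t)] - d$t[1L] < lag_h + 24)
    stop("record must span at least the lag plus one day")
  lag_n <- round(lag_h / dt)
  if (abs(lag_n * dt - lag_h) > 1e-9)
    warning("lag is not a multiple of the sampling interval; using ",
            lag_n * dt, " h")
  n <- length(d$x)
  idx <- (lag_n + 1L):n
  x1 <- d$x[idx]
  x2 <- d$x[idx - lag_n]
  win <- max(1L, round(24 / dt))
  x1c <- x1 - running_mean(x1, win)
  x2c <- x2 - running_mean(x2, win)
  ang <- atan2(x2c, x1c)
  phase <- unwrap_phase(ang)
  rad <- sqrt(x1c^2 + x2c^2)
  amp <- running_mean(rad, max(1L, round(3 / dt)))
  data.frame(t_h = d$t[idx], phase_rad = phase, amplitude = amp,
             valid = rad >= d$sigma_noise)
}

# centered running mean with edge shrinkage
running_mean <- function(x, win) {
  n <- length(x)
  if (win <= 1L || n == 1L) return(if (win >= n) rep(mean(x), n) else x)
  half <- win %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# unwrap angles to a continuous phase
unwrap_phase <- function(a) {
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(a[1L], d))
}

#' Write a per-window fit table to CSV
#'
#' @param fits_list Named list (by cell) of classified
#'   [sine_fit_windows()] tables.
#' @param path File path.
#' @export
write_fits_csv <- function(fits_list, path) {
  df <- do.call(rbind, lapply(names(fits_list), function(id) {
    f <- fits_list[[id]]
    data.frame(cell_id = id, midpoint_h = f$midpoint_h,
               period_h = f$period_h, amplitude = f$amplitude,
               phase_h = f$phase_h, gof = f$gof,
               rhythmic = if ("reliably_rhythmic" %in% names(f))
                 f$reliably_rhythmic else NA,
               failed_criteria = if ("failed_criteria" %in% names(f))
                 f$failed_criteria else "",
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
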