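#' Waveform-based order parameter R
#'
#' Quantifies the synchrony of phase, period and waveform of an
#' oscillator ensemble on 24-h segments bounded by the control
#' schedule's lights-on times. On each segment,
#' \deqn{R = \mathrm{Var}_t\!\big(\textstyle\frac1N\sum_i \tilde
#'   x_i(t)\big) \,/\, \textstyle\frac1N\sum_i \mathrm{Var}_t(\tilde
#'   x_i(t))}
#' over the detrended traces \eqn{\tilde x_i}: identical traces give
#' R = 1, independent noise gives R near 1/N, perfect cancellation
#' gives 0. No cell is discarded; cells with zero variance within a
#' segment are dropped from that segment's denominator with a warning.
#' Segments with fewer than 2 usable cells are reported missing.
#'
#' @param cells List of `detrended_trace` objects on a common grid.
#' @param lights_on Lights-on boundaries: a numeric vector of hours or a
#'   [lights_on_times()] data.frame. Under a shifted (weekend light
#'   shift) arm, pass the control schedule's boundaries.
#' @param roll_days Rolling step in days between consecutive segments
#'   (default 1; a finer slide can be had by passing fractional values).
#' @return A data.frame of class `synchrony_series`: `day` (0-based
#'   index of the segment's lights-on boundary), `mid_h` (segment
#'   midpoint), `R`, `n_cells` (cells entering the denominator).
#' @export
order_parameter <- function(cells, lights_on, roll_days = 1) {
  stopifnot(is.list(cells), length(cells) >= 2L)
  if (is.data.frame(lights_on)) lights_on <- lights_on$lights_on_h
  t <- cells[[1L]]$t
  for (d in cells)
    if (!isTRUE(all.equal(d$t, t)))
      stop("all traces must share one time grid")
  X <- vapply(cells, function(d) d$x, numeric(length(t)))  # time x cells
  bounds <- seq(lights_on[1L], max(lights_on), by = 24 * roll_days)
  rows <- lapply(seq_along(bounds), function(i) {
    on_d <- bounds[i]
    sel <- t >= on_d - 1e-9 & t < on_d + 24 - 1e-9
    out <- data.frame(day = (on_d - lights_on[1L]) / 24,
                      mid_h = on_d + 12, R = NA_real_, n_cells = 0L)
    if (sum(sel) < 2L || t[1L] > on_d + 1e-9 ||
        t[length(t)] < on_d + 24 - (t[2L] - t[1L]) - 1e-9)
      return(out)
    out$R <- segment_r(X[sel, , drop = FALSE])
    out$n_cells <- attr(out$R, "n_used") %||% ncol(X)
    out$R <- as.numeric(out$R)
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("synchrony_series", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# R on one segment: columns are cells
segment_r <- function(Xseg, warn = TRUE) {
  v <- apply(Xseg, 2L, stats::var)
  usable <- v > 0
  if (!all(usable) && warn)
    warning(sum(!usable), " zero-variance cell(s) excluded from a segment")
  if (sum(usable) < 2L) return(structure(NA_real_, n_used = sum(usable)))
  r <- stats::var(rowMeans(Xseg[, usable, drop = FALSE])) / mean(v[usable])
  structure(min(max(r, 0), 1), n_used = sum(usable))
}

#' Randomization confidence bands for a group difference in R
#'
#' Tests per-day differences in the order parameter between two arms
#' (e.g. weekend-light-shift vs control) with the randomization scheme
#' of the source analysis: cells from both conditions are pooled, two
#' disjoint subsets of size `n_subset` (the smallest cluster size) are
#' drawn uniformly, and their per-day R difference computed;
#' `n_rand` replicates give empirical 95% and 99% bands under the null
#' hypothesis of no group difference. The observed difference
#' `R_test - R_ref` falling outside a band marks that day significant.
#'
#' @param ref,test Lists of `detrended_trace` objects (reference arm,
#'   e.g. control, and test arm, e.g. WLS), common grid.
#' @param lights_on Control-schedule lights-on boundaries (vector of
#'   hours or [lights_on_times()] output).
#' @param n_rand Number of randomization replicates (5000 in the source
#'   analysis).
#' @param seed Integer seed, recorded in the output.
#' @param roll_days Segment step, as in [order_parameter()].
#' @return A data.frame of class `randomization_result`: `day`, `mid_h`,
#'   `dR` (observed), `lo95`, `hi95`, `lo99`, `hi99`, `sig95`, `sig99`;
#'   attributes `n_rand`, `n_subset`, `seed`.
#' @export
delta_r_bands <- function(ref, test, lights_on, n_rand = 5000, seed = 1L,
                          roll_days = 1) {
  if (length(ref) < 2L || length(test) < 2L)
    stop("both groups need at least 2 cells")
  if (is.data.frame(lights_on)) lights_on <- lights_on$lights_on_h
  pool <- c(ref, test)
  n_subset <- min(length(ref), length(test))
  if (length(pool) < 2L * n_subset)
    stop("pooled cells fewer than twice the subset size")
  t <- pool[[1L]]$t
  for (d in pool)
    if (!isTRUE(all.equal(d$t, t)))
      stop("all traces must share one time grid")
  X <- vapply(pool, function(d) d$x, numeric(length(t)))
  bounds <- seq(lights_on[1L], max(lights_on), by = 24 * roll_days)
  dt <- t[2L] - t[1L]
  seg_ok <- vapply(bounds, function(on_d)
    t[1L] <= on_d + 1e-9 && t[length(t)] >= on_d + 24 - dt - 1e-9 &&
      sum(t >= on_d - 1e-9 & t < on_d + 24 - 1e-9) >= 2L, logical(1L))
  segs <- lapply(bounds[seg_ok], function(on_d)
    which(t >= on_d - 1e-9 & t < on_d + 24 - 1e-9))

  r_groups <- function(idx_a, idx_b) {
    vapply(segs, function(sel) {
      c(as.numeric(segment_r(X[sel, idx_a, drop = FALSE], warn = FALSE)),
        as.numeric(segment_r(X[sel, idx_b, drop = FALSE], warn = FALSE)))
    }, numeric(2L))
  }
  obs <- r_groups(length(ref) + seq_along(test), seq_along(ref))
  dR_obs <- obs[1L, ] - obs[2L, ]

  set.seed(seed)
  null_d <- matrix(NA_real_, n_rand, length(segs))
  for (r in seq_len(n_rand)) {
    pick <- sample.int(ncol(X), 2L * n_subset)
    rr <- r_groups(pick[seq_len(n_subset)],
                   pick[n_subset + seq_len(n_subset)])
    null_d[r, ] <- rr[1L, ] - rr[2L, ]
  }
  qs <- apply(null_d, 2L, stats::quantile,
              probs = c(0.025, 0.975, 0.005, 0.995), na.rm = TRUE,
              names = FALSE)
  out <- data.frame(
    day = (bounds[seg_ok] - lights_on[1L]) / 24,
    mid_h = bounds[seg_ok] + 12,
    dR = dR_obs,
    lo95 = qs[1L, ], hi95 = qs[2L, ], lo99 = qs[3L, ], hi99 = qs[4L, ])
  out$sig95 <- !is.na(out$dR) & (out$dR < out$lo95 | out$dR > out$hi95)
  out$sig99 <- !is.na(out$dR) & (out$dR < out$lo99 | out$dR > out$hi99)
  structure(out, n_rand = n_rand, n_subset = n_subset, seed = seed,
            class = c("randomization_result", class(out)))
}

#' Circular phase statistics per sliding window
#'
#' Summarizes the peak phases of reliably rhythmic cells at each
#' sine-fit window midpoint: phases are expressed in Zeitgeber time
#' standardized so that ZT0 equals `reference` (conventionally the
#' overall mean phase of all control cells on day 3, when entrainment is
#' most stable; see [reference_phase()]), mapped to angles
#' `2 pi (phi - reference) / 24`, and reduced to the circular mean
#' direction, resultant length rho, and the Rayleigh test p-value (the
#' standard series approximation with `z = n rho^2`). Windows with no
#' qualifying cell are omitted, not reported as zero.
#'
#' @param fits_list List (one element per cell) of classified
#'   [sine_fit_windows()] tables (after [classify_rhythmic()]).
#' @param reference Reference phase in clock hours defining ZT0.
#' @param alpha Rayleigh significance level used for the plotting
#'   threshold radius `sqrt(-log(alpha)/n)`.
#' @return A data.frame of class `circular_phase_summary`: `midpoint_h`,
#'   `n`, `mean_zt_h`, `rho`, `rayleigh_p`, `alpha_radius`.
#' @export
circular_summary <- function(fits_list, reference = 0, alpha = 0.05) {
  stopifnot(length(fits_list) >= 1L)
  all_fits <- do.call(rbind, lapply(fits_list, function(f) {
    if (!"reliably_rhythmic" %in% names(f))
      stop("run classify_rhythmic() first")
    f
  }))
  keep <- all_fits$reliably_rhythmic & !is.na(all_fits$phase_h)
  all_fits <- all_fits[keep, , drop = FALSE]
  if (nrow(all_fits) == 0L)
    return(structure(data.frame(midpoint_h = numeric(0), n = integer(0),
                                mean_zt_h = numeric(0), rho = numeric(0),
                                rayleigh_p = numeric(0),
                                alpha_radius = numeric(0)),
                     class = c("circular_phase_summary", "data.frame")))
  peak_clock <- (all_fits$midpoint_h - attr_window(all_fits) / 2 +
                   all_fits$phase_h) %% 24
  theta <- 2 * pi * (peak_clock - reference) / 24
  mids <- sort(unique(all_fits$midpoint_h))
  rows <- lapply(mids, function(m) {
    th <- theta[all_fits$midpoint_h == m]
    n <- length(th)
    C <- mean(cos(th)); S <- mean(sin(th))
    rho <- sqrt(C^2 + S^2)
    mu <- atan2(S, C)
    data.frame(midpoint_h = m, n = n,
               mean_zt_h = (mu * 24 / (2 * pi)) %% 24, rho = rho,
               rayleigh_p = rayleigh_p(n, rho),
               alpha_radius = sqrt(-log(alpha) / n))
  })
  structure(do.call(rbind, rows),
            class = c("circular_phase_summary", "data.frame"))
}

attr_window <- function(fits) {
  w <- attr(fits, "window_h")
  if (is.null(w)) 48 else w
}

#' Rayleigh test p-value
#'
#' Series approximation `exp(-z) (1 + (2z - z^2)/(4n) - (24z - 132z^2 +
#' 76z^3 - 9z^4)/(288 n^2))` with `z = n rho^2`, clamped to `[0, 1]`.
#'
#' @param n Number of angles.
#' @param rho Resultant vector length.
#' @return The p-value for the null of circular uniformity.
#' @export
rayleigh_p <- function(n, rho) {
  z <- n * rho^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) /
                      (288 * n^2))
  min(max(p, 0), 1)
}

#' Compute the ZT0 reference phase from control-arm fits
#'
#' The overall circular mean peak phase (clock hours mod 24) of all
#' control cells' reliably rhythmic windows whose midpoint falls on the
#' given day.
#'
#' @param fits_list List of classified [sine_fit_windows()] tables for
#'   the control arm.
#' @param day 0-based day index (default 3).
#' @return Reference phase in clock hours.
#' @export
reference_phase <- function(fits_list, day = 3) {
  all_fits <- do.call(rbind, fits_list)
  keep <- all_fits$reliably_rhythmic & !is.na(all_fits$phase_h) &
    all_fits$midpoint_h >= 24 * day & all_fits$midpoint_h < 24 * (day + 1)
  f <- all_fits[keep, , drop = FALSE]
  if (nrow(f) == 0L) stop("no reliably rhythmic windows on that day")
  peak_clock <- (f$midpoint_h - attr_window(all_fits) / 2 + f$phase_h) %% 24
  th <- 2 * pi * peak_clock / 24
  (atan2(mean(sin(th)), mean(cos(th))) * 24 / (2 * pi)) %% 24
}

#' Export a phase-ensemble table
#'
#' Long-format table of per-cell relative phase and normalized amplitude
#' over time, sufficient to re-render phase-ensemble disk animations
#' (each cell a disk whose polar angle is its phase relative to the
#' reference-group mean and whose radius tracks normalized amplitude).
#' No rendering is performed.
#'
#' @param embeds Named list (by cell id) of [embed_phase()] outputs.
#' @param groups Named character vector mapping cell ids to group
#'   labels.
#' @param reference_group Group whose circular mean phase defines the
#'   zero angle at each time (default the first group).
#' @return data.frame `t_h`, `cell_id`, `group`, `rel_phase_rad`
#'   (wrapped to `(-pi, pi]`), `radius` (amplitude / per-cell max, in
#'   `[0, 1]`).
#' @export
phase_ensemble_export <- function(embeds, groups,
                                  reference_group = NULL) {
  stopifnot(length(embeds) >= 1L, !is.null(names(embeds)),
            all(names(embeds) %in% names(groups)))
  if (is.null(reference_group)) reference_group <- groups[[1L]]
  t_h <- embeds[[1L]]$t_h
  for (e in embeds)
    if (!isTRUE(all.equal(e$t_h, t_h)))
      stop("all embeddings must share one time grid")
  ph <- vapply(embeds, function(e) e$phase_rad, numeric(length(t_h)))
  ref_cells <- names(embeds)[groups[names(embeds)] == reference_group]
  if (length(ref_cells) == 0L) stop("reference group has no cells")
  refm <- atan2(rowMeans(sin(ph[, ref_cells, drop = FALSE])),
                rowMeans(cos(ph[, ref_cells, drop = FALSE])))
  rows <- lapply(names(embeds), function(id) {
    e <- embeds[[id]]
    rel <- (e$phase_rad - refm + pi) %% (2 * pi) - pi
    amax <- max(e$amplitude)
    data.frame(t_h = t_h, cell_id = id, group = unname(groups[id]),
               rel_phase_rad = rel,
               radius = if (amax > 0) e$amplitude / amax else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
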