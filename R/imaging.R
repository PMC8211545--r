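#' Cosmic-ray frame rejection
#'
#' Emulates the acquisition-time cosmic-ray filter: for every frame the
#' statistic S = sum of the pixel values that exceed `pixel_threshold`
#' is computed, and a frame is rejected when its S exceeds the running
#' mean by more than `sd_mult` standard deviations, both taken over the
#' trailing `window` previously accepted frames. The first `window`
#' frames are a warm-up and are never rejected. With `statistic =
#' "total_sum"` the alternative reading (reject on the total pixel sum
#' exceeding the threshold rule) is used: S = total sum of all pixels,
#' with `pixel_threshold` ignored.
#'
#' @param stack A `frame_stack`.
#' @param pixel_threshold Per-pixel intensity threshold (default 800).
#' @param sd_mult Rejection multiple of the running SD (default 3).
#' @param window Trailing window length in accepted frames (default 30).
#' @param statistic `"sum_above_threshold"` (default) or `"total_sum"`.
#' @return List with `stack` (accepted frames) and `rejected` (integer
#'   indices into the input stack).
#' @export
filter_cosmic_rays <- function(stack, pixel_threshold = 800, sd_mult = 3,
                               window = 30L,
                               statistic = c("sum_above_threshold",
                                             "total_sum")) {
  stopifnot(inherits(stack, "frame_stack"), window >= 2L)
  statistic <- match.arg(statistic)
  n <- dim(stack$frames)[3L]
  if (n == 0L) stop("empty stack")
  S <- vapply(seq_len(n), function(f) {
    fr <- stack$frames[, , f]
    if (statistic == "sum_above_threshold")
      sum(fr[fr > pixel_threshold], na.rm = TRUE)
    else sum(fr, na.rm = TRUE)
  }, numeric(1L))
  accepted <- integer(0)
  rejected <- integer(0)
  for (f in seq_len(n)) {
    na <- length(accepted)
    if (na >= window) {
      recent <- S[accepted[(na - window + 1L):na]]
      m <- mean(recent); s <- stats::sd(recent)
      if (S[f] > m + sd_mult * s) {
        rejected <- c(rejected, f)
        next
      }
    }
    accepted <- c(accepted, f)
  }
  list(stack = frame_stack(stack$frames[, , accepted, drop = FALSE],
                           stack$timestamps_h[accepted],
                           stack$exposure_min),
       rejected = rejected)
}

#' Average frames into fixed time bins
#'
#' Frames whose timestamps fall in each half-open bin
#' `[k b, (k+1) b)` (b = `bin_minutes`) are pixelwise averaged; the
#' output timestamp is the bin midpoint. Bins containing no frame (e.g.
#' after cosmic-ray rejection) are emitted as missing all-`NA` frames,
#' flagged, never as zeros.
#'
#' @param stack A `frame_stack`.
#' @param bin_minutes Bin width in minutes (default 45).
#' @return A binned `frame_stack` (exposure set to `bin_minutes`).
#' @export
bin_frames <- function(stack, bin_minutes = 45) {
  stopifnot(inherits(stack, "frame_stack"), bin_minutes > 0)
  bh <- bin_minutes / 60
  idx <- floor(stack$timestamps_h / bh + 1e-9)
  bins <- seq(min(idx), max(idx))
  d <- dim(stack$frames)
  out <- array(NA_real_, c(d[1L], d[2L], length(bins)))
  miss <- logical(length(bins))
  for (j in seq_along(bins)) {
    sel <- which(idx == bins[j])
    if (length(sel) == 0L) {
      miss[j] <- TRUE
    } else if (length(sel) == 1L) {
      out[, , j] <- stack$frames[, , sel]
    } else {
      out[, , j] <- apply(stack$frames[, , sel, drop = FALSE], c(1L, 2L),
                          mean)
    }
  }
  frame_stack(out, (bins + 0.5) * bh, exposure_min = bin_minutes,
              missing = miss)
}

#' Running-minimum denoising
#'
#' Replaces each frame by the pixelwise minimum of itself and its
#' successor, removing single-frame transients (residual cosmic rays,
#' hot pixels, dark-current spikes). The output has one frame fewer
#' than the input and keeps the earlier frame's timestamp. Missing
#' frames propagate as missing.
#'
#' @param stack A `frame_stack` with at least 2 frames.
#' @return A `frame_stack` of length `n - 1`.
#' @export
running_minimum <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- dim(stack$frames)[3L]
  if (n < 2L) stop("running minimum needs at least 2 frames")
  out <- pmin(stack$frames[, , -n, drop = FALSE],
              stack$frames[, , -1L, drop = FALSE])
  frame_stack(out, stack$timestamps_h[-n], stack$exposure_min,
              missing = stack$missing[-n] | stack$missing[-1L])
}

#' Extract per-cell traces from a frame stack
#'
#' For every frame, each cell's value is the mean intensity over its ROI
#' minus the mean intensity over the background ROI of that same frame.
#' Because the background varies per frame, values may be negative and
#' are not clipped. Missing frames propagate as `NA`.
#'
#' @param stack A `frame_stack`.
#' @param rois A [roi_set()] valid for the stack's frame shape.
#' @return List of `cell_trace` objects (raw intensity units).
#' @export
extract_traces <- function(stack, rois) {
  stopifnot(inherits(stack, "frame_stack"), inherits(rois, "roi_set"))
  d <- dim(stack$frames)
  tab <- rois$rois
  if (any(tab$row0 < 1L) || any(tab$col0 < 1L) ||
      any(tab$row1 > d[1L]) || any(tab$col1 > d[2L]))
    stop("ROI outside frame bounds")
  roi_mean <- function(r) {
    apply(stack$frames[r$row0:r$row1, r$col0:r$col1, , drop = FALSE],
          3L, function(m) mean(m))
  }
  bg <- roi_mean(tab[tab$label == "background", ])
  cellrows <- which(tab$label != "background")
  lapply(cellrows, function(i) {
    r <- tab[i, ]
    cell_trace(stack$timestamps_h, roi_mean(r) - bg,
               cell_id = r$cell_id, brain_id = r$brain_id,
               subgroup = r$subgroup, units = "raw")
  })
}

#' Convert a raw trace to photons per minute
#'
#' @param trace A `cell_trace` in raw units.
#' @param calibration_scale Photons per raw intensity unit (> 0).
#' @param exposure_min Exposure length in minutes the raw values
#'   integrate over.
#' @return The trace with `y` rescaled to photons/min.
#' @export
to_photons_per_minute <- function(trace, calibration_scale = 1,
                                  exposure_min = 15) {
  stopifnot(inherits(trace, "cell_trace"), calibration_scale > 0)
  cell_trace(trace$t, trace$y * calibration_scale / exposure_min,
             trace$cell_id, trace$brain_id, trace$subgroup, trace$reporter,
             units = "photons/min")
}

#' Run the full image-processing chain
#'
#' Cosmic-ray rejection (acquisition order), 45-min binning, running
#' minimum, ROI extraction with per-frame background subtraction, and
#' photons-per-minute conversion, in the standard order.
#'
#' @param stack A raw `frame_stack`.
#' @param rois A [roi_set()].
#' @inheritParams filter_cosmic_rays
#' @param bin_minutes Bin width, minutes.
#' @param calibration_scale Photon conversion scale.
#' @return List with `traces` (photons/min `cell_trace`s) and
#'   `rejected` frame indices.
#' @export
preprocess_stack <- function(stack, rois, pixel_threshold = 800,
                             sd_mult = 3, window = 30L, bin_minutes = 45,
                             calibration_scale = 1) {
  filt <- filter_cosmic_rays(stack, pixel_threshold, sd_mult, window)
  binned <- bin_frames(filt$stack, bin_minutes)
  rm <- running_minimum(binned)
  traces <- extract_traces(rm, rois)
  traces <- lapply(traces, to_photons_per_minute,
                   calibration_scale = calibration_scale,
                   exposure_min = bin_minutes)
  list(traces = traces, rejected = filt$rejected)
}
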