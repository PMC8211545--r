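#' Bioluminescence frame stacks and ROI sets
#'
#' A `frame_stack` holds ordered 2-D intensity frames of fixed shape
#' (array `rows x cols x n_frames`), their timestamps in hours, and the
#' exposure length. Bins left empty by cosmic-ray rejection are carried
#' as all-`NA` frames flagged in `missing`. Stacks are stored in memory
#' as plain arrays; [write_stack_csv()] / [read_stack_csv()] provide a
#' text serialization (no TIFF reader is available in this R stack).
#'
#' @param frames Numeric array `rows x cols x n` of non-negative
#'   intensities (a list of matrices is also accepted).
#' @param timestamps_h Strictly increasing frame times, hours.
#' @param exposure_min Exposure per frame, minutes.
#' @param missing Logical per-frame flag for empty (all-`NA`) bins.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, timestamps_h, exposure_min = 15,
                        missing = NULL) {
  if (is.list(frames)) frames <- simplify2array(frames)
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  n <- dim(frames)[3L]
  stopifnot(length(timestamps_h) == n, n >= 1L)
  if (n > 1L && any(diff(timestamps_h) <= 0))
    stop("timestamps must be strictly increasing")
  if (is.null(missing)) missing <- apply(is.na(frames), 3L, all)
  structure(list(frames = frames, timestamps_h = as.numeric(timestamps_h),
                 exposure_min = exposure_min, missing = missing),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %dx%d px, %.2f-%.2f h, %g-min exposure",
              d[3L], d[1L], d[2L], x$timestamps_h[1L],
              x$timestamps_h[d[3L]], x$exposure_min))
  if (any(x$missing)) cat(sprintf(", %d missing", sum(x$missing)))
  cat("\n")
  invisible(x)
}

#' @rdname frame_stack
#' @param stack A `frame_stack`.
#' @param path File path.
#' @export
write_stack_csv <- function(stack, path) {
  d <- dim(stack$frames)
  df <- data.frame(
    frame = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    t_h = rep(stack$timestamps_h, each = d[1L] * d[2L]),
    row = rep(rep(seq_len(d[1L]), times = d[2L]), times = d[3L]),
    col = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
    value = as.vector(stack$frames))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname frame_stack
#' @export
read_stack_csv <- function(path) {
  df <- utils::read.csv(path)
  nr <- max(df$row); nc <- max(df$col); nf <- max(df$frame)
  a <- array(NA_real_, c(nr, nc, nf))
  a[cbind(df$row, df$col, df$frame)] <- df$value
  ts <- tapply(df$t_h, df$frame, `[`, 1L)
  frame_stack(a, as.numeric(ts),
              exposure_min = if ("exposure_min" %in% names(df))
                df$exposure_min[1L] else 15)
}

#' ROI sets
#'
#' Rectangular regions of interest over a frame, with cell labels, plus
#' exactly one background ROI. Coordinates are 1-based inclusive pixel
#' indices (`row0 <= row1`, `col0 <= col1`).
#'
#' @param rois data.frame with columns `label`, `cell_id`, `brain_id`,
#'   `subgroup`, `row0`, `row1`, `col0`, `col1`; exactly one row must
#'   have `label == "background"`.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(rois) {
  need <- c("label", "cell_id", "brain_id", "subgroup",
            "row0", "row1", "col0", "col1")
  stopifnot(is.data.frame(rois), all(need %in% names(rois)))
  if (sum(rois$label == "background") != 1L)
    stop("roi_set needs exactly one background ROI")
  if (any(rois$row1 < rois$row0) || any(rois$col1 < rois$col0))
    stop("degenerate ROI rectangle")
  structure(list(rois = rois), class = "roi_set")
}

#' @rdname roi_set
#' @param x A `roi_set`.
#' @param path File path for CSV round-trip.
#' @export
write_rois_csv <- function(x, path) {
  utils::write.csv(x$rois, path, row.names = FALSE)
  invisible(path)
}

#' @rdname roi_set
#' @export
read_rois_csv <- function(path) {
  roi_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Render synthetic bioluminescence frames from cell traces
#'
#' Draws each cell as a 2-D Gaussian spot at a fixed position, scaled by
#' that cell's signal at each frame time, over a dark-current offset,
#' with optional Poisson photon noise, injected cosmic-ray streaks at
#' chosen frames, and single-frame hot pixels at known positions.
#' Returns the stack plus an ROI set matching the layout (one rectangle
#' per spot and one empty background region).
#'
#' @param traces List of `cell_trace` objects sharing one time grid.
#' @param shape `c(rows, cols)` of each frame.
#' @param spot_sigma_px Gaussian spot SD in pixels.
#' @param dark_offset Constant dark-current level added to every pixel.
#' @param poisson_noise If `TRUE`, pixel values are Poisson draws around
#'   their expectation.
#' @param cosmic_ray_frames Integer frame indices receiving a bright
#'   streak (one full row driven to `cosmic_ray_value`).
#' @param cosmic_ray_value Intensity of the streak pixels.
#' @param hot_pixels Optional data.frame `frame, row, col, value` of
#'   single-frame hot pixels.
#' @param roi_half Half-width of the square cell ROIs, pixels.
#' @param seed Integer seed.
#' @return List with `stack` (a [frame_stack()]), `rois` (a
#'   [roi_set()]), and `spot_gain` (per-cell ROI-mean intensity per unit
#'   trace signal, for ground-truth checks).
#' @export
simulate_frames <- function(traces, shape = c(48L, 64L), spot_sigma_px = 1.3,
                            dark_offset = 5, poisson_noise = TRUE,
                            cosmic_ray_frames = integer(0),
                            cosmic_ray_value = 4000, hot_pixels = NULL,
                            roi_half = 3L, seed = 1L) {
  stopifnot(length(traces) >= 1L)
  t_h <- traces[[1L]]$t
  for (tr in traces)
    if (!isTRUE(all.equal(tr$t, t_h))) stop("traces must share a time grid")
  set.seed(seed)
  nr <- shape[1L]; nc <- shape[2L]; nf <- length(t_h)
  n_cell <- length(traces)
  # grid layout with a reserved background corner (top-left block)
  spacing <- 2L * roi_half + 3L
  per_row <- max(1L, (nc - spacing) %/% spacing)
  ci <- seq_len(n_cell) - 1L
  cx <- spacing + (ci %% per_row) * spacing + roi_half + 1L
  cy <- spacing + (ci %/% per_row) * spacing + roi_half + 1L
  if (any(cy + roi_half > nr) || any(cx + roi_half > nc))
    stop("frame shape too small for this many non-overlapping spots")

  kern <- outer(-roi_half:roi_half, -roi_half:roi_half, function(a, b)
    exp(-(a^2 + b^2) / (2 * spot_sigma_px^2)))
  base <- matrix(dark_offset, nr, nc)
  frames <- array(0, c(nr, nc, nf))
  Y <- vapply(traces, function(tr) tr$y, numeric(nf))
  for (f in seq_len(nf)) {
    img <- base
    for (i in seq_len(n_cell)) {
      rr <- (cy[i] - roi_half):(cy[i] + roi_half)
      cc <- (cx[i] - roi_half):(cx[i] + roi_half)
      img[rr, cc] <- img[rr, cc] + max(Y[f, i], 0) * kern
    }
    if (poisson_noise) img <- matrix(stats::rpois(nr * nc, img), nr, nc)
    frames[, , f] <- img
  }
  for (f in cosmic_ray_frames)
    frames[ceiling(nr / 2), , f] <- cosmic_ray_value
  if (!is.null(hot_pixels))
    frames[cbind(hot_pixels$row, hot_pixels$col, hot_pixels$frame)] <-
      hot_pixels$value

  rois <- data.frame(
    label = c(vapply(traces, function(tr) tr$cell_id, ""), "background"),
    cell_id = c(vapply(traces, function(tr) tr$cell_id, ""), NA),
    brain_id = c(vapply(traces, function(tr) tr$brain_id, ""), NA),
    subgroup = c(vapply(traces, function(tr) tr$subgroup, ""), NA),
    row0 = c(cy - roi_half, 1L), row1 = c(cy + roi_half, roi_half * 2L + 1L),
    col0 = c(cx - roi_half, 1L), col1 = c(cx + roi_half, roi_half * 2L + 1L),
    stringsAsFactors = FALSE)
  list(stack = frame_stack(frames, t_h, exposure_min = 45),
       rois = roi_set(rois),
       spot_gain = sum(kern) / length(kern))
}
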