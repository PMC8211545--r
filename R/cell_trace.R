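#' Single-cell bioluminescence traces
#'
#' A `cell_trace` holds one cell's bioluminescence time series on a
#' uniform time grid (default cadence 0.75 h, i.e. 45-min bins) together
#' with its anatomical labels. Values are photons per minute after
#' background subtraction and may be negative. A set of traces is a plain
#' list of `cell_trace` objects; [traces_to_df()] / [df_to_traces()]
#' convert to and from the long-format CSV representation.
#'
#' @param t Time grid in hours, strictly increasing and uniform.
#' @param y Signal, same length as `t` (photons/min; `NA` marks missing
#'   bins).
#' @param cell_id,brain_id Identifiers.
#' @param subgroup One of `"s-LNv"`, `"l-LNv"`, `"LNd"`, `"DN1"`,
#'   `"DN3"`, or another label.
#' @param reporter `"PER"` or `"TIM"`.
#' @param units Unit string carried as metadata.
#' @return An object of class `cell_trace`.
#' @export
cell_trace <- function(t, y, cell_id = "cell1", brain_id = "brain1",
                       subgroup = "s-LNv", reporter = "PER",
                       units = "photons/min") {
  stopifnot(length(t) == length(y), length(t) >= 2L)
  dt <- diff(t)
  if (any(dt <= 0)) stop("`t` must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6) stop("`t` must be a uniform grid")
  structure(list(t = as.numeric(t), y = as.numeric(y),
                 cell_id = cell_id, brain_id = brain_id,
                 subgroup = subgroup, reporter = reporter, units = units),
            class = "cell_trace")
}

#' @export
print.cell_trace <- function(x, ...) {
  cat(sprintf("<cell_trace> %s / %s / %s (%s), %d samples, %.1f-%.1f h\n",
              x$brain_id, x$subgroup, x$cell_id, x$reporter,
              length(x$t), x$t[1L], x$t[length(x$t)]))
  invisible(x)
}

#' @rdname cell_trace
#' @param traces A list of `cell_trace` objects.
#' @export
traces_to_df <- function(traces) {
  do.call(rbind, lapply(traces, function(tr)
    data.frame(cell_id = tr$cell_id, brain_id = tr$brain_id,
               subgroup = tr$subgroup, reporter = tr$reporter,
               t_h = tr$t, photons_per_min = tr$y,
               stringsAsFactors = FALSE)))
}

#' @rdname cell_trace
#' @param df A data.frame in the long format written by
#'   [write_traces_csv()].
#' @export
df_to_traces <- function(df) {
  need <- c("cell_id", "brain_id", "subgroup", "reporter", "t_h",
            "photons_per_min")
  if (!all(need %in% names(df)))
    stop("trace table must have columns: ", paste(need, collapse = ", "))
  key <- paste(df$brain_id, df$cell_id, sep = "\r")
  lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
         function(i) {
           d <- df[i, , drop = FALSE]
           d <- d[order(d$t_h), , drop = FALSE]
           cell_trace(d$t_h, d$photons_per_min, cell_id = d$cell_id[1L],
                      brain_id = d$brain_id[1L], subgroup = d$subgroup[1L],
                      reporter = d$reporter[1L])
         })
}

#' @rdname cell_trace
#' @param path File path for CSV I/O.
#' @export
write_traces_csv <- function(traces, path) {
  utils::write.csv(traces_to_df(traces), path, row.names = FALSE)
  invisible(path)
}

#' @rdname cell_trace
#' @export
read_traces_csv <- function(path) {
  df_to_traces(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Drop the initial culture transient from traces
#'
#' The first hours after dissection show elevated, highly variable
#' bioluminescence; the standard analysis excludes the first 12 h of each
#' record before any quantification (raw files keep them).
#'
#' @param traces A list of `cell_trace` objects (or a single one).
#' @param hours Hours to drop from the start of each record.
#' @return Trimmed traces (same structure as input).
#' @export
trim_initial <- function(traces, hours = 12) {
  one <- function(tr) {
    keep <- tr$t >= hours
    if (!any(keep)) stop("`hours` removes the whole record")
    cell_trace(tr$t[keep], tr$y[keep], tr$cell_id, tr$brain_id,
               tr$subgroup, tr$reporter, tr$units)
  }
  if (inherits(traces, "cell_trace")) return(one(traces))
  lapply(traces, one)
}
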