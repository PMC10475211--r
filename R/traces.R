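#' Construct a bioluminescence trace matrix
#'
#' Container for hourly (or finer) single-cell bioluminescence intensities
#' of one SCN slice: a uniform time grid, a cells x times intensity matrix
#' and per-slice metadata.
#'
#' @param times numeric vector of sampling times (h), strictly increasing
#'   and uniformly spaced.
#' @param intensity numeric matrix, cells x times.
#' @param cell_ids character vector of cell identifiers (default
#'   `cell_0001`, ...).
#' @param metadata list with optional fields `age` ("young"/"old"),
#'   `photoperiod` ("LP"/"SP"), `position` ("anterior"/"posterior").
#' @return an object of class `scn_traces`.
#' @export
scn_traces <- function(times, intensity, cell_ids = NULL, metadata = list()) {
  intensity <- as.matrix(intensity)
  if (length(times) != ncol(intensity))
    stop("'times' length must equal ncol(intensity)")
  if (nrow(intensity) < 2L) stop("need at least 2 cells")
  d <- diff(times)
  if (any(d <= 0)) stop("'times' must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * mean(d))
    stop("non-uniform time grid in trace matrix")
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("trace intensities must be finite")
  if (is.null(cell_ids))
    cell_ids <- sprintf("cell_%04d", seq_len(nrow(intensity)))
  md <- validate_metadata(metadata)
  rownames(intensity) <- cell_ids
  structure(list(times = as.numeric(times), intensity = intensity,
                 cell_ids = cell_ids, metadata = md),
            class = "scn_traces")
}

validate_metadata <- function(metadata) {
  vocab <- list(age = c("young", "old"), photoperiod = c("LP", "SP"),
                position = c("anterior", "posterior"))
  for (f in names(vocab))
    if (!is.null(metadata[[f]]) && !metadata[[f]] %in% vocab[[f]])
      stop("metadata '", f, "' must be one of: ",
           paste(vocab[[f]], collapse = ", "))
  metadata
}

#' @export
print.scn_traces <- function(x, ...) {
  cat("SCN trace matrix:", nrow(x$intensity), "cells x",
      ncol(x$intensity), "samples, grid",
      round(diff(x$times[1:2]) * 60, 2), "min, span",
      round(diff(range(x$times)), 1), "h\n")
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a trace matrix as CSV
#'
#' Plain-text interchange format: first column `time_h`, one column per
#' cell.  Metadata is not stored in the CSV; supply it on read.
#'
#' @param traces an `scn_traces` object.
#' @param path file path.
#' @rdname trace_io
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "scn_traces"))
  df <- data.frame(time_h = traces$times,
                   t(traces$intensity), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param metadata metadata list attached on read.
#' @rdname trace_io
#' @export
read_traces <- function(path, metadata = list()) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "time_h")
    stop("trace CSV must have first column 'time_h'")
  scn_traces(df$time_h, t(as.matrix(df[, -1L, drop = FALSE])),
             cell_ids = names(df)[-1L], metadata = metadata)
}

#' Smooth and resample traces to a fine uniform grid
#'
#' Centred moving-average smoothing (default 3 h window) followed by cubic
#' spline interpolation onto a 1-sample-per-minute grid spanning the input
#' range, emulating the preprocessing applied to raw hourly PER2::LUC
#' recordings.  Edges use a shrinking (partial) window.  Deterministic.
#'
#' @param traces an `scn_traces` object covering at least 48 h.
#' @param window_h smoothing window in hours.
#' @param resample_min output grid spacing in minutes.
#' @return a new `scn_traces` on the fine grid.
#' @export
smooth_and_resample <- function(traces, window_h = 3, resample_min = 1) {
  stopifnot(inherits(traces, "scn_traces"))
  span <- diff(range(traces$times))
  if (span < 48) stop("need at least 48 h of data")
  if (window_h > span) stop("smoothing window longer than the record")
  dt <- diff(traces$times[1:2])
  k <- max(1L, round(window_h / dt))
  if (k %% 2L == 0L) k <- k + 1L
  sm <- t(apply(traces$intensity, 1L, moving_average, k = k))
  xout <- seq(traces$times[1L], traces$times[length(traces$times)],
              by = resample_min / 60)
  out <- t(apply(sm, 1L, function(y)
    stats::spline(traces$times, y, xout = xout, method = "fmm")$y))
  scn_traces(xout, out, cell_ids = traces$cell_ids,
             metadata = traces$metadata)
}

## centred moving average with shrinking edge windows
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  h <- (k - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
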