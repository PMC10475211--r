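#' Detect per-cell expression peaks
#'
#' Local maxima of each (smoothed, resampled) trace with a minimum
#' separation of `min_separation_h` hours and topographic prominence above
#' `prominence_frac` of the cell's amplitude range.  The defaults are safe
#' for circadian periods in the 20--28 h inclusion band.  Per-cell periods
#' are the mean inter-peak interval; the slice consensus period is the
#' median of per-cell periods; cycle indices are assigned on a common
#' slice-wide grid so that "cycle k" is comparable across cells.
#'
#' @param traces an `scn_traces` object (smoothed/resampled input).
#' @param min_separation_h minimum distance between accepted peaks (h).
#' @param prominence_frac prominence threshold as a fraction of each
#'   cell's intensity range.
#' @return an object of class `peak_series`: list with `peaks`
#'   (data.frame: cell_id, cycle, peak_time_h), `periods` (data.frame:
#'   cell_id, period_h, n_peaks), consensus `tau`, `cell_ids`, `metadata`
#'   and a `filtered` flag.  Cells with fewer than 2 peaks are retained
#'   with an empty series (period `NA`).
#' @export
detect_peaks <- function(traces, min_separation_h = 16,
                         prominence_frac = 0.2) {
  stopifnot(inherits(traces, "scn_traces"))
  tt <- traces$times
  dt <- diff(tt[1:2])
  min_sep <- round(min_separation_h / dt)
  pk <- lapply(seq_len(nrow(traces$intensity)), function(i) {
    find_peaks(traces$intensity[i, ], min_sep, prominence_frac)
  })
  periods <- vapply(pk, function(ix)
    if (length(ix) >= 2L) mean(diff(tt[ix])) else NA_real_, numeric(1))
  n_peaks <- lengths(pk)
  tau <- stats::median(periods, na.rm = TRUE)
  if (!is.finite(tau))
    stop("no cell has two or more peaks; cannot estimate a period")
  ## common cycle grid anchored on the median first peak
  first <- vapply(pk, function(ix)
    if (length(ix)) tt[ix[1L]] else NA_real_, numeric(1))
  anchor <- stats::median(first, na.rm = TRUE)
  rows <- lapply(seq_along(pk), function(i) {
    if (!length(pk[[i]])) return(NULL)
    tp <- tt[pk[[i]]]
    data.frame(cell_id = traces$cell_ids[i],
               cycle = as.integer(round((tp - anchor) / tau)) + 1L,
               peak_time_h = tp)
  })
  peaks <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(peaks = peaks,
                 periods = data.frame(cell_id = traces$cell_ids,
                                      period_h = periods,
                                      n_peaks = n_peaks),
                 tau = tau, cell_ids = traces$cell_ids,
                 metadata = traces$metadata, filtered = FALSE),
            class = "peak_series")
}

## indices of local maxima with minimum separation and prominence filter;
## greedy acceptance in decreasing height order
find_peaks <- function(v, min_sep, prominence_frac) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  rng <- diff(range(v))
  if (rng <= 1e-9 * max(1, abs(mean(v)))) return(integer(0))  # flat trace
  d <- diff(v)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  if (!length(cand)) return(integer(0))
  thr <- prominence_frac * diff(range(v))
  prom <- vapply(cand, peak_prominence, numeric(1), v = v)
  cand <- cand[prom >= thr & prom > 0]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(v[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (ix in cand)
    if (!length(keep) || all(abs(keep - ix) >= min_sep))
      keep <- c(keep, ix)
  sort(keep)
}

## topographic prominence: height above the higher of the two valley
## minima separating the peak from higher ground (or the record edge)
peak_prominence <- function(i, v) {
  h <- v[i]
  left <- v[seq_len(i - 1L)]
  hi <- which(left > h)
  lbase <- min(left[seq.int(if (length(hi)) max(hi) else 1L, i - 1L)])
  right <- v[seq.int(i + 1L, length(v))]
  hi <- which(right > h)
  rbase <- min(right[seq_len(if (length(hi)) min(hi) else length(right))])
  h - max(lbase, rbase)
}

#' Apply the cycle-count and period inclusion filter
#'
#' Retains cells with at least `min_cycles` complete cycles (a cycle is an
#' inter-peak interval, so `min_cycles = 3` requires 4 peaks) and a
#' per-cell period inside `period_range` (default 20--28 h).  Idempotent.
#'
#' @param series a `peak_series`.
#' @param min_cycles minimum number of inter-peak intervals.
#' @param period_range inclusive period band in hours.
#' @return the filtered `peak_series`, with attributes `n_retained` and
#'   `n_dropped` recorded in its `counts` field.
#' @export
filter_cells <- function(series, min_cycles = 3L, period_range = c(20, 28)) {
  stopifnot(inherits(series, "peak_series"))
  p <- series$periods
  ok <- !is.na(p$period_h) &
    p$period_h >= period_range[1L] & p$period_h <= period_range[2L] &
    p$n_peaks >= min_cycles + 1L
  keep <- p$cell_id[ok]
  if (!length(keep))
    stop("all cells dropped by the cycle/period filter; nothing to analyse")
  out <- series
  out$peaks <- series$peaks[series$peaks$cell_id %in% keep, , drop = FALSE]
  out$periods <- p[ok, , drop = FALSE]
  out$cell_ids <- keep
  out$tau <- stats::median(out$periods$period_h)
  out$filtered <- TRUE
  out$counts <- c(n_retained = sum(ok), n_dropped = sum(!ok))
  out
}

#' Peak-time dispersion of one cycle
#'
#' Sample standard deviation of the chosen cycle's peak times across all
#' cells that exhibit that cycle; the slice-level measure of phase
#' distribution width.
#'
#' @param series a `peak_series`.
#' @param cycle cycle index (default 2, the first full cycle after the
#'   culture transient).
#' @return dispersion in hours.
#' @export
peak_time_dispersion <- function(series, cycle = 2L) {
  tp <- cycle_peak_times(series, cycle)
  if (length(tp) < 2L)
    stop("fewer than 2 cells contribute peaks at cycle ", cycle)
  stats::sd(tp)
}

## named vector of peak times of one cycle (cells lacking it are skipped)
cycle_peak_times <- function(series, cycle) {
  stopifnot(inherits(series, "peak_series"))
  sel <- series$peaks$cycle == cycle
  tp <- series$peaks$peak_time_h[sel]
  names(tp) <- series$peaks$cell_id[sel]
  tp[!duplicated(names(tp))]
}

#' @export
print.peak_series <- function(x, ...) {
  cat("Peak series:", length(x$cell_ids), "cells,",
      nrow(x$peaks), "peaks, consensus period",
      round(x$tau, 2), "h",
      if (isTRUE(x$filtered)) "(filtered)" else "(unfiltered)", "\n")
  invisible(x)
}

#' Write a peak series as tidy CSV
#'
#' Columns: cell_id, cycle, peak_time_h, period_h.
#'
#' @param series a `peak_series`.
#' @param path output file.
#' @export
write_peak_series <- function(series, path) {
  stopifnot(inherits(series, "peak_series"))
  df <- merge(series$peaks, series$periods[, c("cell_id", "period_h")],
              by = "cell_id", sort = TRUE)
  utils::write.csv(df[order(df$cell_id, df$cycle), ], path,
                   row.names = FALSE)
  invisible(path)
}
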