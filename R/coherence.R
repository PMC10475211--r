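#' Mean peak time of one cycle
#'
#' Arithmetic mean of the per-cell peak times of the specified cycle.
#'
#' @param series a `peak_series`.
#' @param cycle cycle index.
#' @return mean peak time in hours.
#' @export
mean_peak_time <- function(series, cycle = 2L) {
  tp <- cycle_peak_times(series, cycle)
  if (length(tp) < 2L)
    stop("fewer than 2 cells contribute peaks at cycle ", cycle)
  mean(tp)
}

#' Relative phases of the cells at one cycle
#'
#' Converts relative peak times to phases,
#' `theta_j = (tbar_p - t_j) * 2 * pi / tau`, using the slice consensus
#' period, then wraps onto (-pi, pi].  A cell peaking earlier than the mean
#' leads (positive phase).  The small-angle reading of peak-time offsets as
#' phases is inherited from the measurement model; no further correction is
#' applied.
#'
#' @param series a `peak_series`.
#' @param cycle cycle index.
#' @param tau period in hours (defaults to the slice consensus period);
#'   must lie in [20, 28].
#' @return named numeric vector of phases (rad), one per contributing cell.
#' @export
relative_phases <- function(series, cycle = 2L, tau = NULL) {
  if (is.null(tau)) tau <- series$tau
  if (!is.finite(tau) || tau < 20 || tau > 28)
    stop("'tau' must lie in [20, 28] h")
  tp <- cycle_peak_times(series, cycle)
  if (length(tp) < 2L)
    stop("fewer than 2 cells contribute peaks at cycle ", cycle)
  wrap_phase((mean(tp) - tp) * 2 * pi / tau)
}

#' Kuramoto order parameter
#'
#' Magnitude of the population-mean unit phasor,
#' `r = |mean(exp(i theta))|`: 0 for incoherent phases, 1 for perfect
#' synchrony.
#'
#' @param phases numeric vector of phases (rad), length >= 2.
#' @return scalar in [0, 1].
#' @examples
#' order_parameter(c(pi / 12, 0, -pi / 12))  # (1 + 2 cos(pi/12)) / 3
#' @export
order_parameter <- function(phases) {
  if (length(phases) < 2L) stop("need at least 2 phases")
  if (anyNA(phases)) stop("phases must not contain NA")
  Mod(mean(exp(1i * phases)))
}

#' Per-community order parameters
#'
#' Applies [order_parameter()] within each community, each community using
#' its own within-group mean peak time (community 1 is the medial-oriented
#' cluster, community 2 the lateral-oriented cluster).
#'
#' @param series a `peak_series`.
#' @param labels community labels: a named vector (names = cell ids,
#'   values 1 or 2), or a data.frame with columns `cell_id`, `community`,
#'   or a `community_assignment`.
#' @param cycle cycle index.
#' @param tau period (defaults to slice consensus).
#' @return named vector `c(r1, r2)`.
#' @export
community_order_parameters <- function(series, labels, cycle = 2L,
                                       tau = NULL) {
  if (is.null(tau)) tau <- series$tau
  labs <- as_label_vector(labels)
  tp <- cycle_peak_times(series, cycle)
  labs <- labs[names(tp)]
  if (anyNA(labs)) stop("labels do not cover all retained cells")
  vapply(1:2, function(g) {
    tpg <- tp[labs == g]
    if (length(tpg) < 2L)
      stop("community ", g, " has fewer than 2 cells at cycle ", cycle)
    order_parameter(wrap_phase((mean(tpg) - tpg) * 2 * pi / tau))
  }, numeric(1)) -> r
  c(r1 = r[1L], r2 = r[2L])
}

as_label_vector <- function(labels) {
  if (inherits(labels, "community_assignment")) labels <- labels$labels
  if (is.data.frame(labels)) {
    v <- labels$community
    names(v) <- labels$cell_id
    return(v)
  }
  if (is.null(names(labels)))
    stop("'labels' must be named by cell id (or be a data.frame)")
  labels
}

#' Full slice coherence summary
#'
#' Mean peak time, relative phases, order parameter, contributing cell
#' count and peak-time dispersion of the specified cycle, optionally with
#' per-community order parameters.
#'
#' @param series a filtered `peak_series`.
#' @param cycle cycle index.
#' @param labels optional community labels (see
#'   [community_order_parameters()]).
#' @return an object of class `coherence_result`.
#' @export
slice_coherence <- function(series, cycle = 2L, labels = NULL) {
  phases <- relative_phases(series, cycle)
  res <- list(mean_peak_time = mean_peak_time(series, cycle),
              relative_phases = phases,
              r = order_parameter(phases),
              dispersion_h = peak_time_dispersion(series, cycle),
              n_cells = length(phases),
              cycle = cycle, tau = series$tau)
  if (!is.null(labels)) {
    rc <- community_order_parameters(series, labels, cycle)
    res$r1 <- rc[["r1"]]; res$r2 <- rc[["r2"]]
  }
  structure(res, class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat("Slice coherence (cycle ", x$cycle, "): r = ", round(x$r, 3),
      ", dispersion = ", round(x$dispersion_h, 2), " h, n = ",
      x$n_cells, "\n", sep = "")
  if (!is.null(x$r1))
    cat("  community order parameters: r1 =", round(x$r1, 3),
        " r2 =", round(x$r2, 3), "\n")
  invisible(x)
}

#' Correlation between order parameter and peak-time dispersion
#'
#' Pearson correlation across slices; on realistic ensembles this is
#' strongly negative, since wide peak-time dispersion implies low phase
#' coherence.
#'
#' @param r order parameters, one per slice (>= 3 slices).
#' @param dispersion_h matching peak-time dispersions (h).
#' @return Pearson correlation coefficient.
#' @export
coherence_dispersion_correlation <- function(r, dispersion_h) {
  if (length(r) != length(dispersion_h)) stop("length mismatch")
  if (length(r) < 3L) stop("need at least 3 slices")
  if (stats::sd(r) == 0 || stats::sd(dispersion_h) == 0)
    stop("zero-variance input")
  stats::cor(r, dispersion_h)
}
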