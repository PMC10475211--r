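#' Fit the noisy Kuramoto coupling model to a slice of traces
#'
#' The main fitting entry point.  Runs the measurement pipeline on raw
#' single-cell bioluminescence traces — smoothing and resampling, peak
#' detection, cycle/period inclusion filtering, phase coherence at the
#' analysis cycle — and then the model-based inference: interval estimates
#' of the coupling strength `K` and noise strength `D` from the
#' one-community model, and, when two communities are available (detected
#' from the traces or supplied as labels), the per-community order
#' parameters and the linear `K`--`L` coupling relations of the
#' two-community model.
#'
#' @param x an `scn_traces`, an `scn_slice`, or a cells x times matrix.
#' @param times sampling times (h) when `x` is a bare matrix.
#' @param cycle analysis cycle index (default 2, the first full cycle
#'   after the transient).
#' @param labels optional community labels (named vector, data.frame or
#'   `community_assignment`); overrides detection.
#' @param detect_communities run RMT community detection when no labels
#'   are given.
#' @param smooth_window_h,resample_min,min_separation_h,prominence_frac,
#'   min_cycles,period_range pipeline settings, see
#'   [smooth_and_resample()], [detect_peaks()], [filter_cells()].
#' @param D_lines noise strength used for the two-community lines.
#' @return an object of class `kuramoto_fit` with components `coherence`
#'   (a `coherence_result`), `bounds` (a `one_community_bounds`), `lines`
#'   (a `condition_lines` or `NULL`), `communities`, `peaks`, `traces`
#'   and `call`.
#' @examples
#' slice <- simulate_scn_slice(one_community_params(n_oscillators = 40,
#'   K = 2, D = 0.8, n_cycles = 6, seed = 7))
#' fit <- kuramoto_fit(slice, detect_communities = FALSE)
#' coef(fit)
#' @export
kuramoto_fit <- function(x, times = NULL, cycle = 2L, labels = NULL,
                         detect_communities = TRUE,
                         smooth_window_h = 3, resample_min = 1,
                         min_separation_h = 16, prominence_frac = 0.2,
                         min_cycles = 3L, period_range = c(20, 28),
                         D_lines = 1) {
  cl <- match.call()
  if (inherits(x, "scn_slice")) x <- x$traces
  if (is.matrix(x) && !inherits(x, "scn_traces")) {
    if (is.null(times)) stop("supply 'times' with a bare matrix")
    x <- scn_traces(times, x)
  }
  stopifnot(inherits(x, "scn_traces"))
  fine <- smooth_and_resample(x, window_h = smooth_window_h,
                              resample_min = resample_min)
  peaks <- filter_cells(detect_peaks(fine,
                                     min_separation_h = min_separation_h,
                                     prominence_frac = prominence_frac),
                        min_cycles = min_cycles,
                        period_range = period_range)
  communities <- NULL
  if (is.null(labels) && isTRUE(detect_communities)) {
    communities <- detect_communities(x)
    if (!communities$degenerate) labels <- communities$labels
  }
  lab_ok <- !is.null(labels)
  coh <- tryCatch(slice_coherence(peaks, cycle,
                                  labels = if (lab_ok) labels),
                  error = function(e) {
                    if (!lab_ok) stop(e)
                    lab_ok <<- FALSE
                    slice_coherence(peaks, cycle)
                  })
  bounds <- estimate_coupling_bounds(peaks, cycle)
  lines <- if (!is.null(coh$r1))
    condition_lines(coh$r1, coh$r2, D = D_lines) else NULL
  structure(list(coherence = coh, bounds = bounds, lines = lines,
                 communities = communities, labels = labels,
                 peaks = peaks, traces = x, cycle = cycle, call = cl),
            class = "kuramoto_fit")
}

#' @export
print.kuramoto_fit <- function(x, ...) {
  cat("Noisy Kuramoto coupling fit\n")
  cat("  cells retained:", length(x$peaks$cell_ids),
      " consensus period:", round(x$peaks$tau, 2), "h\n")
  cat("  order parameter r =", round(x$coherence$r, 3),
      " (cycle", x$cycle, ")\n")
  cat("  K in [", round(x$bounds$K_minus, 3), ",",
      round(x$bounds$K_plus, 3), "]  D in [",
      round(x$bounds$D_minus, 3), ",", round(x$bounds$D_plus, 3), "]\n")
  if (!is.null(x$lines))
    cat("  two-community lines: r1 =", round(x$lines$r1, 3),
        " r2 =", round(x$lines$r2, 3), "\n")
  invisible(x)
}

#' @export
summary.kuramoto_fit <- function(object, ...) {
  x <- object
  s <- list(n_cells = length(x$peaks$cell_ids),
            counts = x$peaks$counts,
            tau = x$peaks$tau,
            cycle = x$cycle,
            r = x$coherence$r,
            dispersion_h = x$coherence$dispersion_h,
            r1 = x$coherence$r1, r2 = x$coherence$r2,
            coef = coef(x),
            lines = x$lines,
            quality = if (!is.null(x$communities)) x$communities$quality)
  class(s) <- "summary.kuramoto_fit"
  s
}

#' @export
print.summary.kuramoto_fit <- function(x, ...) {
  cat("Noisy Kuramoto coupling fit\n")
  cat("  retained cells:", x$n_cells)
  if (!is.null(x$counts))
    cat("  (dropped:", x$counts[["n_dropped"]], ")")
  cat("\n  consensus period:", round(x$tau, 2), "h;  analysis cycle:",
      x$cycle, "\n")
  cat("  phase coherence: r =", round(x$r, 4),
      "; peak-time dispersion =", round(x$dispersion_h, 2), "h\n")
  if (!is.null(x$r1))
    cat("  community order parameters: r1 =", round(x$r1, 4),
        ", r2 =", round(x$r2, 4), "\n")
  cat("  coupling bounds:  K- =", round(x$coef[["K_minus"]], 4),
      " K+ =", round(x$coef[["K_plus"]], 4), "\n")
  cat("  noise bounds:     D- =", round(x$coef[["D_minus"]], 4),
      " D+ =", round(x$coef[["D_plus"]], 4), "\n")
  if (!is.null(x$lines)) print(x$lines)
  invisible(x)
}

#' @export
coef.kuramoto_fit <- function(object, ...) {
  b <- object$bounds
  c(r = b$r, C = b$C, K_minus = b$K_minus, K_plus = b$K_plus,
    D_minus = b$D_minus, D_plus = b$D_plus)
}

#' Plot method for Kuramoto fits
#'
#' `type = "traces"` overlays the raw traces; `"phases"` shows the
#' relative-phase rose at the analysis cycle; `"lines"` draws the
#' two-community coupling lines inside the standard search window.
#'
#' @param x a `kuramoto_fit`.
#' @param type one of `"traces"`, `"phases"`, `"lines"`.
#' @param max_cells cap on plotted traces.
#' @param ... passed to the underlying plot calls.
#' @export
plot.kuramoto_fit <- function(x, type = c("traces", "phases", "lines"),
                              max_cells = 25L, ...) {
  type <- match.arg(type)
  if (type == "traces") {
    m <- x$traces$intensity
    sel <- seq_len(min(nrow(m), max_cells))
    graphics::matplot(x$traces$times, t(m[sel, , drop = FALSE]),
                      type = "l", lty = 1,
                      col = grDevices::hcl.colors(length(sel), "Zissou 1"),
                      xlab = "time (h)", ylab = "intensity (a.u.)",
                      main = "single-cell bioluminescence", ...)
  } else if (type == "phases") {
    ph <- x$coherence$relative_phases
    graphics::plot(cos(ph), sin(ph), asp = 1, xlim = c(-1, 1),
                   ylim = c(-1, 1), xlab = "cos", ylab = "sin",
                   main = sprintf("relative phases (r = %.3f)",
                                  x$coherence$r), ...)
    graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE)
    graphics::arrows(0, 0, mean(cos(ph)), mean(sin(ph)), length = 0.08,
                     lwd = 2)
  } else {
    if (is.null(x$lines)) stop("fit has no two-community lines")
    ln <- x$lines
    L <- seq(-5, 10, length.out = 200)
    K1 <- ln$slope1 * L + ln$intercept1
    K2 <- ln$slope2 * L + ln$intercept2
    graphics::plot(L, K1, type = "l", ylim = c(0, 10), lwd = 2,
                   xlab = "cross-community coupling L",
                   ylab = "within-community coupling K",
                   main = "coupling lines", ...)
    graphics::lines(L, K2, lwd = 2, lty = 2)
    graphics::legend("topright", c("community 1 (medial)",
                                   "community 2 (lateral)"),
                     lty = 1:2, lwd = 2, bty = "n")
  }
  invisible(x)
}

#' Simulate traces from a fitted model
#'
#' Regenerates synthetic slices at the fitted operating point: the
#' midpoint of the inferred `[K-, K+]` and `[D-, D+]` intervals, the
#' measured consensus period and the retained cell count.  Useful as a
#' posterior-predictive style check of the measurement pipeline.
#'
#' @param object a `kuramoto_fit`.
#' @param nsim number of slices.
#' @param seed master seed.
#' @param ... passed to [render_options()].
#' @return list of `scn_slice` objects (length `nsim`).
#' @export
simulate.kuramoto_fit <- function(object, nsim = 1, seed = 1L, ...) {
  b <- object$bounds
  K <- (b$K_minus + b$K_plus) / 2
  D <- (b$D_minus + b$D_plus) / 2
  n <- length(object$peaks$cell_ids)
  ncyc <- max(3L, max(object$peaks$peaks$cycle))
  lapply(seq_len(nsim), function(i)
    simulate_scn_slice(one_community_params(n_oscillators = n, K = K,
                                            D = D, tau = object$peaks$tau,
                                            n_cycles = ncyc,
                                            seed = seed + i - 1L),
                       render_options(...)))
}

#' Residual relative phases
#'
#' The relative phases at the analysis cycle; under the fitted stationary
#' model these are approximately von Mises with concentration `C r`.
#'
#' @param object a `kuramoto_fit`.
#' @param ... unused.
#' @return numeric vector (rad).
#' @export
residuals.kuramoto_fit <- function(object, ...) {
  object$coherence$relative_phases
}
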