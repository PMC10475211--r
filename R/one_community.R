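#' Cycle-to-cycle phase increments
#'
#' For every retained cell and every pair of consecutive cycles both
#' present in its peak series, the change in relative phase over one
#' period, `Delta_T = theta_r(k+1) - theta_r(k)`, wrapped onto (-pi, pi].
#' Samples are pooled across cells and cycle pairs.  In the rotating frame
#' the expected change is zero; the spread of `Delta_T` carries the noise
#' information used by [coupling_and_noise_bounds()].
#'
#' @param series a filtered `peak_series`.
#' @param tau period of the average phase, `T`, in hours (defaults to the
#'   slice consensus period).
#' @param cycles optional integer vector restricting which cycles are used.
#' @return an object of class `phase_increments`: list with `samples`
#'   (rad), `T` (h) and `n`.
#' @export
phase_increments <- function(series, tau = NULL, cycles = NULL) {
  stopifnot(inherits(series, "peak_series"))
  if (is.null(tau)) tau <- series$tau
  if (!is.finite(tau) || tau < 20 || tau > 28)
    stop("'T' must lie in [20, 28] h")
  cyc <- sort(unique(series$peaks$cycle))
  if (!is.null(cycles)) cyc <- intersect(cyc, cycles)
  ## relative phases per cycle (cycles with >= 2 contributing cells)
  ph <- list()
  for (k in cyc) {
    tp <- cycle_peak_times(series, k)
    if (length(tp) >= 2L)
      ph[[as.character(k)]] <- wrap_phase((mean(tp) - tp) * 2 * pi / tau)
  }
  ks <- as.integer(names(ph))
  samples <- numeric(0)
  for (j in seq_along(ks)) {
    if (!((ks[j] + 1L) %in% ks)) next
    a <- ph[[as.character(ks[j])]]
    b <- ph[[as.character(ks[j] + 1L)]]
    common <- intersect(names(a), names(b))
    samples <- c(samples, wrap_phase(b[common] - a[common]))
  }
  if (length(samples) < 5L)
    stop("fewer than 5 pooled phase-increment samples")
  structure(list(samples = unname(samples), T = tau, n = length(samples)),
            class = "phase_increments")
}

#' Unbiased moment estimates (h-statistics)
#'
#' Sample central moments `m2`, `m4` and the unbiased estimators
#' `h2 = n m2 / (n - 1)` (variance) and the fourth h-statistic
#' `h4 = [3 (3 - 2n) n^2 m2^2 + n^2 (n^2 - 2n + 3) m4] /
#'        [(n - 1)(n - 2)(n - 3) n]`
#' of the fourth central moment.
#'
#' @param samples a `phase_increments` object or numeric vector (n >= 5).
#' @return an object of class `moment_estimates`: list with `m`, `m2`,
#'   `m4`, `h2`, `h4`, `n`.
#' @export
h_statistics <- function(samples) {
  x <- if (inherits(samples, "phase_increments")) samples$samples
       else as.numeric(samples)
  n <- length(x)
  if (n < 5L) stop("need at least 5 samples (h4 requires n >= 4)")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m4 <- mean((x - m)^4)
  h2 <- n * m2 / (n - 1)
  h4 <- (3 * (3 - 2 * n) * n^2 * m2^2 + n^2 * (n^2 - 2 * n + 3) * m4) /
    ((n - 1) * (n - 2) * (n - 3) * n)
  structure(list(m = m, m2 = m2, m4 = m4, h2 = h2, h4 = h4, n = n),
            class = "moment_estimates")
}

#' Interval estimates of coupling and noise strength
#'
#' Closed-form bounds for the one-community model.  From the Taylor
#' truncation of the sine drift, the noise strength is bounded by
#' `D-^2 = h2 (1 + 2 K r T) / T - 2 K r h4 / 6` and
#' `D+^2 = h2 (1 + 2 K r T) / T`; inserting `K = C D / 2` (from the
#' concentration relation `C = 2 K / D`) and solving the resulting
#' quadratics for `K` gives
#' `K+ = (C^2 h2 r + sqrt(C^4 h2^2 r^2 + 4 C^2 h2 / T)) / 4` and
#' `K- = (C^2 r (6 h2 - h4) + sqrt(C^4 (6 h2 - h4)^2 r^2 +
#'        144 C^2 h2 / T)) / 24`,
#' with `D± = 2 K± / C`.
#'
#' @param C concentration from [solve_concentration()].
#' @param moments a `moment_estimates` (needs `h2 > 0`).
#' @param T period of the average phase (h).
#' @param r order parameter used for `C`.
#' @return an object of class `one_community_bounds`: list with `r`, `C`,
#'   `K_minus`, `K_plus`, `D_minus`, `D_plus`, `n_samples`, `T`.
#' @export
coupling_and_noise_bounds <- function(C, moments, T, r) {
  stopifnot(inherits(moments, "moment_estimates"))
  if (!is.finite(C) || C <= 0) stop("'C' must be positive")
  if (moments$h2 <= 0) stop("need h2 > 0")
  if (T <= 0) stop("'T' must be positive")
  h2 <- moments$h2; h4 <- moments$h4
  K_plus <- (C^2 * h2 * r +
             sqrt(C^4 * h2^2 * r^2 + 4 * C^2 * h2 / T)) / 4
  g <- 6 * h2 - h4
  K_minus <- (C^2 * r * g +
              sqrt(C^4 * g^2 * r^2 + 144 * C^2 * h2 / T)) / 24
  structure(list(r = r, C = C,
                 K_minus = K_minus, K_plus = K_plus,
                 D_minus = 2 * K_minus / C, D_plus = 2 * K_plus / C,
                 n_samples = moments$n, T = T),
            class = "one_community_bounds")
}

#' @export
print.one_community_bounds <- function(x, ...) {
  cat("One-community coupling/noise bounds (r = ", round(x$r, 3),
      ", C = ", round(x$C, 3), ", n = ", x$n_samples, ")\n",
      "  K in [", round(x$K_minus, 3), ", ", round(x$K_plus, 3), "]",
      "   D in [", round(x$D_minus, 3), ", ", round(x$D_plus, 3), "]\n",
      sep = "")
  invisible(x)
}

#' Estimate coupling/noise bounds from a peak series
#'
#' Convenience wrapper running the full one-community inference on a
#' filtered peak series: order parameter at `cycle`, concentration from
#' the Bessel-ratio self-consistency, pooled phase increments, unbiased
#' moments, and the closed-form bounds.
#'
#' @param series a filtered `peak_series`.
#' @param cycle cycle index used for the order parameter.
#' @return a `one_community_bounds` object.
#' @export
estimate_coupling_bounds <- function(series, cycle = 2L) {
  r <- order_parameter(relative_phases(series, cycle))
  C <- solve_concentration(r)
  mom <- h_statistics(phase_increments(series))
  coupling_and_noise_bounds(C, mom, series$tau, r)
}
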