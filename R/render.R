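#' Options for rendering phases as bioluminescence traces
#'
#' The phase-to-intensity map is a raised cosine:
#' `I_i(t) = baseline_i + amplitude_i (1 + cos theta_i(t)) / 2 + eps`,
#' with cell-specific baselines and amplitudes and Gaussian measurement
#' noise `eps`.  Peaks of the noiseless waveform fall where
#' `theta_i = 0 (mod 2 pi)`.  Defaults emulate single-cell PER2::LUC
#' recordings sampled once per hour (arbitrary camera units; amplitude
#' about twice the baseline and 5% measurement noise).
#'
#' @param baseline_mean,baseline_sd mean and cell-to-cell spread of the
#'   baseline (a.u.).
#' @param amplitude_mean,amplitude_sd mean and spread of the oscillation
#'   amplitude (a.u.); `amplitude_mean` must be positive.  Non-positive
#'   amplitude draws are clipped at 1% of `amplitude_mean`.
#' @param noise_sd standard deviation of additive measurement noise (a.u.).
#' @param interval_h sampling interval in hours (> 0).
#' @param phase_integration_h reporter integration window (h): the
#'   luminescence signal follows a centred moving average of the
#'   oscillator phase over this window, modelling the low-pass effect of
#'   transcription-to-luciferase protein dynamics.  Raw SDE phases are
#'   white-noise rough at the integration step; real reporter traces are
#'   smooth within a cycle while still diffusing across cycles, which
#'   this reproduces.  Set to 0 for instantaneous rendering.
#' @return an object of class `render_options`.
#' @export
render_options <- function(baseline_mean = 100, baseline_sd = 20,
                           amplitude_mean = 200, amplitude_sd = 40,
                           noise_sd = 2, interval_h = 1,
                           phase_integration_h = 6) {
  if (amplitude_mean <= 0) stop("'amplitude_mean' must be positive")
  if (interval_h <= 0) stop("'interval_h' must be positive")
  if (noise_sd < 0 || baseline_sd < 0 || amplitude_sd < 0)
    stop("spreads must be non-negative")
  if (phase_integration_h < 0) stop("'phase_integration_h' must be >= 0")
  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 noise_sd = noise_sd, interval_h = interval_h,
                 phase_integration_h = phase_integration_h),
            class = "render_options")
}

## phases after the reporter low-pass of the render options
integrated_phases <- function(traj, integration_h) {
  if (!integration_h) return(traj$phases)
  dt <- traj$times[2L] - traj$times[1L]
  k <- round(integration_h / dt)
  if (k %% 2L == 0L) k <- k + 1L
  if (k <= 1L) return(traj$phases)
  t(apply(traj$phases, 1L, moving_average, k = k))
}

#' Render a phase trajectory as bioluminescence traces
#'
#' Samples each oscillator's unwrapped phase at the requested interval
#' (linear interpolation between integration steps) and applies the raised
#' cosine map of [render_options()].
#'
#' @param traj a `phase_trajectory`.
#' @param opts a [render_options()] object.
#' @param seed integer seed for baseline/amplitude draws and measurement
#'   noise (defaults to the trajectory's simulation seed + 1).
#' @param metadata slice metadata list passed to [scn_traces()].
#' @return an `scn_traces` object.
#' @export
render_bioluminescence <- function(traj, opts = render_options(),
                                   seed = NULL, metadata = list()) {
  stopifnot(inherits(traj, "phase_trajectory"),
            inherits(opts, "render_options"))
  if (length(traj$times) < 2L) stop("empty trajectory")
  if (is.null(seed)) seed <- traj$params$seed + 1L
  n <- nrow(traj$phases)
  tout <- seq(traj$times[1L], traj$times[length(traj$times)],
              by = opts$interval_h)
  set.seed(seed)
  baseline <- stats::rnorm(n, opts$baseline_mean, opts$baseline_sd)
  amplitude <- stats::rnorm(n, opts$amplitude_mean, opts$amplitude_sd)
  amplitude <- pmax(amplitude, 0.01 * opts$amplitude_mean)
  eps <- matrix(stats::rnorm(n * length(tout), 0, opts$noise_sd),
                n, length(tout))
  phi <- integrated_phases(traj, opts$phase_integration_h)
  ph <- t(apply(phi, 1L, function(th)
    stats::approx(traj$times, th, xout = tout)$y))
  inten <- baseline + amplitude * (1 + cos(ph)) / 2 + eps
  scn_traces(tout, inten, metadata = metadata)
}

#' Simulate a complete synthetic SCN slice fixture
#'
#' Convenience wrapper: simulate a one- or two-community phase trajectory,
#' render it as hourly bioluminescence traces, and keep the ground truth
#' (parameters, per-cycle order parameters, phase-zero crossing times and
#' community labels) alongside the traces.
#'
#' @param params a [one_community_params()] or [two_community_params()]
#'   object.
#' @param opts a [render_options()] object.
#' @param metadata slice metadata (`age`, `photoperiod`, `position`).
#' @param render_seed optional seed for the renderer.
#' @return an object of class `scn_slice`: list with `traces`, `truth`
#'   (params, labels, crossings, cycle order parameters) and `metadata`.
#' @export
simulate_scn_slice <- function(params, opts = render_options(),
                               metadata = list(), render_seed = NULL) {
  traj <- if (inherits(params, "two_community_params"))
    simulate_two_community(params) else simulate_one_community(params)
  traces <- render_bioluminescence(traj, opts, seed = render_seed,
                                   metadata = metadata)
  cyc_idx <- which(traj$times %% traj$params$tau == 0)
  rmat <- trajectory_order_parameter(traj, by_community = TRUE)
  truth <- list(params = traj$params,
                community_labels = traj$community_labels,
                crossings = phase_zero_crossings(traj,
                                                 opts$phase_integration_h),
                cycle_order_parameters = trajectory_order_parameter(traj)[cyc_idx],
                cycle_r_by_community = rmat[, cyc_idx, drop = FALSE])
  structure(list(traces = traces, truth = truth, metadata = metadata),
            class = "scn_slice")
}

#' @export
print.scn_slice <- function(x, ...) {
  cat("Synthetic SCN slice fixture\n")
  print(x$traces)
  r <- x$truth$cycle_order_parameters
  cat("  ground-truth order parameter (last cycle):",
      round(r[length(r)], 3), "\n")
  invisible(x)
}

#' Calibrate two-community parameters to target order parameters
#'
#' Inverse use of the two-community self-consistency relations: given
#' target stationary order parameters `(r1, r2)` and a chosen
#' cross-coupling `L` (used for both directions), place `(K1, K2)` on the
#' implied coupling lines so that simulation reproduces the targets:
#' `K_c = (x_c - L r_other) / r_c` with `V(x_c) = r_c` and `D = 1`.
#'
#' @param r1_target,r2_target target order parameters in (0, 1).
#' @param L_choice cross-community coupling used for both `L1` and `L2`.
#' @param n_per_community,n_cycles,seed,... forwarded to
#'   [two_community_params()].
#' @return a `two_community_params` object lying on the condition lines.
#' @export
calibrate_condition <- function(r1_target, r2_target, L_choice = 1,
                                n_per_community = 250, n_cycles = 20,
                                seed = 1L, ...) {
  for (r in c(r1_target, r2_target))
    if (!is.finite(r) || r <= 0 || r >= 1)
      stop("target order parameters must lie strictly in (0, 1)")
  x1 <- bessel_ratio_inverse(r1_target)
  x2 <- bessel_ratio_inverse(r2_target)
  K1 <- (x1 - L_choice * r2_target) / r1_target
  K2 <- (x2 - L_choice * r1_target) / r2_target
  if (K1 < 0 || K2 < 0)
    stop("L_choice too large: implied within-community coupling is negative")
  two_community_params(n_per_community = n_per_community, K1 = K1, K2 = K2,
                       L1 = L_choice, L2 = L_choice, D = 1,
                       n_cycles = n_cycles, seed = seed, ...)
}

#' Write a slice fixture to plain-text files
#'
#' Writes the trace CSV (`<stem>_traces.csv`), a community label CSV
#' (`<stem>_labels.csv`: cell_id, community) and a ground-truth/metadata
#' JSON sidecar (`<stem>_truth.json`).
#'
#' @param slice an `scn_slice`.
#' @param stem path stem for the three files.
#' @return invisibly, the three paths.
#' @export
write_slice_fixture <- function(slice, stem) {
  stopifnot(inherits(slice, "scn_slice"))
  paths <- paste0(stem, c("_traces.csv", "_labels.csv", "_truth.json"))
  write_traces(slice$traces, paths[1L])
  utils::write.csv(data.frame(cell_id = slice$traces$cell_ids,
                              community = slice$truth$community_labels),
                   paths[2L], row.names = FALSE)
  tr <- slice$truth
  jsonlite::write_json(list(metadata = slice$metadata,
                            params = unclass(tr$params),
                            cycle_order_parameters = tr$cycle_order_parameters),
                       paths[3L], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
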