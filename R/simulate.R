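#' Parameters for a one-community noisy Kuramoto simulation
#'
#' The model is `dtheta_i = (K/N) sum_j sin(theta_j - theta_i) dt + D dW_i`,
#' simulated in the lab frame with a common natural frequency `2*pi/tau`
#' (equivalent to the rotating-frame model because all oscillators share
#' the frequency).
#'
#' @param n_oscillators number of oscillators (>= 2).
#' @param K within-community coupling strength (phase units per hour, >= 0).
#' @param D noise strength, the diffusion amplitude of the phase Brownian
#'   term (rad / sqrt(h), >= 0).
#' @param tau intrinsic period in hours.
#' @param dt Euler--Maruyama step in hours; must satisfy `dt <= tau/100`.
#' @param n_cycles number of periods to simulate.
#' @param seed master integer seed; per-oscillator noise substreams are
#'   derived from it so that adding oscillators does not perturb the noise
#'   stream of existing ones.
#' @param init_sd standard deviation (rad) of the wrapped-normal initial
#'   phase distribution around `init_mean`.
#' @param init_mean mean initial phase (rad).
#' @return an object of class `one_community_params`.
#' @export
one_community_params <- function(n_oscillators = 100, K = 2, D = 1,
                                 tau = 24, dt = tau / 200, n_cycles = 10,
                                 seed = 1L, init_sd = 1, init_mean = 0) {
  p <- list(n_oscillators = as.integer(n_oscillators), K = K, D = D,
            tau = tau, dt = dt, n_cycles = as.integer(n_cycles),
            seed = as.integer(seed), init_sd = init_sd,
            init_mean = init_mean)
  validate_sim_params(p, two = FALSE)
  class(p) <- "one_community_params"
  p
}

#' Parameters for a two-community noisy Kuramoto simulation
#'
#' Two labelled communities of `n_per_community` oscillators each.  Within
#' community c the coupling is `K_c`; the cross-community coupling into
#' community 1 is `L1` (from community 2) and into community 2 is `L2`.
#' Both the within- and between-community mean fields are divided by the
#' total population `2N`, matching the mean-field convention of the
#' governing equations.  The community mean phases are assumed equal
#' (`psi1 = psi2 = 0`); `init_offset` only offsets the *initial* phases of
#' community 2, which is useful for community-detection fixtures.
#'
#' @param n_per_community oscillators per community (>= 2).
#' @param K1,K2 within-community coupling strengths (>= 0).
#' @param L1,L2 between-community coupling strengths (any sign; negative
#'   values are repulsive).
#' @param init_offset initial mean phase of community 2 relative to
#'   community 1 (rad); the model assumption remains psi1 = psi2 = 0.
#' @inheritParams one_community_params
#' @return an object of class `two_community_params`.
#' @export
two_community_params <- function(n_per_community = 100, K1 = 2, K2 = 2,
                                 L1 = 0, L2 = 0, D = 1, tau = 24,
                                 dt = tau / 200, n_cycles = 10, seed = 1L,
                                 init_sd = 1, init_offset = 0) {
  p <- list(n_per_community = as.integer(n_per_community),
            K1 = K1, K2 = K2, L1 = L1, L2 = L2, D = D, tau = tau, dt = dt,
            n_cycles = as.integer(n_cycles), seed = as.integer(seed),
            init_sd = init_sd, init_offset = init_offset)
  validate_sim_params(p, two = TRUE)
  class(p) <- "two_community_params"
  p
}

validate_sim_params <- function(p, two) {
  num <- if (two) c("K1", "K2", "L1", "L2", "D", "tau", "dt") else
    c("K", "D", "tau", "dt")
  for (f in num)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]))
      stop("parameter '", f, "' must be a finite numeric scalar")
  if (!two && p$K < 0) stop("'K' must be non-negative")
  if (two && (p$K1 < 0 || p$K2 < 0))
    stop("within-community couplings must be non-negative")
  if (p$D < 0) stop("'D' must be non-negative")
  if (p$tau <= 0 || p$dt <= 0) stop("'tau' and 'dt' must be positive")
  if (p$dt > p$tau / 100)
    stop("integration step too coarse: need dt <= tau/100")
  n <- if (two) p$n_per_community else p$n_oscillators
  if (is.na(n) || n < 2L) stop("need at least 2 oscillators")
  if (p$n_cycles < 1L) stop("'n_cycles' must be positive")
  invisible(p)
}

## Per-oscillator noise substreams: the master seed draws one sub-seed per
## oscillator; each oscillator's initial deviate and Brownian increments come
## from its own stream.  Adding oscillators leaves earlier streams intact
## (trajectories still change through the mean field, which is unavoidable).
oscillator_noise <- function(seed, n_osc, n_steps) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, n_osc)
  z0 <- numeric(n_osc)
  dW <- matrix(0, n_osc, n_steps)
  for (i in seq_len(n_osc)) {
    set.seed(sub[i])
    z <- stats::rnorm(n_steps + 1L)
    z0[i] <- z[1L]
    dW[i, ] <- z[-1L]
  }
  list(z0 = z0, dW = dW)
}

#' Simulate a one-community noisy Kuramoto network
#'
#' Euler--Maruyama integration of the mean-field phase model in the lab
#' frame: every oscillator advances at `2*pi/tau` plus the coupling drift
#' `K R sin(psi - theta_i)` (with `R e^{i psi}` the population mean phasor)
#' plus white phase noise of strength `D`.
#'
#' @param params a [one_community_params()] object.
#' @return an object of class `phase_trajectory`: list with `times` (h),
#'   `phases` (oscillators x times, unwrapped rad), `community_labels`
#'   (all 1), and `params`.
#' @examples
#' traj <- simulate_one_community(one_community_params(n_oscillators = 20,
#'   K = 2, D = 0.5, n_cycles = 3, seed = 42))
#' @export
simulate_one_community <- function(params) {
  stopifnot(inherits(params, "one_community_params"))
  p <- params
  n_steps <- round(p$n_cycles * p$tau / p$dt)
  noise <- oscillator_noise(p$seed, p$n_oscillators, n_steps)
  theta <- p$init_mean + p$init_sd * noise$z0
  out <- matrix(0, p$n_oscillators, n_steps + 1L)
  out[, 1L] <- theta
  omega <- 2 * pi / p$tau
  sdt <- sqrt(p$dt)
  for (s in seq_len(n_steps)) {
    ms <- mean(sin(theta)); mc <- mean(cos(theta))
    drift <- omega + p$K * (ms * cos(theta) - mc * sin(theta))
    theta <- theta + drift * p$dt + p$D * sdt * noise$dW[, s]
    out[, s + 1L] <- theta
  }
  structure(list(times = (0:n_steps) * p$dt, phases = out,
                 community_labels = rep(1L, p$n_oscillators),
                 params = p),
            class = "phase_trajectory")
}

#' Simulate a two-community noisy Kuramoto network
#'
#' As [simulate_one_community()], with within-community couplings `K1`,
#' `K2` and cross couplings `L1`, `L2`, all divided by the total population
#' `2N`.  Oscillators `1..N` belong to community 1 and `N+1..2N` to
#' community 2.
#'
#' @param params a [two_community_params()] object.
#' @return a `phase_trajectory` with `community_labels` in `{1, 2}`.
#' @export
simulate_two_community <- function(params) {
  stopifnot(inherits(params, "two_community_params"))
  p <- params
  N <- p$n_per_community
  n_steps <- round(p$n_cycles * p$tau / p$dt)
  noise <- oscillator_noise(p$seed, 2L * N, n_steps)
  i1 <- seq_len(N); i2 <- N + i1
  theta <- p$init_sd * noise$z0
  theta[i2] <- theta[i2] + p$init_offset
  out <- matrix(0, 2L * N, n_steps + 1L)
  out[, 1L] <- theta
  omega <- 2 * pi / p$tau
  sdt <- sqrt(p$dt)
  for (s in seq_len(n_steps)) {
    t1 <- theta[i1]; t2 <- theta[i2]
    s1 <- mean(sin(t1)); c1 <- mean(cos(t1))
    s2 <- mean(sin(t2)); c2 <- mean(cos(t2))
    ## (1/2N) sum_{j in c} sin(theta_j - theta) = (1/2) [s_c cos(theta) - c_c sin(theta)]
    d1 <- omega + (p$K1 * (s1 * cos(t1) - c1 * sin(t1)) +
                   p$L1 * (s2 * cos(t1) - c2 * sin(t1))) / 2
    d2 <- omega + (p$K2 * (s2 * cos(t2) - c2 * sin(t2)) +
                   p$L2 * (s1 * cos(t2) - c1 * sin(t2))) / 2
    theta <- theta + c(d1, d2) * p$dt + p$D * sdt * noise$dW[, s]
    out[, s + 1L] <- theta
  }
  structure(list(times = (0:n_steps) * p$dt, phases = out,
                 community_labels = rep(1:2, each = N), params = p),
            class = "phase_trajectory")
}

#' Instantaneous order parameter(s) of a phase trajectory
#'
#' @param traj a `phase_trajectory`.
#' @param by_community if `TRUE`, one row per community label.
#' @return numeric vector over time, or a matrix (communities x times).
#' @export
trajectory_order_parameter <- function(traj, by_community = FALSE) {
  stopifnot(inherits(traj, "phase_trajectory"))
  op <- function(m) Mod(colMeans(exp(1i * m)))
  if (!by_community) return(op(traj$phases))
  labs <- sort(unique(traj$community_labels))
  t(vapply(labs, function(l) op(traj$phases[traj$community_labels == l, ,
                                            drop = FALSE]),
           numeric(ncol(traj$phases))))
}

#' Stationary self-consistent order parameters of the two-community model
#'
#' Fixed-point iteration on `r1 = V((K1 r1 + L1 r2)/D)`,
#' `r2 = V((K2 r2 + L2 r1)/D)` in the infinite-oscillator limit.
#' Used as the analytic reference for simulated two-community runs.
#'
#' @param K1,K2,L1,L2,D model parameters.
#' @param tol convergence tolerance; `max_iter` iteration cap.
#' @param r_init starting values.
#' @return named vector `c(r1, r2)`; the incoherent solution `(0, 0)` is
#'   returned if iteration collapses to it.
#' @export
two_community_fixed_point <- function(K1, L1, K2, L2, D = 1,
                                      tol = 1e-12, max_iter = 10000,
                                      r_init = c(0.9, 0.9)) {
  r <- r_init
  for (it in seq_len(max_iter)) {
    a1 <- (K1 * r[1] + L1 * r[2]) / D
    a2 <- (K2 * r[2] + L2 * r[1]) / D
    rn <- c(bessel_ratio(max(a1, 0)), bessel_ratio(max(a2, 0)))
    if (max(abs(rn - r)) < tol) return(c(r1 = rn[1], r2 = rn[2]))
    r <- rn
  }
  warning("fixed-point iteration did not converge")
  c(r1 = r[1], r2 = r[2])
}

#' Ground-truth phase-zero crossing times
#'
#' Upward crossings of `theta = 0 (mod 2*pi)` of the unwrapped phases,
#' located by linear interpolation between integration steps.  These are
#' the times where the noiseless raised-cosine waveform peaks.  When the
#' renderer applies a reporter integration window, pass the same window
#' here so the crossings refer to the phase that actually drives the
#' waveform.
#'
#' @param traj a `phase_trajectory`.
#' @param integration_h reporter integration window (h, default 0: raw
#'   phases); see [render_options()].
#' @return list (one element per oscillator) of crossing times in hours.
#' @export
phase_zero_crossings <- function(traj, integration_h = 0) {
  stopifnot(inherits(traj, "phase_trajectory"))
  tt <- traj$times
  ph <- integrated_phases(traj, integration_h)
  apply(ph, 1L, function(th) {
    lv <- 2 * pi * seq(ceiling(min(th) / (2 * pi)),
                       floor(max(th) / (2 * pi)))
    unlist(lapply(lv, function(l) {
      up <- which(th[-length(th)] < l & th[-1L] >= l)
      if (!length(up)) return(numeric(0))
      j <- up[1L]
      tt[j] + (l - th[j]) / (th[j + 1L] - th[j]) * (tt[j + 1L] - tt[j])
    }))
  }, simplify = FALSE)
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat("Phase trajectory:", nrow(x$phases), "oscillators,",
      length(x$times), "time points over",
      round(max(x$times), 2), "h\n")
  r <- trajectory_order_parameter(x)
  cat("  final instantaneous order parameter:", round(r[length(r)], 3), "\n")
  invisible(x)
}
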