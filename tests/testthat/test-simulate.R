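test_that("parameter validation rejects bad inputs", {
  expect_error(one_community_params(K = NA), "finite")
  expect_error(one_community_params(K = -1), "non-negative")
  expect_error(one_community_params(dt = 1), "too coarse")
  expect_error(one_community_params(n_oscillators = 1), "at least 2")
  expect_error(two_community_params(K1 = -0.1), "non-negative")
})

test_that("noiseless synchronized state is a fixed point with r = 1", {
  p <- one_community_params(n_oscillators = 10, K = 1, D = 0,
                            n_cycles = 2, init_sd = 0, seed = 3)
  traj <- simulate_one_community(p)
  # all phases stay identical at every step
  expect_true(all(apply(traj$phases, 2L, function(c) diff(range(c))) < 1e-12))
  expect_true(all(abs(trajectory_order_parameter(traj) - 1) < 1e-12))
})

test_that("free rotation advances phases exactly linearly at 2*pi/tau", {
  p <- one_community_params(n_oscillators = 5, K = 0, D = 0,
                            n_cycles = 2, tau = 24, seed = 11)
  traj <- simulate_one_community(p)
  expected <- outer(traj$phases[, 1L], rep(1, length(traj$times))) +
    rep(2 * pi / 24, 5) %o% traj$times
  expect_equal(traj$phases, expected, tolerance = 1e-10)
})

test_that("identical seeds give bit-identical trajectories", {
  p <- one_community_params(n_oscillators = 20, K = 1.5, D = 0.8,
                            n_cycles = 3, seed = 99)
  expect_identical(simulate_one_community(p), simulate_one_community(p))
  q <- two_community_params(n_per_community = 15, K1 = 2, K2 = 1,
                            L1 = 0.5, L2 = -0.5, D = 0.7, n_cycles = 3,
                            seed = 7)
  expect_identical(simulate_two_community(q), simulate_two_community(q))
})

test_that("with K = 0 phase increments diffuse with variance D^2 dt", {
  D <- 0.7
  p <- one_community_params(n_oscillators = 100, K = 0, D = D,
                            n_cycles = 4, seed = 21)
  traj <- simulate_one_community(p)
  dinc <- t(diff(t(traj$phases))) - 2 * pi / p$tau * p$dt
  v <- stats::var(as.vector(dinc))
  expect_equal(v, D^2 * p$dt, tolerance = 0.02)
})

test_that("noiseless coupling monotonically increases coherence", {
  p <- one_community_params(n_oscillators = 50, K = 1, D = 0,
                            n_cycles = 4, init_sd = 1.5, seed = 13)
  r <- trajectory_order_parameter(simulate_one_community(p))
  expect_true(all(diff(r) > -1e-6))
  expect_gt(r[length(r)], r[1L])
})

test_that("sub- and super-critical regimes sit on either side of C = 2", {
  # C = 2K/D = 1 < 2: incoherent up to the finite-size noise floor
  p <- one_community_params(n_oscillators = 400, K = 0.5, D = 1,
                            n_cycles = 15, dt = 24 / 100, seed = 31)
  r <- trajectory_order_parameter(simulate_one_community(p))
  tail_r <- mean(r[round(length(r) / 2):length(r)])
  expect_lt(tail_r, 3 / sqrt(400) + 0.1)
})

test_that("stationary order parameter matches the mean-field fixed point", {
  # K = 2, D = 1: r* solves r = V(2 K r), bisection oracle
  f <- function(r) bessel_ratio(4 * r) - r
  lo <- 0.5; hi <- 0.99
  for (i in 1:50) { mid <- (lo + hi) / 2; if (f(mid) > 0) lo <- mid else hi <- mid }
  r_star <- (lo + hi) / 2
  expect_equal(r_star, 0.83, tolerance = 0.01)
  p <- one_community_params(n_oscillators = 500, K = 2, D = 1,
                            n_cycles = 40, seed = 41)
  r <- trajectory_order_parameter(simulate_one_community(p))
  burn <- round(length(r) / 4)
  expect_equal(mean(r[burn:length(r)]), r_star, tolerance = 0.03)
  expect_gt(mean(r[burn:length(r)]), r_star - 0.05)
})

test_that("decoupled communities behave like independent one-community runs", {
  # within divisor is 2N, so K1 = 4 in the two-community model matches
  # K = 2 in the one-community model
  q <- two_community_params(n_per_community = 250, K1 = 4, K2 = 4,
                            L1 = 0, L2 = 0, D = 1, n_cycles = 12, seed = 5)
  rt <- trajectory_order_parameter(simulate_two_community(q),
                                   by_community = TRUE)
  p <- one_community_params(n_oscillators = 250, K = 2, D = 1,
                            n_cycles = 12, seed = 6)
  r1c <- trajectory_order_parameter(simulate_one_community(p))
  burn <- round(ncol(rt) / 2)
  sel <- burn:ncol(rt)
  expect_equal(mean(rt[1L, sel]), mean(r1c[sel]), tolerance = 0.05)
  expect_equal(mean(rt[2L, sel]), mean(r1c[sel]), tolerance = 0.05)
})

test_that("exchangeable communities reach equal long-run coherence", {
  q <- two_community_params(n_per_community = 200, K1 = 3, K2 = 3,
                            L1 = 3, L2 = 3, D = 1, n_cycles = 12, seed = 17)
  rt <- trajectory_order_parameter(simulate_two_community(q),
                                   by_community = TRUE)
  sel <- round(ncol(rt) / 2):ncol(rt)
  expect_equal(mean(rt[1L, sel]), mean(rt[2L, sel]), tolerance = 0.05)
})

test_that("calibrated parameters land on the condition lines", {
  p <- calibrate_condition(0.77, 0.81, L_choice = 0)
  # with L = 0 the within coupling is the line intercept C(r)/r at D = 1
  expect_equal(p$K1, solve_concentration(0.77), tolerance = 1e-10)
  expect_equal(p$K2, solve_concentration(0.81), tolerance = 1e-10)
  p2 <- calibrate_condition(0.94, 0.94, L_choice = 1)
  expect_equal(p2$K1, p2$K2, tolerance = 1e-12)
  # returned parameters satisfy the self-consistency relations exactly
  on_lines <- function(par, r1, r2) {
    expect_lt(abs(bessel_ratio(par$K1 * r1 + par$L1 * r2) - r1), 1e-9)
    expect_lt(abs(bessel_ratio(par$K2 * r2 + par$L2 * r1) - r2), 1e-9)
  }
  on_lines(p, 0.77, 0.81)
  on_lines(p2, 0.94, 0.94)
  expect_error(calibrate_condition(1.2, 0.5), "strictly")
})
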