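test_that("h-statistics match hand evaluation and vanish on constants", {
  h <- h_statistics(c(-1, 0, 0, 1, 0))
  expect_equal(h$n, 5L)
  hc <- h_statistics(rep(2.5, 8))
  expect_equal(hc$h2, 0)
  expect_equal(hc$h4, 0)
  # hand evaluation for {-1, 0, 0, 1} embedded at n = 4 is below the n >= 5
  # guard, so evaluate the formula pieces directly at n = 4 via moments
  x <- c(-1, 0, 0, 1)
  n <- 4; m2 <- 0.5; m4 <- 0.5
  h2 <- n * m2 / (n - 1)
  h4 <- (3 * (3 - 2 * n) * n^2 * m2^2 + n^2 * (n^2 - 2 * n + 3) * m4) /
    ((n - 1) * (n - 2) * (n - 3) * n)
  expect_equal(h2, 2 / 3, tolerance = 1e-12)
  expect_equal(h4, 28 / 24, tolerance = 1e-12)
  expect_error(h_statistics(1:4), "at least 5")
})

test_that("h2 and h4 are unbiased for the normal second and fourth moments", {
  set.seed(12)
  reps <- 2000; n <- 20
  x <- matrix(rnorm(reps * n), n)
  h2s <- apply(x, 2, function(v) h_statistics(v)$h2)
  h4s <- apply(x, 2, function(v) h_statistics(v)$h4)
  expect_lt(abs(mean(h2s) - 1), 3 * sd(h2s) / sqrt(reps))
  expect_lt(abs(mean(h4s) - 3), 3 * sd(h4s) / sqrt(reps))
})

test_that("phase increments vanish for rigid offsets and track drift", {
  # fixed phase offsets, perfectly periodic: all increments zero
  tp <- outer(c(0, 1, 2, 3), rep(1, 5)) + rep(24 * (0:4), each = 4)
  s <- make_series(tp, tau = 24)
  inc <- phase_increments(s)
  expect_true(all(abs(inc$samples) < 1e-12))
  expect_equal(inc$n, 16L)
  expect_equal(inc$T, 24)
  # one cell drifting +1 h per cycle against a synchronized pool of 30
  pool <- matrix(rep(24 * (0:4), each = 30), 30)
  drift <- 24 * (0:4) + 0:4
  s2 <- make_series(rbind(pool, drift), tau = 24)
  inc2 <- phase_increments(s2)
  drift_samples <- inc2$samples[abs(inc2$samples) > 1e-9]
  # the drifting cell appears once per cycle pair, shifted by ~ -2 pi / 24
  drifter <- drift_samples[drift_samples < -0.1]
  expect_length(drifter, 4L)
  expect_lt(max(abs(drifter - (-2 * pi / 24))), 0.012)
})

test_that("stationary fixtures have near-zero mean phase increment", {
  sl <- quick_slice(K = 2, D = 1, n = 60, n_cycles = 8, seed = 23)
  fitp <- filter_cells(detect_peaks(smooth_and_resample(sl$traces)))
  inc <- phase_increments(fitp)
  expect_lt(abs(mean(inc$samples)), 0.08)
})

test_that("coupling bounds are ordered and match quadratic root-finding", {
  set.seed(77)
  for (i in 1:200) {
    h2 <- runif(1, 0.01, 2)
    h4 <- runif(1, 0, 12 * h2)
    C <- runif(1, 0.3, 10)
    r <- runif(1, 0.05, 0.95)
    T <- runif(1, 20, 28)
    mom <- structure(list(m = 0, m2 = h2, m4 = h4, h2 = h2, h4 = h4,
                          n = 100L), class = "moment_estimates")
    b <- coupling_and_noise_bounds(C, mom, T, r)
    expect_lte(b$K_minus, b$K_plus)
    expect_lte(b$D_minus, b$D_plus)
    expect_gte(b$K_minus, 0)
    # independent oracle: positive roots of the two quadratics
    # 4K^2 - 2C^2 h2 r K - C^2 h2 / T = 0   (upper)
    # 12K^2 - C^2 r (6h2 - h4) K - 3 C^2 h2 / T = 0   (lower)
    up <- max(Re(polyroot(c(-C^2 * h2 / T, -2 * C^2 * h2 * r, 4))))
    lo <- max(Re(polyroot(c(-3 * C^2 * h2 / T, -C^2 * r * (6 * h2 - h4),
                            12))))
    expect_equal(b$K_plus, up, tolerance = 1e-10)
    expect_equal(b$K_minus, lo, tolerance = 1e-10)
    # D bounds follow from the concentration relation C = 2K/D
    expect_equal(b$D_minus, 2 * b$K_minus / C, tolerance = 1e-12)
  }
})

test_that("h4 = 6 h2 collapses the lower bound to its closed form", {
  h2 <- 0.4; h4 <- 6 * h2; C <- 3; T <- 24; r <- 0.8
  mom <- structure(list(m = 0, m2 = h2, m4 = h4, h2 = h2, h4 = h4,
                        n = 50L), class = "moment_estimates")
  b <- coupling_and_noise_bounds(C, mom, T, r)
  expect_equal(b$K_minus, C * sqrt(h2 / T) / 2, tolerance = 1e-12)
  expect_lte(b$K_minus, b$K_plus)
})

test_that("both bounds shrink as the period grows", {
  h2 <- 0.5; h4 <- 0.7; C <- 4; r <- 0.85
  mom <- structure(list(m = 0, m2 = h2, m4 = h4, h2 = h2, h4 = h4,
                        n = 50L), class = "moment_estimates")
  Ts <- seq(20, 28, by = 2)
  km <- vapply(Ts, function(T)
    coupling_and_noise_bounds(C, mom, T, r)$K_minus, numeric(1))
  kp <- vapply(Ts, function(T)
    coupling_and_noise_bounds(C, mom, T, r)$K_plus, numeric(1))
  expect_true(all(diff(km) < 0))
  expect_true(all(diff(kp) < 0))
})

test_that("the full estimator runs end to end on a rendered fixture", {
  sl <- quick_slice(K = 2, D = 1, n = 60, n_cycles = 8, seed = 33)
  ser <- filter_cells(detect_peaks(smooth_and_resample(sl$traces)))
  b <- estimate_coupling_bounds(ser)
  expect_s3_class(b, "one_community_bounds")
  expect_true(b$K_minus <= b$K_plus)
  expect_true(b$D_minus <= b$D_plus)
  expect_true(b$r > 0.3 && b$r < 1)
})
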