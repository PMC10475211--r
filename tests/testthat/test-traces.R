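test_that("trace container enforces a uniform grid and finite values", {
  expect_error(scn_traces(c(0, 1, 3), matrix(1, 2, 3)), "non-uniform")
  expect_error(scn_traces(1:3, matrix(c(1, NA), 2, 3)), "finite")
  expect_error(scn_traces(1:3, matrix(1, 1, 3)), "2 cells")
  expect_error(scn_traces(1:3, matrix(1, 2, 3),
                          metadata = list(age = "teen")), "age")
})

test_that("trace CSV round-trips", {
  tr <- quick_slice(n = 5, n_cycles = 3)$traces
  f <- tempfile(fileext = ".csv")
  write_traces(tr, f)
  back <- read_traces(f)
  expect_equal(back$times, tr$times)
  expect_equal(unname(back$intensity), unname(tr$intensity),
               tolerance = 1e-12)
})

test_that("smoothing keeps constants and recovers cosine peak times", {
  times <- 0:96
  const <- scn_traces(times, matrix(5, 2, length(times)))
  sm <- smooth_and_resample(const)
  expect_true(all(abs(sm$intensity - 5) < 1e-9))
  expect_equal(diff(sm$times[1:2]) * 60, 1, tolerance = 1e-9)  # 1/min grid

  cosm <- scn_traces(times, rbind(10 + cos(2 * pi * times / 24),
                                  10 + cos(2 * pi * times / 24)))
  smc <- smooth_and_resample(cosm)
  # analytic maxima at t = 24, 48, 72; found maxima within 2 min
  for (t0 in c(24, 48, 72)) {
    win <- which(abs(smc$times - t0) <= 6)
    tmax <- smc$times[win][which.max(smc$intensity[1L, win])]
    expect_lt(abs(tmax - t0), 2 / 60)
  }
})

test_that("averaging contracts the variance of white noise", {
  set.seed(4)
  x <- matrix(rnorm(2 * 97), 2, 97)
  tr <- scn_traces(0:96, x)
  sm <- smooth_and_resample(tr)
  expect_lt(stats::var(sm$intensity[1L, ]), stats::var(x[1L, ]))
})

test_that("smoothing rejects records that are too short or windows too long", {
  tr <- scn_traces(0:40, matrix(rnorm(82), 2))
  expect_error(smooth_and_resample(tr), "48 h")
  tr2 <- scn_traces(0:96, matrix(rnorm(194), 2))
  expect_error(smooth_and_resample(tr2, window_h = 200), "window")
})

test_that("the inclusion filter applies the cycle and period rules", {
  tp <- rbind(c(0, 19.5, 39, 58.5, NA),       # period 19.5 h: dropped
              c(0, 24, 48, 72, NA),           # 3 cycles at 24 h: retained
              c(0, 24, 48, NA, NA),           # 2 cycles: dropped
              c(0, 28.5, 57, 85.5, NA),       # period 28.5: dropped
              c(1, 25, 49, 73, 97))           # 4 cycles at 24: retained
  s <- make_series(tp)
  f <- filter_cells(s)
  expect_setequal(f$cell_ids, c("cell_0002", "cell_0005"))
  expect_equal(unname(f$counts), c(2L, 3L))
  # idempotent
  expect_equal(filter_cells(f)$cell_ids, f$cell_ids)
  # all dropped -> explicit error
  expect_error(filter_cells(make_series(tp[3, , drop = FALSE])), "dropped")
})

test_that("peak-time dispersion is a plain standard deviation", {
  s <- make_series(rbind(c(0, 23), c(0, 24), c(0, 25)))
  expect_equal(peak_time_dispersion(s, 2), 1)
  s0 <- make_series(rbind(c(0, 24), c(0, 24), c(0, 24)))
  expect_equal(peak_time_dispersion(s0, 2), 0)
  # translation invariance
  s5 <- make_series(rbind(c(0, 23), c(0, 24), c(0, 25)) + 5)
  expect_equal(peak_time_dispersion(s5, 2), peak_time_dispersion(s, 2))
  expect_error(peak_time_dispersion(s, 7), "fewer than 2")
})

test_that("two interleaved cells 12 h apart keep separate peak series", {
  times <- seq(0, 96, by = 1)
  a <- 10 + 5 * cos(2 * pi * times / 24)
  b <- 10 + 5 * cos(2 * pi * (times - 12) / 24)
  tr <- scn_traces(times, rbind(a, b))
  pk <- detect_peaks(smooth_and_resample(tr))
  ta <- pk$peaks$peak_time_h[pk$peaks$cell_id == "cell_0001"]
  tb <- pk$peaks$peak_time_h[pk$peaks$cell_id == "cell_0002"]
  expect_true(all(abs((ta %% 24)) < 0.2 | abs((ta %% 24) - 24) < 0.2))
  expect_true(all(abs((tb %% 24) - 12) < 0.2))
  expect_equal(mean(diff(ta)), 24, tolerance = 0.02)
  expect_equal(mean(diff(tb)), 24, tolerance = 0.02)
})

test_that("flat traces have no peaks and the pipeline is deterministic", {
  times <- 0:96
  tr <- scn_traces(times, rbind(rep(1, 97), 5 + cos(2 * pi * times / 24)))
  pk <- detect_peaks(smooth_and_resample(tr))
  expect_equal(sum(pk$peaks$cell_id == "cell_0001"), 0)
  sl <- quick_slice(n = 10, n_cycles = 5, seed = 2)
  p1 <- detect_peaks(smooth_and_resample(sl$traces))
  p2 <- detect_peaks(smooth_and_resample(sl$traces))
  expect_identical(p1, p2)
})
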