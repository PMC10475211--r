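test_that("line enumeration respects the grid and the L window", {
  cfg <- search_space_config()
  # slope -1, intercept 5: L = 5 - K stays in [-5, 10] for all 101 K's
  pts <- enumerate_line_points(fake_lines(-1, 5), 1, cfg)
  expect_equal(nrow(pts), 101L)
  expect_equal(pts[, "K"], seq(0, 10, by = 0.1))
  expect_true(all(pts[, "L"] >= -5 & pts[, "L"] <= 10))
  # intercept 20: only K = 10 keeps L = (K - 20)/(-1) = 10 inside
  pts2 <- enumerate_line_points(fake_lines(-1, 20), 1, cfg)
  expect_equal(nrow(pts2), 1L)
  expect_equal(unname(pts2[1, ]), c(10, 10))
  # all points satisfy the line equation
  expect_true(all(abs(pts[, "K"] - (-1 * pts[, "L"] + 5)) < 1e-9))
  # a line entirely outside the window errors
  expect_error(enumerate_line_points(fake_lines(-1, 40), 1, cfg),
               "misses")
})

test_that("adaptive capacity follows the stated conventions", {
  lp <- list(c1 = c(K = 2, L = 1), c2 = c(K = 1, L = 0))
  sp <- list(c1 = c(K = 5, L = -2), c2 = c(K = 1, L = 0))
  # magnitude convention: 3 + ||-2| - |1|| = 4
  expect_equal(adaptive_capacity(lp, sp, "abs_of_abs"), 4)
  # plain convention: 3 + |-2 - 1| = 6
  expect_equal(adaptive_capacity(lp, sp, "plain"), 6)
  # identical points give zero capacity
  expect_equal(adaptive_capacity(lp, lp, "plain"), 0)
  # symmetric under swapping the photoperiods
  expect_equal(adaptive_capacity(sp, lp, "plain"),
               adaptive_capacity(lp, sp, "plain"))
})

test_that("constraint checking flags each rule", {
  mk <- function(K, L) {
    data.frame(condition = rep(c("YLP", "YSP", "OLP", "OSP"), each = 2),
               community = rep(1:2, 4), K = K, L = L)
  }
  # young above old, SP above LP, consistent community ordering -> pass
  good <- mk(K = c(5, 4, 8, 7, 3, 2, 6, 5),
             L = c(3, 2, 4, 3, 2, 1, 3, 2))
  res <- check_constraints(good)
  expect_true(res$pass)
  expect_true(res$c1 && res$c2 && res$c3)
  # flip the community-1 vs community-2 K ordering in one condition
  bad3 <- mk(K = c(5, 4, 8, 7, 2, 3, 6, 5),
             L = c(3, 2, 4, 3, 2, 1, 3, 2))
  r3 <- check_constraints(bad3)
  expect_false(r3$c3)
  expect_false(r3$pass)
  # an exact tie fails (strict inequalities)
  tie <- mk(K = c(5, 4, 8, 7, 5, 2, 6, 5),
            L = c(3, 2, 4, 3, 2, 1, 3, 2))
  expect_false(check_constraints(tie)$c1)
})

test_that("identical young and old lines leave the capacity comparison at chance", {
  ln <- condition_lines(0.8, 0.82)
  lnSP <- condition_lines(0.92, 0.93)
  lines <- list(YLP = ln, YSP = lnSP, OLP = ln, OSP = lnSP)
  cfg <- search_space_config(mc_samples = 2e5, seed = 42)
  rep <- unconstrained_fractions(lines, cfg)
  # strictly-greater with ties counted against: at one half up to the
  # (small) tie mass and Monte Carlo error
  expect_lt(abs(rep$fraction_old_exceeds_young - 0.5), 0.01)
})

test_that("single-point lines give deterministic fractions", {
  # intercept 20, slope -1 keeps exactly one grid point per line
  one <- fake_lines(-1, 20)
  lines <- list(YLP = one, YSP = one, OLP = one, OSP = one)
  rep <- unconstrained_fractions(lines,
                                 search_space_config(mc_samples = 1e3))
  expect_identical(rep$fraction_old_exceeds_young, 0)
  expect_identical(rep$fraction_diff_larger_LP, 0)
})

test_that("Monte Carlo agrees with exact enumeration on a reduced grid", {
  op <- scn_order_parameters()
  lines <- lapply(seq_len(4), function(i)
    condition_lines(op$r_medial[i], op$r_lateral[i]))
  names(lines) <- op$condition
  cfg_mc <- search_space_config(K_step = 0.5, mc_samples = 4e5, seed = 7)
  cfg_ex <- search_space_config(K_step = 0.5, method = "enumerate")
  mc <- unconstrained_fractions(lines, cfg_mc)
  ex <- unconstrained_fractions(lines, cfg_ex)
  se1 <- sqrt(ex$fraction_old_exceeds_young *
                (1 - ex$fraction_old_exceeds_young) / cfg_mc$mc_samples)
  se2 <- sqrt(ex$fraction_diff_larger_LP *
                (1 - ex$fraction_diff_larger_LP) / cfg_mc$mc_samples)
  expect_lt(abs(mc$fraction_old_exceeds_young -
                  ex$fraction_old_exceeds_young), 3 * se1)
  expect_lt(abs(mc$fraction_diff_larger_LP -
                  ex$fraction_diff_larger_LP), 3 * se2)
})

test_that("fractions are invariant to a global community swap", {
  op <- scn_order_parameters()
  mk <- function(swap) {
    lines <- lapply(seq_len(4), function(i)
      if (swap) condition_lines(op$r_lateral[i], op$r_medial[i])
      else condition_lines(op$r_medial[i], op$r_lateral[i]))
    names(lines) <- op$condition
    lines
  }
  cfg <- search_space_config(K_step = 0.5, method = "enumerate")
  a <- unconstrained_fractions(mk(FALSE), cfg)
  b <- unconstrained_fractions(mk(TRUE), cfg)
  expect_equal(a$fraction_old_exceeds_young, b$fraction_old_exceeds_young,
               tolerance = 1e-12)
  expect_equal(a$fraction_diff_larger_LP, b$fraction_diff_larger_LP,
               tolerance = 1e-12)
})

test_that("two-stage constrained sampling matches naive rejection", {
  # well-separated conditions so naive rejection is feasible
  lines <- list(YLP = condition_lines(0.85, 0.86),
                YSP = condition_lines(0.95, 0.95),
                OLP = condition_lines(0.75, 0.76),
                OSP = condition_lines(0.90, 0.89))
  cfg <- search_space_config(K_step = 0.5, survivor_target = 2e4,
                             max_batches = 12L, seed = 11)
  two <- constrained_fractions(lines, cfg)
  naive <- suppressWarnings(constrained_fractions(lines, cfg,
                                                  naive = TRUE))
  expect_gt(naive$n_survivors, 150)
  for (f in c("fraction_old_exceeds_young_constrained",
              "fraction_diff_larger_LP_constrained")) {
    p <- two[[f]]
    se <- sqrt(p * (1 - p) / naive$n_survivors +
                 p * (1 - p) / two$n_survivors) + 1e-6
    expect_lt(abs(p - naive[[f]]), 4 * se)
  }
  expect_equal(two$constraint_pass_rate, naive$constraint_pass_rate,
               tolerance = 0.25)
})

test_that("a construction that forces young dominance yields zero", {
  # old lines far below young, SP far above LP: survivors exist and the
  # old capacity can never exceed the young capacity
  lines <- list(YLP = fake_lines(-1, 4.0), YSP = fake_lines(-1, 9.5),
                OLP = fake_lines(-1, 2.0), OSP = fake_lines(-1, 4.5))
  cfg <- search_space_config(K_step = 0.5, survivor_target = 5e3,
                             max_batches = 4L, seed = 3)
  rep <- suppressWarnings(constrained_fractions(lines, cfg))
  expect_gt(rep$n_survivors, 100)
  expect_lt(rep$fraction_old_exceeds_young_constrained, 0.05)
})

test_that("the full analysis object prints and carries both analyses", {
  cfg <- search_space_config(K_step = 0.5, mc_samples = 5e4,
                             survivor_target = 5e3, max_batches = 5L,
                             seed = 9)
  rep <- suppressWarnings(search_space_analysis(config = cfg))
  expect_s3_class(rep, "capacity_report")
  expect_true(all(c("fraction_old_exceeds_young",
                    "fraction_old_exceeds_young_constrained",
                    "constraint_pass_rate") %in% names(rep)))
  expect_true(rep$fraction_old_exceeds_young >= 0 &&
                rep$fraction_old_exceeds_young <= 1)
  out <- capture.output(print(rep))
  expect_true(any(grepl("unconstrained", out)))
  expect_true(any(grepl("constrained", out)))
})
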