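#' Search-space configuration
#'
#' Settings for the coupling search-space analysis.  The stated window is
#' `K` in `[0, 10]` on a 0.1 grid and `L` in `[-5, 10]`; every grid point
#' on a condition line is one "possible solution", and configurations are
#' independent uniform choices of one point per condition and community.
#'
#' @param K_range,K_step grid for the within-community coupling.
#' @param L_range admissible window for the cross-community coupling.
#' @param method `"monte_carlo"` (default) or `"enumerate"` (exact
#'   convolution of component distributions; feasible on reduced grids).
#' @param mc_samples Monte Carlo configuration draws for the
#'   unconstrained fractions.
#' @param survivor_target number of constraint-passing configurations to
#'   accumulate for the constrained fractions.
#' @param max_batches cap on constrained sampling batches (a warning is
#'   issued if the target is not reached).
#' @param seed integer seed for all sampling.
#' @param delta_convention how coupling differences are taken:
#'   `"plain"` uses `|L - L'|`, `"abs_of_abs"` uses `||L| - |L'||`
#'   (differences in `K` are always `|K - K'|`).
#' @param constraint3 whether the cross-community ordering constraint
#'   compares `"magnitude"` (`|L1|` vs `|L2|`) or `"signed"` values.
#' @return an object of class `search_space_config`.
#' @export
search_space_config <- function(K_range = c(0, 10), K_step = 0.1,
                                L_range = c(-5, 10),
                                method = c("monte_carlo", "enumerate"),
                                mc_samples = 1e7,
                                survivor_target = 1e6,
                                max_batches = 60L,
                                seed = 1L,
                                delta_convention = c("plain", "abs_of_abs"),
                                constraint3 = c("magnitude", "signed")) {
  stopifnot(K_step > 0, diff(K_range) > 0, diff(L_range) > 0)
  structure(list(K_range = K_range, K_step = K_step, L_range = L_range,
                 method = match.arg(method), mc_samples = mc_samples,
                 survivor_target = survivor_target,
                 max_batches = as.integer(max_batches),
                 seed = as.integer(seed),
                 delta_convention = match.arg(delta_convention),
                 constraint3 = match.arg(constraint3)),
            class = "search_space_config")
}

#' Grid points of one condition line inside the search window
#'
#' Discretizes `K` on the configured grid, computes the matching `L` on
#' the line, and discards points whose `L` leaves the window.
#'
#' @param lines a `condition_lines` object.
#' @param community 1 or 2.
#' @param config a [search_space_config()].
#' @return matrix with columns `K`, `L`, ascending in `K`.
#' @export
enumerate_line_points <- function(lines, community = 1L,
                                  config = search_space_config()) {
  stopifnot(inherits(lines, "condition_lines"))
  K <- round(seq(config$K_range[1L], config$K_range[2L],
                 by = config$K_step), 10)
  a <- if (community == 1L) lines$slope1 else lines$slope2
  b <- if (community == 1L) lines$intercept1 else lines$intercept2
  L <- (K - b) / a
  keep <- L >= config$L_range[1L] & L <= config$L_range[2L]
  if (!any(keep))
    stop("condition line misses the search window entirely")
  cbind(K = K[keep], L = L[keep])
}

## difference in cross coupling under the configured convention
delta_L <- function(a, b, convention) {
  if (convention == "plain") abs(a - b) else abs(abs(a) - abs(b))
}

#' Total adaptive capacity between two photoperiods
#'
#' `Delta K1 + Delta |L1| + Delta K2 + Delta |L2|` between the short- and
#' long-photoperiod solution points of one age group, measuring how far
#' the coupling parameters move between seasons.  Symmetric in swapping
#' the photoperiods.
#'
#' @param points_lp,points_sp lists with elements `c1` and `c2`, each a
#'   `c(K, L)` point for that community.
#' @param delta_convention see [search_space_config()].
#' @return scalar capacity.
#' @examples
#' lp <- list(c1 = c(K = 2, L = 1), c2 = c(K = 1, L = 0))
#' sp <- list(c1 = c(K = 5, L = -2), c2 = c(K = 1, L = 0))
#' adaptive_capacity(lp, sp, "abs_of_abs")  # 3 + 1 + 0 + 0 = 4
#' @export
adaptive_capacity <- function(points_lp, points_sp,
                              delta_convention = "plain") {
  stopifnot(all(c("c1", "c2") %in% names(points_lp)),
            all(c("c1", "c2") %in% names(points_sp)))
  sum(vapply(c("c1", "c2"), function(cc) {
    abs(points_sp[[cc]][["K"]] - points_lp[[cc]][["K"]]) +
      delta_L(points_sp[[cc]][["L"]], points_lp[[cc]][["L"]],
              delta_convention)
  }, numeric(1)))
}

## ---- internal machinery ---------------------------------------------------

scn_conditions <- c("YLP", "YSP", "OLP", "OSP")

## named list condition -> list("1" = pts matrix, "2" = pts matrix)
line_points_set <- function(lines, config) {
  stopifnot(is.list(lines), all(scn_conditions %in% names(lines)))
  out <- lapply(lines[scn_conditions], function(ln)
    list(`1` = enumerate_line_points(ln, 1L, config),
         `2` = enumerate_line_points(ln, 2L, config)))
  names(out) <- scn_conditions
  out
}

## draw M uniform point indices for every (condition, community);
## returns list(K, L): M x 8 matrices with columns "YLP.1", ..., "OSP.2"
draw_configurations <- function(pts, M) {
  cols <- as.vector(outer(1:2, scn_conditions,
                          function(c, cd) paste(cd, c, sep = ".")))
  K <- matrix(0, M, 8L, dimnames = list(NULL, cols))
  L <- K
  for (cd in scn_conditions) for (cc in 1:2) {
    p <- pts[[cd]][[as.character(cc)]]
    ix <- sample.int(nrow(p), M, replace = TRUE)
    col <- paste(cd, cc, sep = ".")
    K[, col] <- p[ix, 1L]
    L[, col] <- p[ix, 2L]
  }
  list(K = K, L = L)
}

## capacities and photoperiod difference sums for drawn configurations
config_statistics <- function(d, convention) {
  K <- d$K; L <- d$L
  cap <- function(age)
    abs(K[, paste0(age, "SP.1")] - K[, paste0(age, "LP.1")]) +
    delta_L(L[, paste0(age, "SP.1")], L[, paste0(age, "LP.1")], convention) +
    abs(K[, paste0(age, "SP.2")] - K[, paste0(age, "LP.2")]) +
    delta_L(L[, paste0(age, "SP.2")], L[, paste0(age, "LP.2")], convention)
  dif <- function(P)
    abs(K[, paste0("Y", P, ".1")] - K[, paste0("O", P, ".1")]) +
    delta_L(L[, paste0("Y", P, ".1")], L[, paste0("O", P, ".1")], convention) +
    abs(K[, paste0("Y", P, ".2")] - K[, paste0("O", P, ".2")]) +
    delta_L(L[, paste0("Y", P, ".2")], L[, paste0("O", P, ".2")], convention)
  list(cap_young = cap("Y"), cap_old = cap("O"),
       diff_LP = dif("LP"), diff_SP = dif("SP"))
}

## vectorized three-constraint mask for drawn configurations
constraints_mask <- function(d, constraint3 = "magnitude") {
  K <- d$K; L <- d$L; A <- abs(L)
  c1 <- rep(TRUE, nrow(K)); c2 <- c1
  for (cc in 1:2) for (P in c("LP", "SP")) {
    yc <- paste0("Y", P, ".", cc); oc <- paste0("O", P, ".", cc)
    c1 <- c1 & K[, yc] > K[, oc] & A[, yc] > A[, oc]
  }
  for (cc in 1:2) for (age in c("Y", "O")) {
    sc <- paste0(age, "SP.", cc); lc <- paste0(age, "LP.", cc)
    c2 <- c2 & K[, sc] > K[, lc] & A[, sc] > A[, lc]
  }
  Lc <- if (constraint3 == "magnitude") A else L
  sK <- sign(K[, "YLP.1"] - K[, "YLP.2"])
  sL <- sign(Lc[, "YLP.1"] - Lc[, "YLP.2"])
  c3 <- sK != 0 & sL != 0
  for (cd in c("YSP", "OLP", "OSP")) {
    c3 <- c3 & sign(K[, paste0(cd, ".1")] - K[, paste0(cd, ".2")]) == sK &
      sign(Lc[, paste0(cd, ".1")] - Lc[, paste0(cd, ".2")]) == sL
  }
  list(c1 = c1, c2 = c2, c3 = c3, pass = c1 & c2 & c3)
}

#' Check the three biological constraints of one configuration
#'
#' Constraint 1: coupling magnitudes higher in young than old
#' (`K` and `|L|`, both communities, both photoperiods).  Constraint 2:
#' higher in short than long photoperiod (both communities, both ages).
#' Constraint 3: the ordering of community 1 versus community 2 (in `K`,
#' and in `L` under the configured comparison) points the same way in all
#' four conditions.  All inequalities are strict; ties fail.
#'
#' @param configuration data.frame with columns `condition` (YLP, YSP,
#'   OLP, OSP), `community` (1, 2), `K`, `L` — one row per condition and
#'   community (8 rows).
#' @param constraint3 `"magnitude"` or `"signed"` (see
#'   [search_space_config()]).
#' @return list with logical `pass` and per-constraint flags `c1`, `c2`,
#'   `c3`.
#' @export
check_constraints <- function(configuration, constraint3 = "magnitude") {
  df <- configuration
  stopifnot(is.data.frame(df),
            all(c("condition", "community", "K", "L") %in% names(df)),
            nrow(df) == 8L)
  cols <- paste(df$condition, df$community, sep = ".")
  need <- as.vector(outer(1:2, scn_conditions,
                          function(c, cd) paste(cd, c, sep = ".")))
  if (!setequal(cols, need))
    stop("configuration must contain each condition x community once")
  K <- matrix(df$K[match(need, cols)], 1L, dimnames = list(NULL, need))
  L <- matrix(df$L[match(need, cols)], 1L, dimnames = list(NULL, need))
  m <- constraints_mask(list(K = K, L = L), constraint3)
  lapply(m, as.vector)[c("pass", "c1", "c2", "c3")]
}

## ---- exact enumeration helpers -------------------------------------------

## P(X1 + X2 > Y1 + Y2) for independent uniform atom lists, computed as
## P(D1 + D2 > 0) with D = X - Y via sorted tail counts; strict inequality
prob_sum_greater <- function(x1, y1, x2, y2) {
  d1 <- as.vector(outer(x1, y1, "-"))
  d2 <- sort(as.vector(outer(x2, y2, "-")))
  n2 <- length(d2)
  ## findInterval counts d2 <= x, so n2 - count is strictly greater
  mean(n2 - findInterval(-d1, d2)) / n2
}

enumerate_pair_atoms <- function(ptsA, ptsB, convention) {
  ## all |K_a - K_b| + deltaL contributions over point pairs (uniform atoms)
  as.vector(outer(ptsA[, 1L], ptsB[, 1L],
                  function(a, b) abs(a - b))) +
    as.vector(outer(ptsA[, 2L], ptsB[, 2L],
                    function(a, b) delta_L(a, b, convention)))
}

#' Unconstrained search-space fractions
#'
#' Over independent uniform choices of one grid point per condition and
#' community, estimates (1) the probability that the old total adaptive
#' capacity strictly exceeds the young one, and (2) the probability that
#' the summed young-versus-old coupling difference is strictly larger in
#' long than in short photoperiod.  `method = "enumerate"` computes both
#' exactly by convolving the per-community component distributions
#' (feasible on reduced grids); `"monte_carlo"` samples configurations in
#' chunks.
#'
#' @param lines named list of `condition_lines` for `YLP`, `YSP`, `OLP`,
#'   `OSP`.
#' @param config a [search_space_config()].
#' @return an object of class `capacity_report` (partial: unconstrained
#'   fractions only).
#' @export
unconstrained_fractions <- function(lines, config = search_space_config()) {
  pts <- line_points_set(lines, config)
  cv <- config$delta_convention
  if (config$method == "enumerate") {
    sizes <- vapply(scn_conditions, function(cd)
      vapply(1:2, function(cc) nrow(pts[[cd]][[as.character(cc)]]),
             numeric(1)), numeric(2))
    if (max(apply(sizes, 2, prod)) > 4e6 || prod(dim(sizes)) == 0 ||
        max(sizes)^4 > 4e8)
      stop("grid too fine for exact enumeration; use method 'monte_carlo'")
    capA <- function(age, cc)
      enumerate_pair_atoms(pts[[paste0(age, "SP")]][[cc]],
                           pts[[paste0(age, "LP")]][[cc]], cv)
    f1 <- prob_sum_greater(capA("O", "1"), capA("Y", "1"),
                           capA("O", "2"), capA("Y", "2"))
    difA <- function(P, cc)
      enumerate_pair_atoms(pts[[paste0("Y", P)]][[cc]],
                           pts[[paste0("O", P)]][[cc]], cv)
    f2 <- prob_sum_greater(difA("LP", "1"), difA("SP", "1"),
                           difA("LP", "2"), difA("SP", "2"))
    n_used <- sum(sizes)
  } else {
    set.seed(config$seed)
    total <- config$mc_samples
    chunk <- min(total, 1e6)
    n1 <- 0; n2 <- 0; done <- 0
    while (done < total) {
      M <- min(chunk, total - done)
      st <- config_statistics(draw_configurations(pts, M), cv)
      n1 <- n1 + sum(st$cap_old > st$cap_young)
      n2 <- n2 + sum(st$diff_LP > st$diff_SP)
      done <- done + M
    }
    f1 <- n1 / total; f2 <- n2 / total
    n_used <- total
  }
  structure(list(fraction_old_exceeds_young = f1,
                 fraction_diff_larger_LP = f2,
                 method = config$method, n = n_used,
                 seed = config$seed,
                 delta_convention = cv),
            class = "capacity_report")
}

## ---- constrained sampling -------------------------------------------------

## Constraints 1-2 restrict each community's four points to a partial order
## (YSP above YLP and OSP; OLP below both; in K and |L| jointly).  For every
## admissible (YSP, OLP) anchor pair the valid YLP and OSP points are
## conditionally independent, so anchor pairs weighted by
## (#valid YLP) x (#valid OSP) give exact uniform samples of valid 4-tuples.
build_community_sampler <- function(pts_comm) {
  ysp <- pts_comm[["YSP"]]; olp <- pts_comm[["OLP"]]
  ylp <- pts_comm[["YLP"]]; osp <- pts_comm[["OSP"]]
  na <- nrow(ysp); nb <- nrow(olp)
  aK <- ysp[, 1L]; aL <- abs(ysp[, 2L])
  bK <- olp[, 1L]; bL <- abs(olp[, 2L])
  between <- function(mid) {
    mK <- mid[, 1L]; mL <- abs(mid[, 2L])
    sets <- vector("list", na * nb)
    for (j in seq_len(nb)) {
      okb <- mK > bK[j] & mL > bL[j]
      for (i in seq_len(na))
        sets[[(j - 1L) * na + i]] <-
          which(okb & mK < aK[i] & mL < aL[i])
    }
    sets
  }
  sy <- between(ylp); so <- between(osp)
  w <- lengths(sy) * lengths(so)
  total <- as.numeric(na) * nb * nrow(ylp) * nrow(osp)
  list(pts = pts_comm, sets_y = sy, sets_o = so, w = w, na = na,
       W = sum(as.numeric(w)), total = total)
}

## M exact-uniform valid 4-tuples; list of K and L matrices (M x 4 conds)
sample_community_tuples <- function(sampler, M) {
  pairs <- sample.int(length(sampler$w), M, replace = TRUE,
                      prob = sampler$w)
  cnt <- tabulate(pairs, length(sampler$w))
  used <- which(cnt > 0L)
  ord <- order(pairs)
  iy <- integer(M); io <- integer(M)
  pos <- 1L
  for (p in used) {
    k <- cnt[p]
    idx <- ord[pos:(pos + k - 1L)]
    sy <- sampler$sets_y[[p]]; so <- sampler$sets_o[[p]]
    iy[idx] <- sy[sample.int(length(sy), k, replace = TRUE)]
    io[idx] <- so[sample.int(length(so), k, replace = TRUE)]
    pos <- pos + k
  }
  i <- (pairs - 1L) %% sampler$na + 1L
  j <- (pairs - 1L) %/% sampler$na + 1L
  perm <- sample.int(M)
  p <- sampler$pts
  K <- cbind(YLP = p$YLP[iy, 1L], YSP = p$YSP[i, 1L],
             OLP = p$OLP[j, 1L], OSP = p$OSP[io, 1L])[perm, , drop = FALSE]
  L <- cbind(YLP = p$YLP[iy, 2L], YSP = p$YSP[i, 2L],
             OLP = p$OLP[j, 2L], OSP = p$OSP[io, 2L])[perm, , drop = FALSE]
  list(K = K, L = L)
}

## assemble two community tuple draws into the M x 8 layout
bind_communities <- function(t1, t2) {
  cols <- as.vector(outer(1:2, scn_conditions,
                          function(c, cd) paste(cd, c, sep = ".")))
  K <- cbind(t1$K, t2$K); L <- cbind(t1$L, t2$L)
  colnames(K) <- colnames(L) <-
    c(paste0(scn_conditions, ".1"), paste0(scn_conditions, ".2"))
  list(K = K[, cols, drop = FALSE], L = L[, cols, drop = FALSE])
}

#' Constraint-restricted search-space fractions
#'
#' The two fractions of [unconstrained_fractions()], restricted to
#' configurations passing all three constraints of [check_constraints()].
#' Sampling is a two-stage exact-uniform scheme: constraints 1--2 factor
#' into independent per-community partial orders that are sampled by
#' weighted anchor-pair enumeration; constraint 3 couples the communities
#' and is applied by rejection.  `method = "rejection"` (naive, for
#' cross-checks on permissive windows) is available via
#' `config$method = "monte_carlo"` with `naive = TRUE`.
#'
#' @param lines named list of `condition_lines` (YLP, YSP, OLP, OSP).
#' @param config a [search_space_config()].
#' @param naive if `TRUE`, use plain rejection sampling of unconstrained
#'   draws (validation path; infeasibly slow on the full window).
#' @return a `capacity_report` with constrained fractions, the constraint
#'   pass rate, and survivor count.
#' @export
constrained_fractions <- function(lines, config = search_space_config(),
                                  naive = FALSE) {
  pts <- line_points_set(lines, config)
  cv <- config$delta_convention
  set.seed(config$seed + 1L)
  target <- config$survivor_target
  survivors <- list(cap_young = numeric(0), cap_old = numeric(0),
                    diff_LP = numeric(0), diff_SP = numeric(0))
  n_surv <- 0; n_drawn <- 0; n_c3 <- 0
  if (naive) {
    batch <- 1e6
    for (b in seq_len(config$max_batches)) {
      d <- draw_configurations(pts, batch)
      m <- constraints_mask(d, config$constraint3)
      keep <- which(m$pass)
      n_drawn <- n_drawn + batch; n_c3 <- n_c3 + length(keep)
      if (length(keep)) {
        st <- config_statistics(list(K = d$K[keep, , drop = FALSE],
                                     L = d$L[keep, , drop = FALSE]), cv)
        for (f in names(survivors))
          survivors[[f]] <- c(survivors[[f]], st[[f]])
        n_surv <- n_surv + length(keep)
      }
      if (n_surv >= target) break
    }
    pass_rate <- n_surv / n_drawn
  } else {
    s1 <- build_community_sampler(lapply(pts, `[[`, "1"))
    s2 <- build_community_sampler(lapply(pts, `[[`, "2"))
    if (s1$W == 0 || s2$W == 0)
      stop("no configuration satisfies constraints 1-2; ",
           "search window too restrictive")
    batch <- 1e6
    for (b in seq_len(config$max_batches)) {
      d <- bind_communities(sample_community_tuples(s1, batch),
                            sample_community_tuples(s2, batch))
      c3 <- constraints_mask(d, config$constraint3)$c3
      keep <- which(c3)
      n_drawn <- n_drawn + batch; n_c3 <- n_c3 + length(keep)
      if (length(keep)) {
        st <- config_statistics(list(K = d$K[keep, , drop = FALSE],
                                     L = d$L[keep, , drop = FALSE]), cv)
        for (f in names(survivors))
          survivors[[f]] <- c(survivors[[f]], st[[f]])
        n_surv <- n_surv + length(keep)
      }
      if (n_surv >= target) break
    }
    pass_rate <- (s1$W / s1$total) * (s2$W / s2$total) * (n_c3 / n_drawn)
  }
  if (n_surv == 0)
    stop("no constraint-passing configurations found (pass rate ~ ",
         signif(pass_rate, 3), ")")
  if (n_surv < target)
    warning("survivor target not reached: ", n_surv, " < ", target)
  structure(list(fraction_old_exceeds_young_constrained =
                   mean(survivors$cap_old > survivors$cap_young),
                 fraction_diff_larger_LP_constrained =
                   mean(survivors$diff_LP > survivors$diff_SP),
                 constraint_pass_rate = pass_rate,
                 n_survivors = n_surv,
                 method = if (naive) "rejection" else "two_stage",
                 seed = config$seed,
                 delta_convention = cv,
                 constraint3 = config$constraint3),
            class = "capacity_report")
}

#' Full search-space analysis of adaptive capacity
#'
#' Builds the four condition coupling lines from per-condition order
#' parameters (defaults to the published averaged values of
#' [scn_order_parameters()]), then computes the unconstrained and
#' constrained search-space fractions.
#'
#' @param order_params data.frame like [scn_order_parameters()].
#' @param D noise strength for the lines (default 1).
#' @param config a [search_space_config()].
#' @return a `capacity_report` combining both analyses, with the lines
#'   attached.
#' @export
search_space_analysis <- function(order_params = scn_order_parameters(),
                                  D = 1,
                                  config = search_space_config()) {
  lines <- lapply(seq_len(nrow(order_params)), function(i)
    condition_lines(order_params$r_medial[i], order_params$r_lateral[i],
                    D = D, condition = order_params$condition[i]))
  names(lines) <- order_params$condition
  un <- unconstrained_fractions(lines, config)
  cn <- constrained_fractions(lines, config)
  structure(c(unclass(un)[c("fraction_old_exceeds_young",
                            "fraction_diff_larger_LP")],
              unclass(cn)[c("fraction_old_exceeds_young_constrained",
                            "fraction_diff_larger_LP_constrained",
                            "constraint_pass_rate", "n_survivors")],
              list(method = un$method, n = un$n, seed = config$seed,
                   delta_convention = config$delta_convention,
                   constraint3 = config$constraint3, lines = lines)),
            class = "capacity_report")
}

#' @export
print.capacity_report <- function(x, ...) {
  pct <- function(p) if (is.null(p)) NULL else sprintf("%.4g%%", 100 * p)
  cat("Search-space capacity report\n")
  if (!is.null(x$fraction_old_exceeds_young)) {
    cat("  unconstrained:\n")
    cat("    P(old capacity > young capacity) =",
        pct(x$fraction_old_exceeds_young), "\n")
    cat("    P(young-old difference larger in LP) =",
        pct(x$fraction_diff_larger_LP), "\n")
  }
  if (!is.null(x$fraction_old_exceeds_young_constrained)) {
    cat("  constrained (", format(x$n_survivors, big.mark = ","),
        " survivors, pass rate ", signif(x$constraint_pass_rate, 3),
        "):\n", sep = "")
    cat("    P(old capacity > young capacity) =",
        pct(x$fraction_old_exceeds_young_constrained), "\n")
    cat("    P(young-old difference larger in LP) =",
        pct(x$fraction_diff_larger_LP_constrained), "\n")
  }
  invisible(x)
}
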