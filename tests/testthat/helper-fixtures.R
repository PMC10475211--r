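# Shared fixtures, built in code.

# Hand-built peak series: tp is a cells x cycles matrix of peak times (h);
# NA marks a missing cycle for that cell.
make_series <- function(tp, tau = NULL, cell_ids = NULL) {
  n <- nrow(tp)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%04d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    ok <- !is.na(tp[i, ])
    if (!any(ok)) return(NULL)
    data.frame(cell_id = cell_ids[i], cycle = which(ok),
               peak_time_h = tp[i, ok])
  })
  periods <- apply(tp, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 2L) mean(diff(v)) else NA_real_
  })
  if (is.null(tau)) tau <- stats::median(periods, na.rm = TRUE)
  structure(list(peaks = do.call(rbind, rows),
                 periods = data.frame(cell_id = cell_ids,
                                      period_h = periods,
                                      n_peaks = rowSums(!is.na(tp))),
                 tau = tau, cell_ids = cell_ids, metadata = list(),
                 filtered = FALSE),
            class = "peak_series")
}

# Minimal line object with arbitrary slope/intercept (geometry-only tests)
fake_lines <- function(slope1, intercept1, slope2 = slope1,
                       intercept2 = intercept1) {
  structure(list(slope1 = slope1, intercept1 = intercept1,
                 slope2 = slope2, intercept2 = intercept2,
                 D = 1, condition = NA_character_),
            class = "condition_lines")
}

# Small one-community rendered slice for pipeline tests
quick_slice <- function(K = 2, D = 0.8, n = 40, n_cycles = 6, seed = 1,
                        noise_sd = 2) {
  simulate_scn_slice(
    one_community_params(n_oscillators = n, K = K, D = D,
                         n_cycles = n_cycles, seed = seed,
                         init_mean = pi),
    render_options(noise_sd = noise_sd))
}

# Independent series evaluation of the modified Bessel ratio (test oracle)
bessel_ratio_series <- function(x, terms = 60) {
  I <- function(nu) sum(vapply(0:terms, function(k)
    (x / 2)^(2 * k + nu) / (factorial(k) * factorial(k + nu)),
    numeric(1)))
  I(1) / I(0)
}
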