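#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end with a single configuration:
#' simulate (or ingest) traces, process them into filtered peak series,
#' compute phase coherence, detect or import communities, estimate
#' one-community coupling/noise bounds, build two-community coupling
#' lines, and run the search-space capacity analysis.  Every stage writes
#' its output to `out_dir` and the run ends with a single `summary.json`
#' carrying the seed and a hash of the configuration; identical
#' configurations and seeds give byte-identical summaries.  Timings are
#' logged to stderr.
#'
#' Configuration fields (all optional unless noted):
#' \describe{
#'   \item{mode}{`"simulate"` (default), `"traces"` (requires
#'     `traces_csv`), or `"order_params"` (skip measurement stages and run
#'     only the search-space analysis).}
#'   \item{seed}{integer; required whenever a stochastic stage runs.}
#'   \item{preset}{for simulate mode: one of `"young_LP"`, `"young_SP"`,
#'     `"old_LP"`, `"old_SP"`; a two-community fixture calibrated to that
#'     condition's reported order parameters.}
#'   \item{simulate}{overrides for [two_community_params()] /
#'     [calibrate_condition()] (`n_per_community`, `n_cycles`,
#'     `L_choice`).}
#'   \item{traces_csv, labels_csv}{input files for traces mode.}
#'   \item{cycle}{analysis cycle (default 2).}
#'   \item{search}{list of [search_space_config()] overrides plus
#'     optional `order_params` data.frame; by default the published
#'     per-condition order parameters are used.}
#' }
#'
#' @param config configuration list, or path to a JSON file with the same
#'   structure.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mode <- config$mode %||% "simulate"
  seed <- config$seed %||% 1L
  cycle <- config$cycle %||% 2L
  cfg_hash <- config_hash(config)
  summary <- list(schema = "scnkuramoto/pipeline-summary/1",
                  mode = mode, seed = seed, config_hash = cfg_hash)

  if (mode != "order_params") {
    traces <- with_stage("input", {
      if (mode == "simulate") {
        sl <- pipeline_simulate(config, seed)
        write_slice_fixture(sl, file.path(out_dir, "slice"))
        sl$traces
      } else {
        if (is.null(config$traces_csv)) stop("traces mode needs 'traces_csv'")
        read_traces(config$traces_csv)
      }
    })
    labels <- with_stage("communities", {
      if (!is.null(config$labels_csv)) read_labels(config$labels_csv)
      else {
        ca <- detect_communities(traces)
        write_labels(ca$labels, file.path(out_dir, "labels.csv"))
        if (ca$degenerate) NULL else ca$labels
      }
    })
    fit <- with_stage("fit", {
      f <- kuramoto_fit(traces, cycle = cycle, labels = labels,
                        detect_communities = FALSE)
      write_peak_series(f$peaks, file.path(out_dir, "peaks.csv"))
      jsonlite::write_json(coherence_json(f$coherence),
                           file.path(out_dir, "coherence.json"),
                           auto_unbox = TRUE, digits = NA)
      jsonlite::write_json(unclass(f$bounds),
                           file.path(out_dir, "bounds.json"),
                           auto_unbox = TRUE, digits = NA)
      if (!is.null(f$lines))
        jsonlite::write_json(lines_json(f$lines),
                             file.path(out_dir, "lines.json"),
                             auto_unbox = TRUE, digits = NA)
      f
    })
    summary$coherence <- coherence_json(fit$coherence)
    summary$bounds <- unclass(fit$bounds)
    if (!is.null(fit$lines)) summary$lines <- lines_json(fit$lines)
  }

  search_cfg <- config$search %||% list()
  if (!identical(search_cfg$run, FALSE)) {
    report <- with_stage("search_space", {
      op <- search_cfg$order_params %||% scn_order_parameters()
      if (!is.data.frame(op)) op <- as.data.frame(op)
      cfg <- search_space_config(
        K_step = search_cfg$K_step %||% 0.1,
        mc_samples = search_cfg$mc_samples %||% 1e6,
        survivor_target = search_cfg$survivor_target %||% 1e5,
        seed = seed,
        delta_convention = search_cfg$delta_convention %||% "plain",
        constraint3 = search_cfg$constraint3 %||% "magnitude")
      rep <- search_space_analysis(op, config = cfg)
      jsonlite::write_json(capacity_json(rep),
                           file.path(out_dir, "capacity.json"),
                           auto_unbox = TRUE, digits = NA)
      rep
    })
    summary$capacity <- capacity_json(report)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[stage %s] %.2f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

pipeline_simulate <- function(config, seed) {
  sim <- config$simulate %||% list()
  n <- sim$n_per_community %||% 60L
  ncyc <- sim$n_cycles %||% 8L
  if (!is.null(config$preset)) {
    op <- scn_order_parameters()
    key <- c(young_LP = "YLP", young_SP = "YSP",
             old_LP = "OLP", old_SP = "OSP")[[config$preset]]
    if (is.na(key)) stop("unknown preset '", config$preset, "'")
    row <- op[op$condition == key, ]
    params <- calibrate_condition(row$r_medial, row$r_lateral,
                                  L_choice = sim$L_choice %||% 1,
                                  n_per_community = n, n_cycles = ncyc,
                                  seed = seed, init_offset = pi / 2)
    meta <- list(age = row$age, photoperiod = row$photoperiod)
  } else {
    params <- two_community_params(n_per_community = n,
                                   K1 = sim$K1 %||% 3, K2 = sim$K2 %||% 3,
                                   L1 = sim$L1 %||% 0.5,
                                   L2 = sim$L2 %||% 0.5,
                                   D = sim$D %||% 1, n_cycles = ncyc,
                                   seed = seed,
                                   init_offset = sim$init_offset %||% pi / 2)
    meta <- list()
  }
  simulate_scn_slice(params, metadata = meta)
}

coherence_json <- function(coh) {
  out <- list(r = coh$r, dispersion_h = coh$dispersion_h,
              n_cells = coh$n_cells, cycle = coh$cycle, tau = coh$tau)
  if (!is.null(coh$r1)) { out$r1 <- coh$r1; out$r2 <- coh$r2 }
  out
}

lines_json <- function(ln) {
  unclass(ln)[c("r1", "r2", "C1", "C2", "D", "slope1", "intercept1",
                "slope2", "intercept2")]
}

capacity_json <- function(rep) {
  keep <- intersect(c("fraction_old_exceeds_young",
                      "fraction_diff_larger_LP",
                      "fraction_old_exceeds_young_constrained",
                      "fraction_diff_larger_LP_constrained",
                      "constraint_pass_rate", "n_survivors", "method",
                      "n", "seed", "delta_convention", "constraint3"),
                    names(rep))
  unclass(rep)[keep]
}

## md5 of the canonical JSON form of the configuration
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}
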