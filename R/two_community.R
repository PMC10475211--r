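#' Reported per-condition averaged order parameters
#'
#' The averaged order parameters of the medial- and lateral-oriented SCN
#' clusters in the four experimental conditions (young/old x long/short
#' photoperiod), pooling anterior and posterior slices.  These eight
#' numbers are the only inputs of the search-space analysis.
#'
#' @return data.frame with columns `condition` (YLP, YSP, OLP, OSP),
#'   `age`, `photoperiod`, `r_medial`, `r_lateral`.
#' @export
scn_order_parameters <- function() {
  data.frame(condition = c("YLP", "YSP", "OLP", "OSP"),
             age = c("young", "young", "old", "old"),
             photoperiod = c("LP", "SP", "LP", "SP"),
             r_medial = c(0.77, 0.94, 0.84, 0.91),
             r_lateral = c(0.81, 0.94, 0.77, 0.90))
}

#' Linear coupling relations of one experimental condition
#'
#' Given the per-community order parameters `(r1, r2)` of a condition, the
#' two-community self-consistency relations
#' `V((K1 r1 + L1 r2)/D) = r1` and `V((K2 r2 + L2 r1)/D) = r2`
#' constrain each within-community coupling to a line in its
#' cross-coupling: `K_c = a_c L_c + b_c` with slope `a_c = -r_other / r_c`
#' and intercept `b_c = C_c D / r_c`, where `C_c` is the unique positive
#' root of `V(C_c) = r_c`.
#'
#' @param r1 order parameter of community 1 (medial-oriented cluster).
#' @param r2 order parameter of community 2 (lateral-oriented cluster).
#' @param D noise strength, fixed at 1 by convention (the one-community
#'   analysis shows D is close to 1 in all conditions).
#' @param condition optional condition id attached to the object.
#' @return an object of class `condition_lines`: list with `r1`, `r2`,
#'   `C1`, `C2`, `D`, `slope1`, `intercept1`, `slope2`, `intercept2`,
#'   `condition`.
#' @examples
#' condition_lines(0.77, 0.81, condition = "YLP")
#' @export
condition_lines <- function(r1, r2, D = 1, condition = NA_character_) {
  for (r in c(r1, r2))
    if (!is.finite(r) || r <= 0 || r >= 1)
      stop("order parameters must lie strictly in (0, 1)")
  if (!is.finite(D) || D <= 0) stop("'D' must be positive")
  C1 <- bessel_ratio_inverse(r1)
  C2 <- bessel_ratio_inverse(r2)
  stopifnot(abs(bessel_ratio(C1) - r1) <= 1e-10,
            abs(bessel_ratio(C2) - r2) <= 1e-10)
  structure(list(r1 = r1, r2 = r2, C1 = C1, C2 = C2, D = D,
                 slope1 = -r2 / r1, intercept1 = C1 * D / r1,
                 slope2 = -r1 / r2, intercept2 = C2 * D / r2,
                 condition = condition),
            class = "condition_lines")
}

#' @export
print.condition_lines <- function(x, ...) {
  cat("Coupling lines",
      if (!is.na(x$condition)) paste0("(", x$condition, ")"), ":\n",
      "  r1 = ", x$r1, ", r2 = ", x$r2, " (D = ", x$D, ")\n",
      "  K1 = ", round(x$slope1, 4), " L1 + ", round(x$intercept1, 4), "\n",
      "  K2 = ", round(x$slope2, 4), " L2 + ", round(x$intercept2, 4), "\n",
      sep = "")
  invisible(x)
}

#' Evaluate a condition line at a coupling value
#'
#' Given `K`, returns the matching `L` (and vice versa) on the chosen
#' community's line; the round trip is exact.
#'
#' @param lines a `condition_lines` object.
#' @param community 1 (medial) or 2 (lateral).
#' @param K,L supply exactly one of the two.
#' @return named vector `c(K, L)` on the line.
#' @export
point_on_line <- function(lines, community = 1L, K = NULL, L = NULL) {
  stopifnot(inherits(lines, "condition_lines"), community %in% 1:2)
  a <- if (community == 1L) lines$slope1 else lines$slope2
  b <- if (community == 1L) lines$intercept1 else lines$intercept2
  if (is.null(K) + is.null(L) != 1L)
    stop("supply exactly one of 'K' or 'L'")
  if (is.null(L)) L <- (K - b) / a else K <- a * L + b
  c(K = K, L = L)
}

#' Average slice-level order parameters into condition lines
#'
#' Pools anterior and posterior slices of one experimental condition by
#' (weighted) arithmetic mean of the slice-level `(r1, r2)` pairs, then
#' builds the condition's coupling lines.  The averaging weights are
#' configurable because the upstream convention is unstated; the default
#' is an unweighted mean.
#'
#' @param r1 slice-level order parameters of the medial cluster.
#' @param r2 slice-level order parameters of the lateral cluster.
#' @param weights optional non-negative weights (e.g. cell counts).
#' @param D,condition passed to [condition_lines()].
#' @return a `condition_lines` object.
#' @export
average_condition_lines <- function(r1, r2, weights = NULL, D = 1,
                                    condition = NA_character_) {
  if (is.null(weights)) weights <- rep(1, length(r1))
  condition_lines(stats::weighted.mean(r1, weights),
                  stats::weighted.mean(r2, weights),
                  D = D, condition = condition)
}
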