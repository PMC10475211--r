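#' Modified Bessel function ratio V(x) = I1(x)/I0(x)
#'
#' The mean resultant length of a von Mises distribution with concentration
#' `x`.  It is the central nonlinearity of the noisy mean-field Kuramoto
#' model: the stationary order parameter of a single community solves the
#' self-consistency relation `V(C r) = r`.
#'
#' `V` is evaluated with exponentially scaled Bessel functions so the ratio
#' is stable for large arguments, where `V(x) -> 1` like `1 - 1/(2x)`.
#'
#' @param x numeric vector, `x >= 0`.
#' @return numeric vector of ratios in `[0, 1)`.
#' @examples
#' bessel_ratio(0)    # 0
#' bessel_ratio(1)    # ~0.4464
#' @export
bessel_ratio <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric")
  if (any(x < 0))
    stop("'x' must be non-negative: the concentration of the stationary ",
         "phase distribution cannot be negative")
  besselI(x, 1, expon.scaled = TRUE) / besselI(x, 0, expon.scaled = TRUE)
}

#' Inverse of the Bessel ratio
#'
#' Finds the unique `x > 0` with `bessel_ratio(x) = r` for `0 < r < 1`,
#' by bracketing and root refinement.  This is the concentration of the
#' phase distribution that produces order parameter `r`.
#'
#' @param r order parameter in (0, 1).
#' @param tol absolute tolerance on `V(x) - r`.
#' @return scalar `x > 0`.
#' @export
bessel_ratio_inverse <- function(r, tol = 1e-12) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r))
    stop("'r' must be a finite scalar")
  if (r <= 0 || r >= 1)
    stop("'r' must lie strictly in (0, 1): r = 0 is degenerate and r = 1 ",
         "requires infinite concentration")
  ## V(x) ~ 1 - 1/(2x) for large x, so 1/(1 - r) safely exceeds the root
  upper <- max(4, 1 / (1 - r))
  while (bessel_ratio(upper) < r) upper <- upper * 2
  stats::uniroot(function(x) bessel_ratio(x) - r, c(1e-12, upper),
                 tol = tol)$root
}

#' Solve the one-community self-consistency V(C r) = r for C
#'
#' In the stationary one-community noisy Kuramoto model the order parameter
#' `r` and the concentration `C` are linked by `V(C r) = r`, which has a
#' unique positive solution for every `0 < r < 1`.  As `r -> 0+` the
#' small-argument expansion `V(x) ~ x/2` gives `C -> 2` (the mean-field
#' synchronization threshold).  `C` relates the coupling and noise strength
#' through `C = 2 K / D`.
#'
#' @param r order parameter, strictly inside (0, 1).
#' @param tol absolute tolerance on `V(C r) - r`.
#' @return scalar concentration `C > 0`.
#' @examples
#' solve_concentration(0.5)   # ~2.319
#' @export
solve_concentration <- function(r, tol = 1e-12) {
  C <- bessel_ratio_inverse(r, tol = tol) / r
  stopifnot(abs(bessel_ratio(C * r) - r) <= 1e-10)
  C
}

## wrap phases onto (-pi, pi]
wrap_phase <- function(x) {
  y <- x %% (2 * pi)
  y[y > pi] <- y[y > pi] - 2 * pi
  y
}
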