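---
title: "Methods: noisy Kuramoto inference of SCN coupling strength"
author: "scnkuramoto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noisy Kuramoto inference of SCN coupling strength}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnkuramoto)
```

# The scientific problem

The suprachiasmatic nucleus (SCN) is a network of roughly 20,000 coupled
neuronal oscillators whose collective phase coherence encodes day length:
in long photoperiod the single-cell PER2::LUC expression peaks spread out
over several hours, in short photoperiod they cluster tightly.  With age
this photoperiodic plasticity deteriorates.  The coupling strengths
between SCN neurons cannot be measured directly; this package infers them
from what *can* be measured — hourly single-cell bioluminescence traces —
through the stationary statistics of a noisy mean-field Kuramoto model.

The pipeline has four layers:

1. **Measurement.** Smooth and resample traces, detect expression peaks,
   apply the inclusion filter (at least 3 full cycles, period between 20
   and 28 h), and convert peak times to relative phases
   $\theta_{r,j} = (\bar t_p - t_{p,j})\,2\pi/\tau$.  Phase coherence is
   the Kuramoto order parameter $r = |N^{-1}\sum_j e^{i\theta_{r,j}}|$,
   and the peak-time dispersion (SD of one cycle's peak times) is its
   classical counterpart.
2. **One-community inference.** For a single community obeying
   $d\theta_i = \frac{K}{N}\sum_j \sin(\theta_j - \theta_i)\,dt + D\,dW_i$,
   stationarity links coherence and coupling through the modified Bessel
   ratio $V(x) = I_1(x)/I_0(x)$: the concentration $C$ solves
   $V(Cr) = r$, with $C = 2K/D$.  Cycle-to-cycle phase increments
   $\Delta_T$ give moment-based interval estimates $[K_-, K_+]$ and
   $[D_-, D_+]$ (below).
3. **Two-community inference.** With within-community couplings $K_1,
   K_2$, cross couplings $L_1, L_2$ (both mean fields divided by the
   total population $2N$) and $D = 1$, the stationary relations
   $V(K_1 r_1 + L_1 r_2) = r_1$ and $V(K_2 r_2 + L_2 r_1) = r_2$
   constrain each condition to a *line*
   $K_c = -\frac{r_{c'}}{r_c} L_c + \frac{C_c}{r_c}$.  The data identify
   the line, not a point on it.
4. **Search-space analysis.** On a grid over the lines ($K \in [0, 10]$
   step 0.1, $L \in [-5, 10]$), the *total adaptive capacity*
   $\Delta K_1 + \Delta|L_1| + \Delta K_2 + \Delta|L_2|$ between long and
   short photoperiod is compared across age groups, unconstrained and
   under three biological constraints.

# The one-community bounds

Integrating the linearized phase SDE over one period $T$ and applying
Itô's lemma with a truncated Taylor expansion of the sine drift gives
two-sided bounds on the noise strength in terms of the unbiased moment
estimators $h_2$ (variance) and $h_4$ (fourth central moment) of the
pooled increments:

$$D_-^2 = \frac{h_2(1 + 2KrT)}{T} - \frac{2Kr\,h_4}{6}, \qquad
  D_+^2 = \frac{h_2(1 + 2KrT)}{T}.$$

Substituting $K = CD/2$ and solving the resulting quadratics yields the
closed forms implemented in `coupling_and_noise_bounds()`:

$$K_+ = \tfrac14\left(C^2 h_2 r + \sqrt{C^4 h_2^2 r^2 + 4C^2 h_2/T}\right),
\qquad
K_- = \tfrac1{24}\left(C^2 r(6h_2 - h_4) +
  \sqrt{C^4 (6h_2 - h_4)^2 r^2 + 144\,C^2 h_2/T}\right),$$

with $D_\pm = 2K_\pm/C$.  Two published forms of these expressions
circulate with typeset damage; the package uses the algebraically
consistent versions — the $h_4$ estimator with quartic factor
$n^2(n^2 - 2n + 3)$, and $144\,C^2 h_2/T$ (with the division) under the
$K_-$ radical — and the test suite verifies both against independent
quadratic root-finding and Monte-Carlo unbiasedness.

**A known limitation, on purpose.**  The derivation of the bounds
conditions on $\theta(0) = 0$, so it equates $\mathrm{E}[\Delta_T^2]$
with $\mathrm{E}[\theta(T)^2\,|\,\theta(0)=0] \approx \sigma^2
(1 - e^{-2KrT})$, where $\sigma^2 = D^2/(2Kr)$ is the stationary phase
variance.  The empirical increments, however, are differences of two
(nearly independent) stationary phases, with variance
$2\sigma^2(1 - e^{-KrT}) \approx 2\sigma^2$ — a factor
$2/(1 + e^{-KrT}) \approx 2$ larger whenever the relaxation time
$1/(Kr)$ is much shorter than the period.  The estimator therefore
overstates $D$ (and hence $K$) by about $\sqrt2$ on synthetic data
generated by the very model it assumes; $D_+$ and $K_+$ remain valid
upper bounds, but $D_-$ can exceed the true $D$.  Reporter integration
(below) compounds this by inflating the measured $r$.  The acceptance
suite runs the full recovery experiment (50 rendered slices at $K = 2$,
$D = 1$, $N = 300$) and *documents this as a red test rather than
papering over it*: the intervals it reports do not bracket the
generating parameters, exactly as this analysis predicts.  Green tests
cover what the estimator does guarantee: the ordering $K_- \le K_+$,
$D_- \le D_+$, the closed forms, and the upper-bound property.

# The synthetic world

`simulate_one_community()` / `simulate_two_community()` integrate the
SDEs by Euler–Maruyama in the lab frame with a common natural frequency
$2\pi/\tau$ (equivalent to the rotating-frame model, which omits it).
Defaults: $\tau = 24$ h, $dt = \tau/200$, wrapped-normal initial phases
with SD 1 rad, one master seed with per-oscillator noise substreams so
enlarging a population does not perturb existing noise streams.  The
between-community mean-field divisor is $2N$, matching the governing
equations (some literature divides by $N$; the self-consistency
relations used here are consistent with $2N$).

`render_bioluminescence()` maps phase to intensity with a raised cosine
$I_i(t) = b_i + a_i\,(1 + \cos\theta_i)/2 + \varepsilon$, with
cell-specific baselines ($100 \pm 20$ a.u.) and amplitudes
($200 \pm 40$ a.u., clipped at 1% of the mean if a draw is non-positive),
1-h sampling and measurement noise of 2 a.u. (~1% of amplitude, the
shot-noise scale of pooled-ROI photon counting).  Crucially, the phase
that drives luminescence is a 6-h moving average of the SDE phase
(`phase_integration_h`): raw SDE paths are white-noise rough between
hourly samples, whereas real reporter traces are smooth within a cycle
because PER2 protein accumulation and luciferase turnover low-pass the
transcriptional phase.  Ground-truth peak times stored with each fixture
are the zero crossings of that same integrated phase.

What the generator does *not* emulate: pixel-level imaging, photon
statistics, slice-to-slice optical variation, frozen cell-to-cell period
heterogeneity, and damping of amplitude over days in culture.  One
consequence matters for interpretation: because the OU relaxation time
of the phase ($1/(Kr) \lesssim 1$ h at the regimes studied) is shorter
than any plausible reporter timescale, the dispersion measured from
rendered peak times underestimates the instantaneous stationary
dispersion, so the measured $r$ of a high-noise fixture is compressed
towards 1 relative to the SDE's stationary $r$.  A green
parameter-recovery test on this world therefore establishes consistency
of the measurement pipeline, not unbiasedness of the published estimator —
see the red acceptance test above.  At $D = 1$ peak detection recovers
the integrated-phase crossings to $\pm 1$ h for $\ge 90\%$ of peaks
(median $\le 0.5$ h); the $\pm 0.5$ h / 95% level holds at $D = 0.5$.
No sampling rate can do better while the instantaneous phase wanders
$\sim 1$ rad per hour.

# Measurement defaults

* Smoothing: centred 3-h moving average, then cubic-spline resampling to
  1 sample/min (the conventional preprocessing for hourly PER2::LUC
  imaging).  Both are deterministic.
* Peak detection: local maxima with topographic prominence above 20% of
  the cell's intensity range and minimum separation 16 h — safe for any
  period inside the 20–28 h inclusion band.  Cycle indices are assigned
  on a slice-wide grid (anchored at the median first peak, consensus
  period = median of per-cell mean inter-peak intervals) so "cycle k" is
  comparable across cells.
* A "cycle" is an inter-peak interval; "at least 3 cycles" therefore
  requires 4 peaks.  Both the count and the period band are arguments of
  `filter_cells()`.
* The analysis cycle defaults to 2 (the first full cycle after the
  culture transient); which in-vitro cycle the original analysis used is
  not recoverable, so it is exposed as an argument everywhere.
* Phase increments are pooled across cells *and* consecutive cycle
  pairs; per-cell restriction is possible via the `cycles` argument.
* Per-community order parameters use the community's own mean peak time
  (the alternative — the whole-slice mean — is not what "coherence of a
  subpopulation" means operationally).

# Community detection

The stand-in for the published clustering chain is: Pearson correlation
matrix of the raw traces → random-matrix filter → sign split of the
leading residual eigenvector.  The filter removes the Marchenko–Pastur
noise bulk $[(1-\sqrt{N/T})^2, (1+\sqrt{N/T})^2]$ and the global mode.
The global mode is identified as the above-bulk eigencomponent whose
eigenvector is most sign-uniform, and removed only when at least 90% of
its loadings share one sign: for data dominated by a common rhythm this
is exactly the largest eigenvalue, but when two subpopulations
oscillate in anti-phase the largest eigenvalue *is* the community
contrast, and removing it blindly would destroy the signal.  A result
is flagged degenerate when no above-bulk structure survives the filter
(single-community data) or the leading residual eigenvector does not
change sign.  Labels can always be supplied externally
(`read_labels()`), which is how the original analysis was run.

# Search-space analysis

The four conditions (young/old × long/short photoperiod) enter through
their reported averaged order parameters, exposed as
`scn_order_parameters()`:
medial 0.77 / 0.94 / 0.84 / 0.91, lateral 0.81 / 0.94 / 0.77 / 0.90 for
YLP / YSP / OLP / OSP.  Each condition and community yields a line; a
*solution configuration* picks one grid point per (condition,
community), uniformly and independently — the operational meaning of
"all possible solutions".

Conventions the source leaves ambiguous, and how they were fixed:

* **Difference convention.**  $\Delta K$ is always $|K - K'|$.  For the
  cross coupling, the package computes $|L - L'|$ (`"plain"`), with
  $||L| - |L'||$ (`"abs_of_abs"`) available behind
  `delta_convention`.  The plain reading is the default because it is
  the only one that reproduces all four reported headline fractions; the
  magnitude reading makes "old capacity exceeds young" algebraically
  identical to "difference larger in LP" once the constraints hold
  (both collapse to the same linear combination), which contradicts the
  two very different reported values.
* **Constraint 3.**  "The relationship between $L_1$ and $L_2$ points
  the same way in all conditions" compares coupling magnitudes
  $|L_1|$ vs $|L_2|$ by default (`constraint3 = "magnitude"`),
  consistent with the magnitude comparisons the other two constraints
  use; the signed comparison is available.
* **Ties** (possible on the shared grid) count as "not greater".

Constraints 1–2 (young > old, SP > LP, in $K$ and $|L|$, strictly)
restrict each community's four points to a partial order — YSP above
both YLP and OSP, OLP below both, in $K$ and $|L|$ jointly — and are
independent across the two communities.  The constrained sampler
exploits this: for every admissible (YSP, OLP) anchor pair the valid
YLP and OSP choices are conditionally independent, so anchor pairs
weighted by the product of their valid-set sizes give *exact* uniform
samples of constraint-1/2-passing tuples; constraint 3 (which couples
the communities) is then applied by rejection.  Naive rejection on the
full window passes at $\sim 2\times10^{-6}$ and could never reach
$10^6$ survivors; the two-stage scheme reaches them in a few batches
and is validated against naive rejection on permissive windows in the
test suite.  Exact enumeration (convolution of per-community component
distributions) is implemented for reduced grids and used to validate
the Monte Carlo path.

# Numerical choices

* $V(x)$ uses exponentially scaled Bessel functions (stable to
  $x \to \infty$); inverses by bracketing + `uniroot` to $10^{-12}$,
  with the $V(Cr) = r$ residual asserted below $10^{-10}$.
* Euler–Maruyama at $dt = \tau/200$ by default ($dt \le \tau/100$
  enforced).  The scheme inflates stationary phase variance by
  $\approx a\,dt/2$ (relaxation rate $a$); analyses that need $r$ to
  better than 0.01 at strong coupling should use $dt = \tau/1000$, as
  the two-community acceptance fixture does.
* Phases are wrapped to $(-\pi, \pi]$ exactly once, at the peak-time →
  phase conversion and after increment differences; no further
  unwrapping heuristics.
* Degenerate inputs fail loudly: empty filters, fewer than 2 cells per
  community, fewer than 5 pooled increments, lines that miss the search
  window, zero constraint survivors.

# Reproducibility

Every stochastic entry point takes an integer seed; trajectories are
bit-identical under the same seed, and `run_pipeline()` writes a
summary JSON that is byte-identical across reruns of the same
configuration and seed (config hash included).  `scripts/acceptance.R`
recomputes the four headline search-space fractions from scratch through
the installed package.
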