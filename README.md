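# scnkuramoto

Coupling-strength inference for the mammalian circadian clock from
single-cell bioluminescence rhythms, with noisy mean-field Kuramoto
models.

## The problem

The suprachiasmatic nucleus (SCN) encodes day length in the phase
coherence of its ~20,000 coupled neuronal oscillators: single-cell
PER2::LUC expression peaks cluster tightly in short photoperiod and
spread out in long photoperiod, and this plasticity weakens with age.
The coupling strengths that produce these regimes cannot be measured
directly.  This package infers them from hourly single-cell
bioluminescence traces:

* **Phase coherence.** Peak times `t_p,j` of each cell give relative
  phases `θ_r,j = (t̄_p − t_p,j)·2π/τ` and the Kuramoto order parameter
  `r = |N⁻¹ Σ exp(iθ_r,j)|`.
* **One community.** For
  `dθ_i = (K/N) Σ_j sin(θ_j − θ_i) dt + D dW_i`, stationarity ties `r`
  to the concentration `C` through the Bessel ratio
  `V(x) = I₁(x)/I₀(x)`: `V(C·r) = r`, `C = 2K/D`.  Unbiased moments
  (h-statistics) of cycle-to-cycle phase increments yield interval
  estimates `[K−, K+]`, `[D−, D+]`.
* **Two communities** (medial- and lateral-oriented clusters, detected
  by correlation + random-matrix filtering): the stationary relations
  `V(K₁r₁ + L₁r₂) = r₁`, `V(K₂r₂ + L₂r₁) = r₂` at `D = 1` constrain
  each experimental condition to a line `K_c = −(r_c'/r_c)·L_c + C_c/r_c`
  in the (L, K) plane.
* **Adaptive capacity.** On a grid over these lines (`K ∈ [0,10]` step
  0.1, `L ∈ [−5,10]`), the total adaptive capacity
  `ΔK₁ + Δ|L₁| + ΔK₂ + Δ|L₂|` between photoperiods is compared across
  age groups, with and without three biological constraints
  (young > old, SP > LP, consistent community ordering).

A full synthetic-data layer (stochastic simulation of both models,
rendered as realistic hourly bioluminescence traces with ground truth
attached) backs every stage with testable fixtures.

## Worked example

```r
library(scnkuramoto)

## a synthetic "old mouse, long photoperiod" slice: two communities
## calibrated to that condition's order parameters (0.84, 0.77)
params <- calibrate_condition(0.84, 0.77, L_choice = 0,
                              n_per_community = 60, n_cycles = 8,
                              seed = 42, init_offset = pi/2)
slice <- simulate_scn_slice(params,
                            metadata = list(age = "old",
                                            photoperiod = "LP"))
fit <- kuramoto_fit(slice)
summary(fit)
#> Noisy Kuramoto coupling fit
#>   retained cells: 120  (dropped: 0 )
#>   consensus period: 24.26 h;  analysis cycle: 2
#>   phase coherence: r = 0.8045 ; peak-time dispersion = 2.56 h
#>   community order parameters: r1 = 0.9422 , r2 = 0.9245
#>   coupling bounds:  K- = 1.4725  K+ = 1.8732
#>   noise bounds:     D- = 0.8092  D+ = 1.0294
#> Coupling lines:
#>   r1 = 0.9421542, r2 = 0.9244766 (D = 1)
#>   K1 = -0.9812 L1 + 9.4671
#>   K2 = -1.0191 L2 + 7.4711
```

All 120 cells pass the inclusion filter (≥3 cycles, period 20–28 h).
The slice-level coherence `r = 0.80` with a 2.6 h peak-time dispersion
is a long-photoperiod regime; each subpopulation is more coherent than
the slice as a whole (`r1 = 0.94`, `r2 = 0.92`), and the noise interval
contains `D = 1`, the value the two-community analysis fixes.  Each
condition line summarises every coupling pair consistent with the
measured coherence — the data identify the line, not a point on it.

The population-level analysis needs only the per-condition order
parameters (built in as `scn_order_parameters()`):

```r
rep <- search_space_analysis(
  config = search_space_config(mc_samples = 1e6,
                               survivor_target = 1e5, seed = 1))
rep
#> Search-space capacity report
#>   unconstrained:
#>     P(old capacity > young capacity) = 33.27%
#>     P(young-old difference larger in LP) = 35.78%
#>   constrained (242,013 survivors, pass rate 2.34e-06):
#>     P(old capacity > young capacity) = 0.004958%
#>     P(young-old difference larger in LP) = 10.74%
```

Unconstrained, old mice out-adapt young ones in a third of the solution
space; under the three biological constraints that fraction collapses to
effectively zero — the aged SCN cannot reach the strong coupling that
short photoperiod demands — and the young–old coupling gap lies in short
photoperiod in ~90% of admissible solutions.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the four headline search-space fractions from scratch with
the installed package — condition lines from the per-condition order
parameters at `D = 1`, the stated grid and window, 10⁷ Monte Carlo
configuration draws for the unconstrained fractions and 10⁶
constraint-passing configurations (exact two-stage uniform sampling) for
the constrained ones — and writes them as JSON.

## Package layout

* `R/simulate.R`, `R/render.R` — SDE simulation and trace rendering
  (synthetic fixtures with ground truth).
* `R/traces.R`, `R/peaks.R` — smoothing/resampling, peak detection,
  inclusion filter, dispersion.
* `R/coherence.R` — order parameters, per-community coherence.
* `R/communities.R` — correlation matrix, random-matrix filter,
  two-community split.
* `R/bessel.R`, `R/one_community.R` — Bessel-ratio self-consistency,
  h-statistics, coupling/noise bounds.
* `R/two_community.R`, `R/search_space.R` — condition lines and the
  constrained capacity analysis.
* `R/fit.R` — `kuramoto_fit()` and its methods; `R/pipeline.R` —
  `run_pipeline()` end-to-end orchestration with JSON outputs.
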