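---
title: "Integrated process models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated process models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipmqbd)
```

## The model

`ipmqbd` represents a downstream purification process as an ordered chain
of unit operations (capture, acid treatment, chromatography, filtration
steps, drug substance).  For every unit operation and every critical
quality attribute (CQA) the package tracks the *specific clearance*
$SC$ — the dimensionless multiplicative change of the CQA's specific
(non-volumetric) concentration across that step.  Because clearance is a
ratio, propagation through the chain is a product: the pool concentration
leaving step $k$ is

$$c_k = c_{k-1} \cdot (SC_k + \varepsilon_k),$$

and the drug-substance value is the pool of the last step.  Working on
the specific-concentration scale is what makes per-step regression models
composable across unit operations with different volumes and hold-ups.

Per unit operation and CQA, $SC$ is predicted by one of:

* a **DoE model** — ordinary least squares on the step's process
  parameters, $SC = \beta_0 + \sum_j \beta_j\, PP_j$, with optional
  interaction/quadratic terms declared as products of parameter columns;
* a **load model** — a unifactorial regression on the specific load
  concentration entering the step, $SC = \beta_0 + \beta_{SLC}\, SLC$.
  The load of step $k$ is the simulated pool of step $k-1$ (the starting
  concentration for the first step), which is the linkage that lets
  variation travel down the chain;
* **both** — the DoE prediction multiplied by the ratio of the load
  prediction at the current load to the load prediction at the mean load
  of the DoE runs,
  $\widehat{SC} = \widehat{SC}(PP)\,
   \widehat{SC}(SLC)/\widehat{SC}(\overline{SLC}_{DoE})$.
  When the simulated load equals the DoE mean the correction is exactly 1
  and the combined prediction collapses to the DoE prediction — a
  machine-precision identity the tests assert;
* a **fixed clearance** $N(\mu, \sigma^2)$ estimated from set-point
  manufacturing runs; or
* nothing, in which case the step passes the CQA through unchanged
  (clearance exactly 1, no noise).

Starting concentrations are normal, $N(\text{start\_mean},
\text{start\_sd}^2)$, per CQA.

## Monte-Carlo simulation and OOA

Each cycle draws starting concentrations, process-parameter settings and
clearance noise, then propagates.  Parameters are sampled independently
as $N(\text{set point}, h/3)$ where $h$ is the NOR half-width — i.e. the
normal operating range is read as $\pm 3$ standard deviations of routine
variation.  Clearance noise per modelled cell is mean-zero normal with
the model's residual standard error (for combined cells the DoE model's
RMSE is used; the load correction is treated as a deterministic
adjustment, so its residual is not double-counted).  Negative
concentrations, which can only arise from an extreme noise draw, are
clamped at zero and counted.

Out-of-acceptance (OOA) probability at drug substance is parametric: the
simulated sample is summarized by $\bar x$ and $s$, and

$$\text{OOA} = 100\left[\Phi\!\left(\frac{LSL - \bar x}{s^*}\right) +
  1 - \Phi\!\left(\frac{USL - \bar x}{s^*}\right)\right],
\qquad
s^* = s\sqrt{\frac{n-1}{\chi^2_{1-\gamma,\,n-1}}}.$$

$s^*$ is the upper one-sided $\gamma$ confidence limit of the standard
deviation (default $\gamma = 0.95$).  Two numerical notes:

* the chi-square quantile is taken at the *lower* tail probability
  $1-\gamma$, which is what makes $s^* \ge s$ an upper limit; and
* the formula carries a square root.  The inflation exists so that OOA
  estimates from a handful of manufacturing runs ($n = 5$ inflates $s$
  by a factor of about 2.37) are conservatively comparable with
  thousand-cycle in-silico estimates ($n = 1000$ inflates by about
  1.04).  $n$ is always the size of the sample actually summarized.

Degenerate samples ($s = 0$) return 0 or 100 by direct comparison of the
mean with the limits; a sample with both limits infinite returns exactly
0.

## Parameter sensitivity analysis

The PSA is a one-at-a-time grid scan: the scanned parameter's screening
range is divided into 10 equidistant points (endpoints inclusive;
configurable), the parameter is fixed at each point while all others
vary in their NORs, and the full 1000-cycle simulation is run per point.
The exact set point is evaluated as an additional dedicated run rather
than snapped to the nearest grid node, because the severity slopes below
are anchored at the set point exactly.  Per-point seeds are derived
deterministically from (master seed, parameter, grid index), making
curves reproducible and points independent.

For cross-parameter overlays, native values are coded onto the
*relative screening range* $(x - x_{sp})/\big((x_{max}-x_{min})/2\big)$:
the set point maps to 0 and the image always lies in $[-2, 2]$ (a set
point sitting on a screening edge codes the range as $[-2,0]$ or
$[0,2]$).

## FMEA severity linearization

Per parameter, CQA and side of the set point:

* the **critical slope** $(5\% - \text{OOA}_{SP})/(SR - SP)$ is the
  largest admissible OOA change per native unit before the predefined
  critical level (default 5%, roughly two standard deviations of a
  centred population) would be reached at the screening edge;
* the **CQA slope** $(\text{OOA}_{SR} - \text{OOA}_{SP})/(SR - SP)$ is
  the simulated change;
* their ratio is formed per side, the worst-case (larger) side is
  retained, and the rubric maps it to a rank: $\ge 0.8 \to 10$,
  $[0.5, 0.8) \to 7$, $[0.3, 0.5) \to 3$, $< 0.3 \to 1$.  Rank 10
  designates the parameter a critical process parameter (CPP).  The
  final parameter ranking is the worst ranking over CQAs.

Edge rules, chosen once and tested: beneficial directions (OOA falling
toward the edge) floor the ratio at 0; a set point already at or above
the critical level makes the ranking 10 by design (the critical slope
direction flips, which the code detects by sign); a set point coinciding
with a screening edge makes that side inapplicable and the assessment
one-sided; band lower bounds are inclusive.  The rubric presentation
"percent of reference" and the threshold values 0.8/0.5/0.3 are only
mutually consistent if the thresholds apply to the plain ratio
(equivalently, to %ref with thresholds 80/50/30); that reading is
implemented.  Other ranking scales can be supplied as a strictly
decreasing threshold table and are validated for non-overlap.

## Proven acceptable range

The PAR of a parameter is the contiguous sub-interval of its screening
range, containing the set point, on which every CQA's OOA stays at or
below the critical level (default 5%).  Moving outward from the set
point, the first interval between adjacent curve points straddling the
level is found and the crossing linearly interpolated; the most
restrictive crossing over CQAs becomes the limit and the binding CQAs
are recorded.  On non-monotone (noisy) curves the crossing nearest the
set point wins, which guarantees a contiguous range around the set
point; an optional isotonic smoothing of each half-curve exists but is
off by default so the plain procedure is reproduced.  Interpolation
versus snapping to grid nodes was an open choice; interpolation is used
and documented, and refinement tests confirm the interpolated crossing
converges to the analytic one as the grid grows.  If the set-point OOA
itself exceeds the critical level the PAR is reported as undefined
rather than empty.

Raising the critical level can only widen the PAR; this monotonicity is
property-tested.

## The synthetic world

No public dataset exists for a full downstream chain with per-step DoE
and load models, so the package ships a generator whose defaults state
one fixed world: 8 unit operations (CAP, AT, DF, AEX, CEX, VF, UFDF,
DS), 4 CQAs (three impurities, one product attribute), and a
model-availability pattern that exercises every cell type — DoE-only,
load-only, combined, and pass-through steps.  Two parameters are created
per DoE-modelled step (8 in total).  Remaining choices, made once as
plausible for a capable monoclonal-antibody process and not revisited:

* NOR half-widths of 5% of the set point; screening ranges 3 NOR
  half-widths wide (screening studies explore well beyond routine
  variation);
* set-point impurity clearances in $[0.3, 0.7]$ per step, product yields
  in $[0.92, 0.99]$;
* screening-edge clearance effects of 0.02–0.12 in absolute clearance
  units with random sign — spanning negligible to clearly critical
  parameters so every rubric band is reachable;
* model RMSE 0.004–0.012 on the clearance scale (sub-noise to a few
  percent of a typical clearance), 4% starting-concentration CV;
* acceptance limits at 4 analytic standard deviations from the
  drug-substance mean at set point, i.e. a capable process
  (set-point OOA well under the 5% critical level), the situation in
  which severity ranking and PAR setting are meaningful.

A closed-form oracle (`analytic_ooa_curve()`) propagates the mean and
variance of the drug-substance distribution exactly for independent
multiplicative factors and reads OOA off the normal tails with the same
$s^*$ inflation; the variance contributed by the load-model linkage is
evaluated on the deterministic set-point trajectory and therefore
neglected to second order.  End-to-end tests regenerate data, refit all
models, rerun the Monte-Carlo PSA and require the fitted pipeline to
reproduce the true chain's rubric rankings on at least 90% of parameters
over 20 replicates in a low-noise regime (RMSE 0.002–0.006).

What a green suite does **not** establish: the generator draws Gaussian
everything (no analytical measurement-error structure, no scale effects
between pilot and manufacturing, no parameter covariance), effects are
linear main effects by default, and the product distribution of
clearances is only approximately normal — the parametric OOA is exact
in the oracle's normal approximation, not in distribution.

## Reproducibility and numerics

All randomness flows from one integer master seed through substreams
derived by a small string hash (`derive_seed()`), kept below $2^{31}$.
Identical seeds give bit-identical simulations and byte-identical CSV
exports.  Model selection minimizes AIC over all main-effect subsets
(plus declared interactions), with ties broken toward the simpler,
earlier candidate; $Q^2$ uses the closed-form leave-one-out PRESS via
the hat matrix and is tested against literal refitting; fits use raw
native units, coded values being display-only.  Chain configurations are
serialized as JSON at full precision (round-tripping costs at most one
ulp on coefficients, which the tests tolerate explicitly).
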