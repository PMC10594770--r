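---
title: "Methods: stochastic fuzzy DEA for mental-health service efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic fuzzy DEA for mental-health service efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`mhrte` assesses the relative technical efficiency (RTE) of mental-health
services within three DESDE-LTC typologies: acute hospital residential
care (T1: R1, R2), non-acute non-hospital residential care (T2: R9, R11,
R12, R13) and non-acute outpatient care (T3: O8, O9, O10). Within a
typology every service is a decision-making unit (DMU) described by
rates: workforce inputs per bed (T1, T2) or per user (T3), and
utilisation outputs — length of stay per user, users per bed, admissions
per bed (T1), contacts per user (T3). Rates remove the service-size
effect; size is the dominant source of spurious variability in
service-level comparisons, and bed counts are a common size proxy in
residential care.

For DMU *k* with input vector $x_k$ and output vector $y_k$, the
input-oriented variable-returns-to-scale (VRS/BCC) envelopment problem is

$$\min_{\theta, \lambda} \theta \quad \text{s.t.} \quad
X^\top\lambda \le \theta x_k,\;\; Y^\top\lambda \ge y_k,\;\;
\mathbf{1}^\top\lambda = 1,\;\; \lambda \ge 0 ,$$

followed by a second phase that fixes $\theta^\ast$ and maximises the
sum of input and output slacks over the same feasible set. No weights
are placed on variables. Classification: *efficient* when
$\theta^\ast = 1$ (within tolerance) and all slacks are zero; *weakly
efficient* when $\theta^\ast = 1$ with positive slack; *inefficient*
when $\theta^\ast < 1$. Input orientation matches the managerial goal of
reducing resource use without losing output; VRS is chosen because no
constant input–output relationship can be assumed across services of
very different scale.

Three stages surround the DEA core:

1. **Pattern-of-use regression.** Raw (unrated) capacity and utilisation
   are regressed on annual users. Non-hospital residential care exhibits
   two regimes — a standard pattern with beds tracking users about 1:1
   and a small high-turnover pattern near 0.14 beds per user —
   detected by `split_patterns()` (below).
2. **Monte Carlo perturbation.** Each observed rate becomes the mode of
   a triangular distribution with support
   $[x(1-d),\, x(1+u)]$, default $d = u = 0.30$. Runs are drawn
   independently across services and variables (no correlation structure
   is assumed) from per-service RNG substreams, so adding a service
   leaves all other draws unchanged. Convergence of any simulated
   quantity is tracked by an error statistic with a 2.5 %-of-mean limit.
3. **Fuzzy appropriateness transformation.** Every DEA variable carries
   an appropriateness range $[x_l, x_r]$ with an orientation. Inside the
   range, when raw monotonicity disagrees with DEA-favourability the
   value is reflected, $x' = (x_r + x_l) - x$; when it agrees, the value
   passes through. Outside the range the value is penalised linearly
   with distance, pushed above $x_r$ for inputs and below $x_l$ (floored
   at 0) for outputs. This encodes the balanced-care view that both
   under- and over-resourcing are inappropriate: a DEA model fed raw
   rates would reward absolute scarcity.

After the runs, each service's score vector yields the RTE mean, SD,
error, error percentage and the run frequencies P(efficient),
P(weakly efficient), P(inefficient) — exhaustive and mutually exclusive,
summing to one — and P(RTE > 0.75). Services are ranked into quartiles
by RTE mean within typology and the workforce of quartile 1 versus
quartile 4 is compared with two-sided Mann–Whitney U tests at the 0.05
level, gross and as rates.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `n_runs` | 1000 | runs | production setting of the study design; tests and examples scale down to seconds |
| perturbation `percentages` | (0.30, 0.30) | fraction of the rate | the stated expert rule; per-variable overrides supported |
| `error_threshold_pct` | 2.5 | % of the mean | stopping limit on the RTE error (95 % CI half-width over mean) |
| `rule_quantiles` | (0.40, 0.60) | quantiles | data-derived default appropriateness range when no expert file is supplied |
| penalty slopes | 1 | per unit distance | linear penalty outside the range; expert files may override |
| `dea_tol` | 1e-6 | — | θ = 1 and zero-slack decisions; LP solver works at ~1e-9 |

The error statistic is implemented as the 95 % confidence half-width of
the mean, $1.96\,s/\sqrt{n}$, expressed as a percentage of the mean
(undefined at mean zero, reported as not-converged with a reason). The
formula sits behind `error_statistic()` so an alternative convergence
measure can be swapped in without touching callers. Convergence failure
in the pipeline warns and recommends more runs rather than aborting:
the limit is a quality criterion, and desk-scale runs legitimately use
fewer runs.

## The synthetic world

`generate_ecosystem()` produces service tables with the statistical
structure the analysis assumes, plus ground-truth labels:

* per-code service counts default to the analysed regional sample
  (2 R1, 18 R2, 1 R9, 18 R11, 8 R12, 2 R13, 3 O8, 33 O9, 3 O10;
  88 services), with a high-turnover subset confined to R11
  (4 of 29 T2 services);
* T2 beds follow `slope · users · (1 + N(0, cv))` with slopes 1.0
  (standard) and 0.14 (turnover). Noise is multiplicative because count
  spread grows with service size; the CVs (0.233, 0.083) are calibrated
  so the *population* within-pattern R² equals the observed fits (0.897,
  0.970) under the default lognormal user-count distributions;
* per-user length of stay is gamma-distributed with means 29.24 (T1),
  335.2 (T2 standard) and 79.51 (T2 turnover) days/user. The T1 SD
  (29.03) is the observed descriptive spread; the T2 SDs (72.5, 4.3) are
  calibrated so the total-days-on-users regressions attain the observed
  R² (0.91, 0.987) — the published "SD ≈ 50" figures there are residual
  SDs of those fits, in days, not per-user spreads;
* T1 users-per-bed is gamma with mean 16.26 and SD 9.46, with a narrow
  bed-count spread so users and beds stay uncoupled, as observed;
  outpatient contact intensity is gamma with means 84.81 (O8) and 14.1
  (O9–O10) and the observed SDs. Gamma replaces the truncated normal one
  might first reach for: truncating N(29.24, 29.03) at zero would shift
  the mean to ≈ 37.5 and silently break the stated regime, whereas
  moment-matched gammas keep mean and SD exact and are non-negative by
  construction;
* workforce counts are lognormal around per-typology medians
  (`sdlog = 0.5`, a spread low enough that median shifts of the reported
  between-quartile magnitude are detectable by U tests at the study's
  group sizes), with zero-median categories mostly absent. Workforce is
  drawn **independently of efficiency**: no workforce–performance
  coupling is planted because none is quantified in the source material.
  A green quartile-comparison test therefore establishes the machinery,
  not the substantive finding.

`plant_frontier()` builds DEA problems with known answers: frontier DMUs
on a strictly concave, strictly monotone surface (inputs ∝ t, outputs ∝
√t), dominated DMUs as frontier points with inputs inflated by a
recorded γ > 1 and expected score exactly 1/γ.

What the generator does **not** emulate: municipality-level clustering
or any covariance between services; pathways of care, diagnoses or
user-level records (the unit is the service-year); and expert
appropriateness ranges — the default rule base is data-quantile-derived
and labelled as such, because the study's expert-elicited ranges are
unpublished (only one is printed, and it is used as the worked example
in the tests). Consequently the pipeline's RTE *levels* on synthetic
data are not comparable to published tables; structural checks (planted
frontiers, exhaustive probabilities, invariances, parameter recovery)
are the meaningful green signals.

## Numerical choices

* **LP solver.** A dense two-phase primal simplex (`simplex_lp()`),
  written for this package because no LP library is available in the
  supported environment. Rows are equilibrated to unit max magnitude
  (DEA matrices mix 1e-9-scale staff rates with 300-day stays); the
  entering column takes the most negative reduced cost with a fallback
  to Bland's rule after a long stall (no cycling); ratio-test ties are
  broken on the largest pivot element, which avoids the tiny-pivot
  blow-ups that plague naive tableau implementations. Verified against
  a brute-force basic-solution enumeration oracle and, for DEA, against
  the closed-form 1-input/1-output convex-hull solution.
* **Zero inputs.** Transformed inputs can legitimately hit zero (a
  degenerate data-derived range at an all-zero staff category). They are
  kept as true zeros: the envelopment LP remains feasible through
  self-inclusion, and a zero entry merely restricts the reference set to
  peers also using none of that resource. Clipping zeros to a shared
  small ε instead would make those columns identical across DMUs —
  forcing every score to 1 — and produce near-singular rows. DMUs with
  *all* inputs zero are rejected.
* **Pattern split.** Seeding uses the robust per-service ratio y/x
  (below half the median ratio seeds the turnover group) rather than
  pooled-regression residuals: the few high-turnover services are large
  and carry the pooled fit's leverage, so no extreme negative residual
  appears at realistic sample sizes. Reassignment to the nearer of the
  two refitted lines is iterated to stability (max 20 rounds) with
  nearness on the relative scale |y − ŷ|/max(ŷ, 1), matching the
  multiplicative noise; absolute distance lets large noisy services leak
  between patterns. The beds-based and days-based analyses are split
  independently — the source fits have different group sizes, so a
  shared partition is not forced.
* **Fuzzy boundaries.** The transform is continuous at $x_l$; at $x_r$
  the penalty branch starts at $x_r$, the *extreme value* of the
  reflection branch (which itself maps $x_r \mapsto x_l$). Pointwise
  continuity at both edges is impossible for reflection-type rules, and
  the implemented contract — out-of-range values strictly less
  favourable than every within-range value, monotonically in distance —
  is the one that matters for DEA.
* **Quartiles.** Type-7 quantile cuts at 25/50/75 % of the service RTE
  means, assignment by mean ≤ cut, ties broken by service id: gives even
  splits when n divides by 4 and a deterministic (2, 1, 1, 1) pattern at
  n = 5.
* **Mann–Whitney.** Exact two-sided p for combined n ≤ 20 without ties,
  normal approximation with tie correction otherwise; verified against
  exhaustive permutation for n₁ + n₂ ≤ 8. No multiple-testing
  correction across workforce categories, mirroring the reporting
  convention of the field; this is noted, not "fixed".
* **Group statistics.** Per-code and per-typology rows pool run-level
  score samples (the run distribution is the primary object); averaging
  service-level statistics instead is available via `pool_runs = FALSE`.

## Sampling variability at desk scale

With ~25 services and a population R² near 0.9, the OLS slope's relative
standard error is about $\sqrt{(1-R^2)/R^2}/\sqrt{n-1} \approx 0.07$, so
"slope within ±0.1" is only a ≈ 85 % event *even for a perfectly
specified generator*. Desk-scale recovery examples are therefore checked
at frozen seeds, while ±0.1 recovery is asserted unconditionally at
10× scale, and the acceptance report measures the regression targets on
a 25× ecosystem where sampling noise is small relative to the reported
tolerances.

## Known limitations

* Input-oriented VRS DEA makes the largest-output DMU in any run
  self-referencing and hence efficient regardless of its inputs; under
  perturbation, dominated copies of the top frontier point can
  occasionally be classified efficient. This is a property of the model,
  visible in the planted-frontier tests, not a solver artefact.
* The data-derived rule base is a stand-in for expert elicitation; RTE
  levels depend strongly on the ranges, so published score tables cannot
  be reproduced from structure alone.
* Scores can only be interpreted within a typology (input/output sets
  differ); cross-typology comparisons are not meaningful and the
  pipeline never makes them.
* The triangular perturbation treats variables as independent; any real
  covariance between staffing and utilisation within a service-year is
  ignored.
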