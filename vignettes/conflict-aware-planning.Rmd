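---
title: "Conflict-risk-aware reserve selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conflict-risk-aware reserve selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(conflictplan)
```

## The problem

Protected-area networks in politically volatile regions face a risk that
ordinary prioritization ignores: an armed conflict can render a protected
planning unit useless. A minimum-set prioritization that just meets a 30%
representation target for every feature has no slack — losing a handful of
units to conflict pushes many features below target. This package implements
a planning pipeline in which per-unit conflict risk is estimated from the
local event history and then folded into reserve selection under four
attitudes to risk, and networks are scored by Monte Carlo simulation of
conflict losses over a five-year management horizon.

The pipeline has five working parts: a synthetic landscape/conflict
generator, a logistic risk model, strategy transformations of the selection
problem, minimum-set solvers, and a Monte Carlo evaluator. Each is usable on
its own; `run_sweep()` chains them.

## The risk model

Incidents affect more than the cell they occur in (conflict actors and
displaced people move), so each incident is given a circular **impact
zone**, 30 km by default: a planning unit experiences an incident iff its
centroid lies within the radius (`assign_exposure()`). Point-in-disc
geometry on centroids, rather than polygon intersection, keeps the
definition unambiguous at grid scale and makes the brute-force test oracle
trivial.

Exposure tallies over a calibration window give three per-unit predictors:
the number of exposing incidents, their summed fatalities, and years since
the last incident. Units never exposed receive a censored
`years_since_last` of window length + 1 (the window provides no deeper
information; the value is configurable). A binary response — any exposure
during a later, disjoint validation window — is regressed on these via
maximum-likelihood logistic regression (IRLS as implemented in `glm`,
convergence 1e-8, max 100 iterations). Fit quality is summarized by
McFadden's pseudo-R², $1 - \ell_{model}/\ell_{null}$, which is 0 when the
covariates add nothing and positive otherwise. Fatalities enter
untransformed by default; a `log1p` option exists for heavy-tailed fatality
counts. Zero-variance covariates are retained with a zero coefficient (the
intercept-only limit) rather than failing; perfect separation and
non-convergence raise an error naming the offending covariate, since a risk
map built from a separated fit would be meaningless.

Predicted five-year risk is the inverse logit of the linear predictor. The
95% interval is computed on the link scale from the coefficient covariance
(`se² = xᵀVx`) and then transformed, which guarantees `0 ≤ ci_low ≤ p ≤
ci_high ≤ 1` — an interval computed on the probability scale can escape the
unit interval. Sensitivity runs re-plan on `ci_low`/`ci_high` while always
evaluating with the point estimate, so that sensitivity rows measure the
consequence of planning conservatism, not of assuming a different world.

## Four attitudes to risk

`apply_strategy()` turns units + risks + features into a selection problem:

* **ignorant** — risk plays no role.
* **avoiding** — units with `p > θ` become unavailable (locked-in units are
  always retained: existing protected areas are not un-protected by a
  planning attitude).
* **accounting** — every unit stays available, but feature amounts are
  discounted to their expected surviving value `a(1 − p)`, so cheap
  high-risk cells stop looking like bargains and extra area is selected.
* **sensitive** — avoiding then accounting on the remainder.

Targets are `T` (default 30%) of each feature's **raw** total. A target
that exceeds the total available effective amount is capped there and
flagged, rather than erroring: an unmeetable target is a reportable
outcome, not a bug.

### Reliability

Discounted amounts secure the *expected* surviving representation, not a
probability guarantee. The binomial arithmetic shows the gap: a feature in
10 cells each facing 25% loss risk, needing 3 protected survivors, has only
an 89.65% chance of success with 5 protected cells but 96.24% with 6
(`meeting_probability(6, 3, 0.25)`). `required_units()` inverts this tail.
For real features — unequal risks, fractional amounts —
`meeting_probability_hetero()` computes the probability that the surviving
amount reaches the target, exactly (enumeration of all $2^n$ loss outcomes,
vectorized, up to 20 units) or by Monte Carlo with a reported standard
error beyond that.

`enforce_reliability()` closes the loop for the accounting/sensitive
strategies: solve, measure each feature's survival reliability over the
selected units, inflate the working target of every unreliable feature by
×1.1 (capped at the available effective amount), re-solve; stop when all
features reach ρ, every shortfall is capped, or after 20 iterations,
returning a per-feature report rather than throwing. The default ρ = 0.95
is the smallest conventional reliability level consistent with the worked
example above (0.90 would accept five cells; 0.95 forces the sixth). The
1.1 inflation step converges in a handful of iterations on desk-scale
problems while avoiding gross target overshoot. The inner loop uses a
single greedy solve per iteration — reliability is a property of roughly
how much redundancy the targets force, not of which near-optimal solution
carries it — and the final inflated problem is then solved by the full
ensemble.

## Minimum-set solvers

The selection problem is the classic minimum-cost representation problem:
minimize summed cost subject to per-feature representation targets.
Locked-in (already protected) units contribute amounts but **zero
acquisition cost** — reported cost is new investment; a configurable
management-cost term is deliberately out of scope.

* `greedy_solve()` — iterative best shortfall-reduction-per-cost additions,
  ties broken by a seed-determined random ranking, followed by a reverse
  pass dropping redundant units (most expensive first).
* `anneal_solve()` — Metropolis chain over single-unit toggles with
  geometric cooling (the Marxan family's approach; the inner loop is
  compiled). The objective is cost plus
  `penalty_scale × Σ_f w_f · shortfall_f`, with `w_f` = (estimated cost of
  covering feature f from its cheapest units) / target_f, making the
  penalty scale dimensionless and feature-balanced. The chain starts from
  a random half-density selection, keeps the best state visited, and is
  finished by a greedy repair (feasibility when attainable) and trim pass.
  Deterministic under a fixed seed.
* `brute_force_solve()` — exact subset enumeration, refused above 20
  candidate units; exists as the oracle the heuristics are tested against.
* `run_ensemble()` — n independent runs (seeds `seed + 0 … n − 1`);
  selection frequency across runs is the priority signal, and the best run
  is the least-cost feasible one.

Default annealing settings (10,000 iterations, cooling 0.999, initial
temperature auto-scaled to the mean candidate cost) solve 12-unit instances
to optimality in well over half of random instances and never below the
optimum (that would indicate a bookkeeping bug, and is tested).

## Monte Carlo evaluation

`simulate_losses()` draws unit losses independently per replicate. The
default `continuous` rule loses a unit iff `u < p`, `u ~ Uniform[0,1)` —
exact. The `paper_integer` mode reproduces the classic percent-roll
variant: an integer `r ~ {1..100}` with loss iff `r < 100p`, whose
effective loss probability is `⌈100p − 1⌉/100`, up to 1 percentage point
below `p` (risks ≤ 1% can never lose). The biased variant is retained
because published analyses use it; the default is the unbiased rule.

`evaluate_network()` scores each replicate against **raw** amounts — even
when selection used discounted amounts — because a loss is realized once
in the simulation; discounting again would double-count it. Locked-in
units are lost like any others. The report gives the per-replicate targets
met, its median and 2.5/97.5 percentiles, cost, and ROI = median targets
met per billion USD (median, not mean, so a long lower tail of bad
conflict draws does not silently inflate apparent performance).
`exact_expected_targets()` is the analytic cross-check: the sum over
features of the exact survival probability, against which the Monte Carlo
mean is tested at 3 standard errors.

## The synthetic landscape

No real data ship with the package; the generator produces landscapes with
the statistical features the analysis depends on:

* **Costs** — log-normal marginal (log-sd 0.5) with separable Gaussian
  smoothing at a configurable range, rescaled to the requested mean: costs
  are positive, right-skewed and spatially autocorrelated.
* **Species** — disc ranges with per-cell jittered boundaries; contiguity
  is what target-setting needs, biological realism is not attempted.
* **Ecoregions and nations** — Voronoi partitions over random seed cells:
  contiguous, exhaustive, non-overlapping (tessellation conserves area
  exactly, which is tested).
* **Conflict** — a small set of hotspots, each emitting Poisson incidents
  per year scattered with Gaussian dispersion; hotspots persist year to
  year with probability `persistence` (history predicts future — the
  property the risk model exploits) and can be placed preferentially in
  species-rich cells (`biodiversity_coupling`, weight `exp(coupling ·
  standardized richness)`), reproducing the positive biodiversity–risk
  association that makes conflict-ignorant planning expensive. Fatalities
  are negative binomial (`size = mean/overdispersion`).

Defaults (5 hotspots, 6 incidents/hotspot/year, 25 km dispersion,
persistence 0.85, years 1999–2014 on a 30×30 grid of 10 km cells) were
chosen so that exposure is widespread but not universal: the validation
response has both presences and absences and predicted risks span the unit
interval, as in real continental event data. On much smaller grids the same
intensity saturates exposure (every unit exposed) and the risk model will
rightly refuse a constant response — shrink the hotspot count/intensity
along with the grid.

Analysis windows default to: validation = last `min(5, ⌊years/3⌋)` years,
calibration = everything before, prediction predictors = last 10 years —
the historical-data convention of calibrating on one decade and validating
on the following five years.

What the generator does **not** emulate: real map projections, population
density, borders' effect on conflict, refugee dynamics, partial losses, or
feature-specific conflict vulnerability (a lost unit loses everything).
Green tests therefore certify the machinery — estimator calibration,
solver optimality gaps, probability arithmetic, orderings among strategies
under a biodiversity-coupled conflict process — not real-world effect
sizes.

## National versus fine-scale risk

`national_risk()` replaces each unit's risk with its nation's mean
fine-scale risk. Real national risk indices are exogenous constructions;
using the within-nation mean instead preserves the one property the
scale comparison turns on — the loss of within-nation variation — without
inventing a scoring formula. National-scale avoidance consequently
excludes entire nations at once, stranding every feature endemic to a
high-risk nation; fine-scale data dissolves that artifact. Rows of a
sweep are always evaluated with fine-scale point risks so that the
comparison across scales is apples-to-apples.

## Numerical conventions

* Feasibility and amount comparisons use an absolute 1e-9 tolerance
  (amounts are km² of 10 km cells; 1e-9 is far below any physical amount).
* Exact/Monte Carlo switch in the heterogeneous probability at 20 units
  (2²⁰ enumerated outcomes ≈ 1M, still fast vectorized).
* Greedy ties are broken by a seeded random ranking; brute-force ties by
  enumeration order (lowest bitmask over id-ordered units) — both
  deterministic.
* `enforce_reliability`: inflation ×1.1, max 20 iterations, Monte Carlo
  reliability at 10,000 replicates for features held in >20 units.
* All randomness is seed-scoped: generators and solvers restore the
  caller's RNG state, and every ensemble/sweep derives child seeds from
  its master seed, so identical configurations give identical results.

## Worked example sizes

The examples and tests in this package run on a 30×30 grid (900 units, 40
species + 6 ecoregions), 25-run ensembles and 500-replicate evaluations —
sizes chosen so a full strategy sweep completes in minutes on a laptop
while leaving the orderings of interest (accounting beats ignorant on ROI;
fine-scale beats national-scale accounting on targets met; avoidance at
low thresholds strands features) clearly resolved. Published
continental-scale analyses use two to three orders of magnitude more units
and 100-run ensembles; nothing in the implementation is specific to the
desk scale, but expect the annealer to need more iterations as instances
grow.

## Known limitations

* Risk is modelled from event history alone (three covariates); no
  socio-political covariates, and no interactions — deliberately, to stay
  within what event data support.
* The annealer makes no compactness/boundary-length adjustment; solutions
  can be spatially fragmented.
* Conflict losses are binary and independent across units given the risk
  map; spatially correlated conflict shocks would widen the true outcome
  distribution relative to what the evaluator reports.
* The reliability loop guarantees per-feature marginal reliability, not
  joint reliability across all features simultaneously.
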