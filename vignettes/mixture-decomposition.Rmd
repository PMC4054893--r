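---
title: "Maximum-likelihood tumor mixture decomposition from read depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-likelihood tumor mixture decomposition from read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(tumormix)
```

## The model

A bulk tumor sample is a mixture of cell populations: admixed normal cells
with a diploid genome, and one or two tumor subpopulations whose genomes
carry copy number aberrations. Given a segmentation of the genome into `m`
intervals and the read counts of the tumor sample and a matched normal
sample over those intervals, `tumormix` infers

* an **interval count matrix** `C` (`m x n`): integer copy numbers per
  interval for each of the `n` genomes in the mixture, with column 1 fixed
  to the all-2 normal genome, tumor entries in `{0, ..., k}`;
* a **genome mixing vector** `mu` on the unit simplex: `mu[1]` is the
  fraction of normal cells (so `1 - mu[1]` is the tumor purity).

Reads are modelled as falling independently into intervals with probability
proportional to the amount of DNA the mixture presents there: interval `j`
attracts reads with probability proportional to `w_j * (C mu)_j`, where the
weight `w_j` accounts for interval length and mappability and is taken from
the matched-normal counts. The tumor read depth vector `r` is then
multinomial, and the fit minimizes the negative log-likelihood
`-sum_j r_j log p_j(C, mu)` (the multinomial coefficient is a constant in
`(C, mu)` and is dropped everywhere; `0 log 0 = 0`).

This is a maximum-likelihood generalization of the visual "peak at ratio
`(1 - f) + f c / 2`" reasoning used when inspecting corrected read depth
ratios; the helpers `expected_ratio()` and `corrected_ratio()` expose those
closed forms.

## Reduction to an unweighted problem

Two coordinate changes make the optimization tractable.

**Weights.** Solving the weighted problem on `r` is equivalent to solving
the *unweighted* problem on the transformed vector
`inverse_weight_transform(r, w) = normalize(r / w) * sum(r)`. All internal
ranking therefore happens in transformed space; the reported `nll` of each
solution is the transformed-space objective (identical to the model nll when
all weights are equal, and offset by a constant otherwise, so comparisons
between solutions and between models are unaffected).

**Mixing coordinates.** For fixed `C`, `normalize(C mu)` equals
`Chat mu'` where `Chat` has L1-normalized columns and
`mu'_h` is proportional to `mu_h * ||c_h||_1` (`mu_to_internal()` /
`internal_to_mu()`). In the `mu'` coordinates the parameter is a convex
combination of fixed simplex points, so the per-candidate subproblem
`min_mu' -sum_j r_j log (Chat mu')_j` is convex.

## The search

With `C` free, the problem is combinatorial: each tumor column ranges over
`(k+1)^m` integer vectors. Two facts cut this down:

* **Order restriction.** At an optimum, each tumor column has *compatible
  order* with the (transformed) read depth vector: positions with strictly
  larger read depth never carry strictly smaller copy number. The package
  uses the weak reading of this condition — ties in either vector impose no
  constraint — so a constant column is compatible with everything. Without
  per-interval bounds the surviving candidate count for one tumor column is
  `choose(m + k, k)` instead of `(k+1)^m` (`count_tumor_columns()` verifies
  this identity).
* **Separable convex subproblem.** For `n = 2` the candidate's objective
  depends on an interval only through its copy value, so the 1-D problem is
  solved on at most `k + 1` grouped terms by a safeguarded Newton/bisection
  root find on the derivative — a few microseconds per candidate. For
  `n = 3` the 2-simplex subproblem is solved by alternating exact line
  searches in a nested parametrization, reusing the same 1-D machinery.

The enumeration and subproblems run in compiled code (`src/mlmdp.cpp`)
as a depth-first walk over non-decreasing value assignments within groups
of equal read depth, with per-interval bounds honoured during the walk. For
`n = 3`, pairs of materialized columns are pruned when some interval pair
inverts *both* tumor columns against the read depth order (a provably safe
subset of the full restriction; surviving solutions are re-checked against
the order condition afterwards).

All solutions within `tie_tol` of the optimum are returned: distinct
`(C, mu)` can produce exactly the same multinomial parameter (for example
proportional tumor columns at `n = 3`), so the tie set — not a single
arbitrary member — is the honest answer. `select_representative()` picks a
canonical member for reporting: the solution carrying the most genomic
length at copy number 2, ties broken toward larger normal fraction.

## Choosing the number of subpopulations

`select_model()` fits `n = 2` and `n = 3` on the same intervals and bounds
and compares them with a modified Bayesian information criterion
(`modified_bic()`):

```
-2 log L + gamma * (m + 1) * (n - 1) * log(b)
```

with `a = (m + 1)(n - 1)` free parameters and `b` the total read count of
both samples over the intervals. The multiplier `gamma` (default 10)
penalizes the larger model more strongly than the classical BIC
(`gamma = 1`).

Two practical caveats, both measurable with the package itself:

* The criterion presumes the multinomial model is exact. Real read depth
  estimates carry extra multiplicative noise (`phi` below), which injects
  on the order of `N * phi^2 / 2` nats of residual deviance for `N` tumor
  reads. At small `m` the *unbounded* two-clone candidate set is dense
  enough to absorb most of that residual, so the likelihood gain of `n = 3`
  on data generated with a single tumor clone can exceed the penalty — the
  criterion then overfits regardless of `gamma` in a moderate range. The
  candidate set thins out as `m` grows (the penalty also grows with `m`),
  and tight per-interval bounds from `infer_baseline_bounds()` remove most
  of the absorbing capacity: in our measurements the same overfitting
  instance is selected correctly once data-derived bounds are applied.
* Conversely, bounds derived from the modal read depth ratio clamp
  intervals whose ratio sits within the baseline window, so a weak
  subclonal signal (a clone at a few percent of the sample, shifting ratios
  by less than the window half-width) can be erased by the bounds and the
  second clone becomes undetectable. Detection requires clones whose ratio
  shifts clear both the noise floor and the baseline window.

The acceptance test for model selection (`tests/testthat/test-acceptance.R`,
criterion 8) encodes both directions with fixed seeds and documents the
direction that remains unmet at desk scale; the decision history and the
measured likelihood gains are recorded in the repository notes.

## The simulation generator

`simulate_tumor_sample()` reproduces the benchmark protocol used by the
acceptance tests:

* intervals: by default the 39 non-acrocentric autosome arms of hg19
  (approximate coordinates embedded in `autosome_arms()`), with arm lengths
  as weights; other `m` use unit weights;
* `C`: tumor entries i.i.d. uniform on `{0, ..., k}`; an all-zero tumor
  column (an empty genome, which makes the mixture degenerate) is redrawn,
  as are identical tumor columns at `n = 3`;
* `mu`: normal fraction uniform on `purity_range` (default `(0.1, 0.9)`);
  at `n = 3` the tumor mass is split with each clone at least
  `min_clone_fraction` (default 5%) of the sample;
* `r`: expected counts `total_reads * p(C, mu, w)` perturbed by
  multiplicative Gaussian noise with coefficient of variation `phi` (the
  *read depth estimation error*), rounded; the matched-normal counts are
  noiseless rounded expectations, so `phi` is applied once, to the tumor
  sample.

The generator is intentionally narrow: it simulates arm-level events with
independent uniform copy numbers, not correlated segmental landscapes, and
its noise is Gaussian-multiplicative rather than overdispersed-count noise
estimated from real libraries. It is the protocol the evaluation utilities
(`run_benchmark()`, `exact_match()`, `copy_number_error()`,
`purity_error()`) are designed around, not a general cancer genome
simulator.

## Numerical choices

* Per-candidate 1-D optimization: safeguarded Newton/bisection on the
  derivative to `opt_tol = 1e-12` in the internal coordinate; logarithms are
  only evaluated once per candidate, at the optimum.
* Tie set: all candidates within `tie_tol = 1e-6` nats of the optimum are
  kept; solutions are deduplicated on canonical `(C, round(mu, 6))` and
  re-filtered with a `1e-9`-tolerant order check to guard optimizer
  round-off.
* The `n = 3` alternating line search stops when an iteration improves the
  objective by less than `1e-10` nats (at most 500 iterations).
* Read counts are treated as doubles throughout; transformed depths are
  real-valued by construction.

## Problem sizes

The package's own choices of feasible sizes (1 CPU):

* `n = 2`: the default benchmark size `m = 39, k = 3` solves in
  milliseconds (`choose(42, 3) = 11480` candidates); `k = 7`
  (`choose(46, 7) ~ 5.4e7` candidates) takes about half a minute per
  dataset.
* `n = 3`: cost is quadratic in the number of admissible columns, so
  unbounded searches are practical up to roughly `m = 8, k = 2`; larger
  instances need per-interval bounds (`infer_baseline_bounds()`), which is
  also how the method is intended to be run on real segmentations.

## Limitations

* **Low purity.** The per-copy read depth signal scales with purity; with
  purity below ~0.3 and `phi = 0.03`, single-copy steps approach the noise
  floor and exact recovery of all `m` entries is not reliably possible for
  any estimator. Purity estimates degrade much more gracefully than exact
  matrix recovery.
* **Identifiability.** Proportional tumor columns at `n = 3` leave the
  split of tumor mass between clones undetermined (the tie set makes this
  visible); at `n = 2` the all-normal and all-diploid-tumor solutions are
  indistinguishable by construction.
* **Model selection at small m** inherits the overfitting caveat above.
* The maximum copy number `k` must be set by the user; amplifications above
  `k` bias neighbouring estimates.
* Input intervals are trusted as given; segmentation and read counting are
  out of scope.
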