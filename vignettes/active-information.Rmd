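---
title: "Quantifying learning and knowledge acquisition with active information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying learning and knowledge acquisition with active information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ainlearn)
```

## The model

`ainlearn` treats an agent's beliefs as epistemic probabilities on a space
of *possible worlds* `X` — the parameter space of a statistical model, of
which exactly one point `x0` is true and all others are counterfactual.  A
proposition `S` corresponds to a truth set `A = {x : f(x) = 1}`, the worlds
in which it holds.  A maximally ignorant person holds the maximum-entropy
uniform measure `P0`; the agent holds a Bayes posterior `P` built from a
prior, a likelihood model `x -> L(D | x)` and observed data `D`.  The
framework is deliberately hybrid: beliefs are Bayesian, but the criteria
below are frequentist because they refer to the true world `x0`, which no
purely Bayesian analysis can see.

The central statistic is the **active information** of the truth set,

$$I^+(A) = \log \frac{P(A)}{P_0(A)},$$

the log-ratio of the agent's belief in `S` to the ignorance baseline.  It
is bounded above by the *functional information* $-\log P_0(A)$ (attained
at full learning, `P(A) = 1`) and equals $-\infty$ exactly when the agent
has ruled `A` out.

* **Learning** has occurred when belief moved in the true direction:
  $I^+(A) > 0$ if `x0` is in `A`, $I^+(A) < 0$ if it is not.
* **Knowledge acquisition** (justified true belief) additionally requires
  the belief to concentrate around the true world: for every radius
  $\epsilon > 0$, $P(B_\epsilon(x_0)) > 0$ and
  $P(B_\epsilon(x_0)) \ge P_0(B_\epsilon(x_0))$, strictly for some radius.
  Full knowledge is the point mass $\delta_{x_0}$.

Learning doubles as a hypothesis test of H0 "`S` is true" versus H1, which
rejects when $I^+(A) \le I$; with the threshold mapped through
$I = -\log[P_0(A)(1 + r)]$ this is decision-identical to the Bayesian rule
"choose H1 when the posterior odds exceed `r`", and the package tests that
equivalence property directly.  Type I/II error rates are computed exactly
by enumerating the data space or by seeded Monte Carlo.  The posterior
expectation of the singleton-set statistic recovers the Kullback–Leibler
divergence $D_{KL}(P \| P_0)$, and its data average the mutual information
between parameter and data, both of which `kl_ain()` and
`mutual_info_ain()` compute and the tests cross-check by independent
enumeration.

Sequential processes use nested discernment partitions and growing data
sets, with three grades of verdict: **strong** (the whole chain
$0 \le I_1^+ \le \dots \le I_n^+$ is monotone with a strict step, plus
monotone ball chains for knowledge), **weak** (only the final step counts),
and **asymptotic** (tail estimates of $\liminf P_k(A)/P_0(A)$; see
"Numerical choices" below).

## Discernment

An agent cannot discern worlds beyond a partition `G` of the space: within
each cell of `G` their beliefs must keep the shape of the baseline.  The
package enforces this constructively rather than assuming it: when a
likelihood model declares a measurability partition, the likelihood is
averaged over each cell under the prior before any update, so every
posterior passes `check_discernment()` by construction.  `coarsen()` is
the corresponding projection, and `g_optimal()` is the best attainable
belief under a partition — all mass on the cell containing `x0`,
baseline-shaped within it.  Under the finest partition of a finite space
it collapses to the point mass at `x0`; under the trivial partition it is
the baseline itself.

## Representation and numerical choices

* **Spaces.** Finite spaces are labelled points; continuous spaces are
  axis-aligned boxes on uniform grids (default 200 cells per dimension,
  1000 for the one-dimensional coin space).  Belief measures are
  piecewise-constant densities stored as per-cell masses, plus explicit
  atoms for point masses.  Atoms are never approximated by narrow
  densities, so `I+ = -Inf` and full-knowledge checks are exact.
* **Quantisation.** Dating/forecast cells follow the half-open convention
  `((i-1)δ, iδ]` with index `floor(x/δ) + 1`; grid resolutions must be
  integer multiples of `1/δ` so partition boundaries align exactly with
  grid cells and coarsening is exact.
* **Regions.** Axis-aligned regions and one-dimensional balls store exact
  per-cell overlap fractions, so their probabilities under
  piecewise-constant measures carry no rasterisation error.  Euclidean
  balls in two or more dimensions are rasterised by cell-centre
  membership; the exact membership function is kept for atoms.
* **"For all ε" conditions.** Ball probabilities are monotone in the
  radius and the measures are piecewise constant, so the quantifier is
  evaluated on a finite grid: `{0, 1}` for categorical metrics, integer
  radii for Hamming, and a geometric grid of 32 radii from the cell width
  to the space diameter for boxes.
* **Strictness margin.** All strict inequalities in the verdicts use an
  absolute margin `tau = 1e-9`; equality within `tau` counts as
  non-strict.  This prevents floating-point noise from manufacturing a
  "strict step".
* **Tie-breaks.** Exact equality `I+ = I` rejects H0 (the test is defined
  with `<=`); grid maximisation in `lr_statistic()` breaks ties toward
  the smallest cell index.  Logs are natural by default with a base-2
  switch.
* **Asymptotics are diagnostics.** The limit conditions are
  operationalised as min/max over the trailing 20% of a finite
  trajectory, and every asymptotic verdict is labelled diagnostic: a
  finite run supports but never proves a limit.
* **Degenerate inputs.** `P0(A)` in `{0, 1}` makes learning undefined and
  errors; impossible data (zero normaliser) errors; Monte Carlo without a
  seed errors — reproducibility is a contract, not a convention.

## The worked experiments

The generators double as documentation and as the synthetic-data layer of
the test suite.  Their defaults are the study conditions, chosen once:

* `student_experiment()` — three worlds (guessing / skilled / helped),
  uniform prior, scores `Bin(10, 0.5/0.8/0.8)`.  Skilled and helped
  students score identically, so the score discernment cannot separate
  them and no score can push `P(x2)` above 0.5; a second-step helper
  signal resolves the ambiguity.  At score 7 the agent learns the scoring
  proposition; after the helper signal says "no help", `P(A)` drops while
  `P(x2)` rises — learning in the weak but not the strong sense, and
  knowledge about the skill proposition.
* `coin_experiment()` — heads probability on `[0, 1]` (grid 1000), margin
  `eps = 0.1`, conjugate `Beta(1 + m, 1 + k - m)` posteriors evaluated in
  closed form, cross-checked against the generic grid update.
* `dating_experiment()` — dating precision `δ = 0.1`, famine `[0.3, 0.6]`
  (endpoints aligned with the dating cells), true time 0.47, 20 grid
  cells per dating cell.  The `-δ` biased variant is a
  true-world-excluding measure: strong learning holds, strong knowledge
  fails because small balls around `x0` carry no mass.
* `camp_experiment()` — forecast precisions `(0.1, 0.2)`, activity range
  `[0.2, 0.8]`, true temperatures `(0.55, 0.55)`.  The ellipse preset for
  the second-step measure is only qualitative — its exact shape is a free
  design choice — and exists to realise "biased but correct-side"
  beliefs: learning without knowledge.
* `replication_experiment()` — tolerance `eps = 0.04`, quantisation
  `δ = 0.1`, true prevalences `(0.55, 0.55)`.  Under partial information
  transfer the replication probability is the exact cell-overlap formula
  and can never reach 1 when `2 eps < δ`.
* `confounding_experiment()` — logistic outcome model with known
  coefficients, independent Bernoulli(0.5) covariates by default (the toy
  assumption that makes the counterfactual curve computable by plain
  marginalisation and equal to the observed curve; dependent covariates
  would separate them).  Everything is exact enumeration, capped at
  `n <= 20` binary dimensions.
* `contraction_diagnostics()` — iid Bernoulli(0.5), uniform prior, one
  posterior draw per simulated data set (matching the compound limiting
  distribution: the draw-around-MLE normal convolved with the MLE's
  sampling normal), sample sizes up to `10^4`, 2000–5000 replicates.  The
  fitted error exponent should sit near `-1/2`, the scaled variance of a
  posterior draw near twice the inverse Fisher information, and that of
  the MLE near one.

What the generators emulate — and what they do not: they reproduce the
*structure* of the scenarios (discernment limits, biased measurement,
partial information transfer, unmeasured confounding) with clean
parametric noise.  Real data bring misspecified likelihoods, dependent
covariates and priors that are not uniform; passing tests show the
framework's internal consistency and its closed-form special cases, not
robustness to those complications.

## Problem sizes

The test suite and the acceptance script run everything at the sizes
above: grids of 100–2000 cells, trajectories up to 2000 steps, 11–121
enumerated outcomes, 1500–5000 Monte Carlo replicates.  These sizes keep
every Monte Carlo standard error far below the margins being tested while
completing in seconds.

## Known limitations

* Box spaces are bounded rectangles with uniform grids; unbounded or
  infinite-dimensional parameter spaces, and maximum-entropy priors under
  constraints, are out of scope.
* Conjugate machinery is limited to Beta–binomial; other models go
  through the generic grid update.
* Euclidean balls in dimension two and higher are rasterised at cell
  centres, so ball probabilities there carry `O(grid^{-1})` error.
* The asymptotic verdicts are finite-horizon diagnostics by design.
* Only single propositions are handled; multiple propositions, social
  consensus dynamics and frequentist confidence-region knowledge curves
  are not modelled.
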