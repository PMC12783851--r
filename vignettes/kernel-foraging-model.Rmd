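---
title: "A kernel-based model of spatial foraging under ambiguity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kernel-based model of spatial foraging under ambiguity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foragekernel)
```

## The scientific problem

A forager on a uniform grid of concealed food sources must decide, search
after search, where to dig next. Nothing in the terrain reveals where food
is hidden, so every choice trades off three drives: *information seeking*
(searching where the terrain is still ambiguous), *reward seeking*
(searching near previous food finds, on the assumption that food is
spatially clustered), and *energy preservation* (searching nearby rather
than walking far). `foragekernel` implements a generative choice model
built on these three drives, simulates foragers from it, quantifies the
spatial statistics of search paths (Levy-type step-size analysis,
unimodality screening, outcome-conditioned step contrasts, a
roaming/dwelling convolutedness index), and recovers the drive weights
from recorded search sequences by maximum likelihood.

The experimental situation it models is a primate foraging arena: 81--108
woodchip piles on a uniform lattice (pitch about 0.3 m), with reward items
hidden under 21 piles according to a *localized* abundance map (a disk
with 3 items at the centre, 2 in each of the 8 surrounding piles, 1 in
each of the 12 piles of the outer margin; 31 items in total), or under 12
piles in a *scattered* map (four random L-shaped three-pile patches).

## The choice model

At every step the model maintains three fields over the piles, each a
superposition of two-dimensional Gaussian kernels evaluated at pile
centres:

* the **ambiguity map**, one kernel per *unsearched* pile (searching a
  pile removes its kernel: the pile's content is then known);
* the **reward map**, one kernel per *discovered reward item*, centred on
  the pile where the item was found (a 3-item pile contributes three
  kernels);
* the **proximity map**, a single kernel centred on the forager's current
  pile.

With mixing weights $w_{\mathrm{info}} + w_{\mathrm{rew}} +
w_{\mathrm{prox}} = 1$, the probability that an available (unsearched)
pile $x$ is chosen next is the weighted sum of the three fields,
normalised to unit sum over the available piles:

$$ P(x) \propto w_{\mathrm{info}}\,m_{\mathrm{ambig}}(x) +
   w_{\mathrm{rew}}\,m_{\mathrm{rew}}(x) +
   w_{\mathrm{prox}}\,m_{\mathrm{prox}}(x). $$

Each kernel is an unnormalised Gaussian $\exp(-d^2 / 2\sigma_m^2)$ of the
lattice distance $d$; each map $m$ averages its kernels ($1/N_m$). The
three kernel sizes $\sigma_{\mathrm{ambig}}, \sigma_{\mathrm{rew}},
\sigma_{\mathrm{prox}}$ are free parameters, interpretable as the spatial
range over which one search is informative about other piles, the assumed
spatial continuity of the hidden food, and the forager's comfortable
reach. The generative simulations use $\sigma = (3, 1, 2)$ pile units
$= (0.9, 0.3, 0.6)$ m at the default 0.3 m pitch.

Two conventions required a decision the model statement leaves open:

* **Component normalisation.** Only the final map is pinned to unit sum
  by the model statement. We normalise *each component* to unit sum over
  the available piles before weighting (then renormalise the sum). This
  keeps the weights comparable across time and map sparsity -- otherwise
  the ambiguity map, with up to 108 kernels against the proximity map's
  one, would dominate at any weight -- and it makes the likelihood
  well-defined throughout a session. When a component is identically
  zero on the available piles (the reward map before the first find; the
  proximity map when every remaining pile is beyond numerical kernel
  range), its weight is redistributed by the final renormalisation. If
  *every* weighted component vanishes the choice falls back to uniform.
* **Boundaries.** Kernels are truncated at the grid edge: no wraparound
  and no per-kernel renormalisation, so edge piles genuinely carry less
  ambiguity mass. This is visible as lower choice probability along the
  walls.

The alternative convention -- weighting the raw kernel-average fields
and normalising only the final sum (`normalize = "final"`) -- is also
implemented, and the two genuinely differ in behaviour, because under
component normalisation a single discovered item already commands a
full third of the probability mass at balanced weights. The simulated
phenotypes split accordingly: the Levy-band slope, the inverse-bell
profile and the post-success step shortening emerge cleanly under the
`"final"` convention (the form in which the weighted-sum model is
usually written down), while the roaming-to-dwelling convolutedness
shift after the first find is strongest under `"component"`. The test
suite exercises each phenotype under the convention where it is the
stated behaviour of the corresponding agent, and the fitting path
always uses `"component"`, where every weight has the same meaning at
every step and the likelihood is well-defined from the first search.

A generative agent samples the next pile from $P(x)^p$ (renormalised).
The exponent $p$ only sets the determinism of the *simulator*: $p = 0$
is uniform, $p > 10$ is almost an argmax. Phenotype simulations use
$p = 5$. The likelihood used for fitting scores the model probability
itself and never applies $p$.

### Before the first search

The proximity kernel needs a location before anything has been searched.
Simulated agents start at a configurable pile (default: the gate-side
corner, pile 0). For recorded sessions the pre-session location is
unknown, so `session_log_likelihood()` excludes each session's first
choice by default; `include_first = TRUE` scores it with the proximity
kernel at a configured start pile.

## Simulated agents

`agent_spec()` covers the generative model plus five reference
strategies: an *information seeker* (argmax of the ambiguity field, ties
at random), a *reward seeker* (uniform until the first find, then
sampling proportional to the reward field), an *energy preserver*
(uniform among the nearest available piles), a *random* searcher
(uniform without replacement -- the naive baseline whose mean first
success on a localized 9 x 12 map is $(108+1)/(21+1) \approx 4.95$
searches), and an *informed* searcher who knows the map and greedily
visits the nearest filled pile (first success at step 1; the
policy behind this upper-bound baseline is not fully specified anywhere,
and nearest-filled-pile greed is the minimal assumption that delivers
it). Weight compositions of the generative agent reproduce distinct
phenotypes, which the test suite checks: balanced weights give a
power-law (Levy-like) step-size decay with log--log slope in $[-3, -1]$;
information-dominant weights give an inverse-bell (Brownian-like)
profile; reward-dominant weights shorten post-success steps
(area-restricted search); reward-plus-proximity-dominant weights switch
the path from roaming to dwelling after the first find, raising the
convolutedness index.

## Path statistics

* **Step sizes** are Euclidean distances between consecutively searched
  pile centres (not the locomotion path), in meters via the pitch, each
  labelled with the outcome of the search it follows.
* **Binned density**: 0.2 m bins by default; density = count / (total x
  width). Power-law fits regress log density on log bin centre by
  ordinary least squares over *occupied* bins only -- adding pseudocounts
  to empty bins would fabricate mass, and a least-squares line on
  observable points is what the slope convention describes. The slope is
  base-invariant; fits with slope in $[-3, -1]$ are flagged as
  Levy-like. Fit weighting by bin count is deliberately not applied
  (unweighted OLS).
* **Dip test**: Hartigan's dip statistic -- the smallest sup-norm
  distance between the empirical cdf and any unimodal cdf -- screens
  step-size distributions for the bimodality a patch-wise search would
  produce. No implementation was available in the supported stack, so
  the package provides one: the classical iterative greatest-convex-
  minorant / least-concave-majorant refinement for samples of distinct
  values, and an exact bisection algorithm (mode enumeration with an
  $O(m^2)$ convex-interpolation feasibility check) for tied samples,
  which matter here because lattice step sizes take few distinct values.
  The two routes agree to $10^{-7}$ on distinct data and are tested
  against closed-form cases (equally spaced points give $1/2n$; two
  equal point masses give $1/4$; the two-pair family $(0, 1, 1+g, 2+g)$
  gives $g/(4(1+g))$) and against frozen values from an independent
  linear-programming solution of the defining minimax problem. The
  p-value calibrates the null by a seeded bootstrap of uniform samples
  (2000 resamples by default).
* **Outcome contrast**: geometric means (matching how such contrasts are
  conventionally reported) of post-success versus post-failure steps,
  two-sided Wilcoxon rank-sum, Benjamini--Hochberg adjustment across the
  foragers compared in one call.
* **Convolutedness**: for a sub-path with steps $d_i$ and turning angles
  $\theta_i$ between consecutive steps,
  $C = -\sum_i d_i \cos\theta_i / \sum_i d_i$ over $i = 2..n$. $C = -1$
  for straight roaming, $0$ for right-angle turning, $+1$ for repeated
  reversals (dwelling); the index is scale-invariant and bounded by
  construction. This "anchor" form is the unique reading that reproduces
  all three canonical 4-pile values ($-1$ straight, $0$ square, $+1$
  lapses). A "wrap" mode that also scores the first step -- taking the
  last step of the path as its predecessor -- is provided as an explicit
  option. Sessions are split at the first food encounter into pre-reward
  and during/post-reward sub-paths, each required to span at least 4
  searches (default) to yield a stable index.

## Fitting

`grid_search_fit()` follows a two-level scheme: the kernel sizes are
searched over the fixed 11-value list (0.1, 0.4, 0.7, 1, 1.3, 1.6, 1.9,
3, 4, 5, 6 pile units; all $11^3 = 1331$ triples), and for each triple
the two free weights $(w_{\mathrm{info}}, w_{\mathrm{rew}})$ are
optimised continuously over the simplex interior
($w \ge 10^{-6}$, honouring the strict-positivity constraint while
keeping the feasible set closed), with
$w_{\mathrm{prox}}$ as the complement. Restricting the $\sigma$s to a
grid avoids recomputing kernel superpositions inside a continuous
optimiser. Two implementation layers exist deliberately:
`fit_weights_given_sigmas()` is the reference path (BFGS on a softmax
parametrisation via `stats::optim()`), and the grid/bootstrap machinery
uses a compiled damped-Newton iteration warm-started across neighbouring
cells; the test suite checks the two agree cell by cell. Replaying a
session factorises over components, so the whole grid needs only
$3 \times 11$ replay columns. Field masses are summed directly over
available piles (never by subtracting prefix totals): with
$\sigma = 0.1$ the true normalising mass can be $\sim 10^{-22}$, far
below the cancellation error of any difference scheme. A choice the
model assigns zero probability (possible only through underflow at tiny
$\sigma$) makes that cell's likelihood $-\infty$; the cell is recorded
and skipped, not fatal. The likelihood surface over the two free weights
is empirically unimodal (the test suite scans a coarse simplex lattice),
so a single initialisation suffices; a multi-start flag verifies this.

`bootstrap_fit()` repeats the full grid search on 100 random subsets,
each containing 80% of the pile searches pooled across sessions, drawn
without replacement. Subsets resample *steps*, not sessions; an excluded
step still updates the replayed state so that the field sequence matches
what the forager actually experienced. With `fraction = 1` all subsets
coincide and the weight spread collapses to zero, which the tests use as
a consistency check. `weight_decodability()` compares two bootstrap
weight distributions by rank-based AUC (ties count one half).

## The synthetic-data generator as study stand-in

The generator reproduces the study's structural conditions: 9 x 12 (or
9 x 9) grids at 0.3 m pitch, localized 21-pile/31-item maps with the
centre drawn uniformly among positions whose disk avoids the edges,
scattered 4-patch maps, sessions started at a corner pile and truncated
either when all rewards are found or at a step cap. Two defaults are the
package's own choices where no value is stated: scattered patches hold
one item per pile and may not overlap (enforced by rejection sampling),
and batch corpora cap sessions at lengths comparable to real sessions
(a 9 x 12 localized session pooled over four animals averages roughly
45 searches).

Parameter-recovery validation simulates the corpus from the *scored*
model, i.e. with $p = 1$: the likelihood deliberately omits the
sharpening exponent, so recovery against a $p = 5$ corpus would conflate
estimator bias with model mismatch. The suite uses 200 sessions at
weights $(0.4, 0.3, 0.3)$, $\sigma = (3, 1, 2)$, a 45-step cap, and
requires every bootstrap-median weight within $\pm 0.1$ of truth.

What passing these tests does *not* show about real data: the generator
draws i.i.d. sessions from a stationary policy, with no learning across
sessions, no satiation or loss of interest, no locomotor constraints,
and outcomes read instantly and noiselessly. Agreement on synthetic
corpora validates the estimator and the statistics, not the behavioural
model itself.

## Numerical choices and problem sizes

* Kernel computations run in lattice units; $\sigma$ given in meters is
  converted through the pitch. The canonical grid values are pile units
  (3 piles = 0.9 m).
* Dip bisection runs 60 halvings (precision far below $10^{-12}$); the
  bootstrap null is seeded and reproducible.
* The compiled weight optimiser stops at gradient norm $10^{-8}$
  (relative) or 100 iterations, with backtracking line search and
  simplex clipping; degenerate subsets are skipped and logged.
* Test-suite problem sizes were chosen to make the statistical
  assertions stable at modest cost: 1000 seeds for map structure, 100
  sessions per phenotype, 200 sessions with 100 bootstrap subsets for
  recovery, 1500 sessions for the random-baseline mean.

## Worked example

```{r example, eval = FALSE}
grid <- make_grid(9, 12, pitch = 0.3)
map <- generate_localized_map(grid, seed = 1)
spec <- agent_spec("generative", weights = weight_set(1/3, 1/3, 1/3),
                   kernels = kernel_params(0.9, 0.3, 0.6, units = "m"),
                   p = 1, stop_rule = "all_rewards", max_steps = 45)
logs <- simulate_sessions(100, grid, spec, seed = 1)

steps <- dplyr::bind_rows(lapply(logs, step_sizes))
fit_power_law(bin_density(steps))          # Levy-band slope
outcome_step_contrast(steps)               # post-success step shortening

boot <- bootstrap_fit(logs, seed = 1)
generics::tidy(boot)                       # weight medians and intervals
ggplot2::autoplot(boot)                    # sorted stacked weights
```

## Known limitations

* Off-lattice (continuous-space) kernels, temporal decay of information
  and memory models are out of scope.
* Applied to idealised lattice step sizes the dip test reacts to the
  lattice's own atoms (a unimodal distribution can carry at most one
  point mass): it is designed for measured, quasi-continuous distances.
* The dip test's tied-sample path is exact but $O(m^2)$ per bisection
  step in the number of distinct values; for very large tied samples it
  is slower than the distinct-value path.
* The informed-searcher baseline is one of several defensible "knows the
  map" policies; its statistics (other than first success at step 1)
  depend on that choice.
* Sessions with revisits are scored by skipping the revisit events;
  alternative treatments (e.g. a renewal of the ambiguity kernel) are
  not modelled.
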