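# foragekernel

Kernel-based modelling of spatial foraging under ambiguity.

`foragekernel` is for behavioural ecologists and neuroscientists who study
how a forager chooses *where to search next* on a terrain that gives no
sensory hint of where food is hidden. The motivating setting is a primate
foraging arena: a uniform grid of 81--108 woodchip piles (pitch ~0.3 m)
concealing reward items laid out by a hidden abundance map -- either one
localized 21-pile disk holding 31 items (3 at the centre, 2 in the eight
piles around it, 1 in the twelve piles of the outer margin) or four
scattered L-shaped 3-pile patches.

At the package's core is a generative choice model in which the
probability that an unsearched pile \((x, y)\) is searched next is a
weighted sum of three Gaussian kernel density fields,

```
map_prob = w_info * map_ambig + w_rew * map_rew + w_prox * map_prox ,
w_info + w_rew + w_prox = 1 ,
```

where each map superposes kernels `exp(-d^2 / 2 sigma_m^2)`: one per
unsearched pile (ambiguity -- information still to be gained), one per
discovered reward item at its find location (reward -- assumed spatial
continuity of food), and one at the forager's current pile (proximity --
energy preservation). Searching a pile removes its ambiguity kernel, adds
one reward kernel per item found, and recentres the proximity kernel.
Simulated agents sample from `map_prob^p` (`p = 5` in the phenotype
simulations); model fitting maximises the log-likelihood
`LL = sum_j log map_prob(chosen pile_j)` over the weights, with the three
kernel sizes searched over a fixed 11-value grid (1331 triples) and
uncertainty from 100 bootstrap refits on 80% subsets of the pooled pile
searches.

Around the model: session simulation (generative, information-seeker,
reward-seeker, energy-preserver, random and informed agents), step-size
statistics with power-law (Levy) fits, Hartigan's dip test of unimodality
(implemented from scratch, exact also for tied samples), post-success vs
post-failure step contrasts, a convolutedness (roaming/dwelling) index,
and ROC-based comparison of fitted weight distributions.

## A worked example

```r
library(foragekernel)

grid <- make_grid(9, 12, pitch = 0.3)           # 108 piles
spec <- agent_spec("generative",
                   weights = weight_set(1/3, 1/3, 1/3),
                   kernels = kernel_params(0.9, 0.3, 0.6, units = "m"),
                   p = 1, stop_rule = "all_rewards", max_steps = 45)
logs <- simulate_sessions(20, grid, spec, seed = 1)

steps <- dplyr::bind_rows(lapply(logs, step_sizes))   # 880 steps
fit_power_law(bin_density(steps))
#> <power_law_fit> slope -1.734 (R^2 0.646), inside the Levy band [-3, -1]

outcome_step_contrast(steps)[c("geomean_success", "geomean_failure", "p_value")]
#> # A tibble: 1 x 3
#>   geomean_success geomean_failure  p_value
#>             <dbl>           <dbl>    <dbl>
#> 1           0.828            1.08 1.40e-09

boot <- bootstrap_fit(logs, seed = 1)
generics::tidy(boot)
#> # A tibble: 3 x 4
#>   term   estimate conf.low conf.high
#>   <chr>     <dbl>    <dbl>     <dbl>
#> 1 w_info    0.296    0.270     0.339
#> 2 w_prox    0.296    0.265     0.327
#> 3 w_rew     0.412    0.362     0.442
```

The power-law slope inside `[-3, -1]` is the conventional signature of a
Levy-like search; the smaller post-success geometric-mean step (0.83 m
vs 1.08 m after failures) is area-restricted search -- the forager
favours the vicinity of its finds; and the bootstrap medians recover the
equal information/reward/proximity composition of the simulated forager
to within about 0.08, with its sampling uncertainty. (Hartigan's dip
test, `dip_bimodality()`, is meant for *measured* step sizes, which are
quasi-continuous; applied to idealised lattice distances it flags the
lattice's own atoms.) `ggplot2::autoplot()` methods draw the session
path, the log--log density with its fitted line, and the sorted stacked
bootstrap weights.

`run_pipeline()` drives simulate / analyze / fit end to end from one flat
YAML config with per-stage seed substreams and a manifest, writing
session CSVs (`step,pile_id,reward_count`), a binned-density CSV, and
JSON reports.

See the vignette (`vignettes/kernel-foraging-model.Rmd`) for the model's
assumptions, the normalisation conventions, and all tunable parameters.

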