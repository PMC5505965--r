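---
title: "Modeling heritable phenotypic heterogeneity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling heritable phenotypic heterogeneity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomem)
```

## The model

`phenomem` simulates a haploid Wright–Fisher population of fixed size $N$
with one biallelic locus. The wild-type allele $A$ expresses a single fixed
phenotype $\Phi_A$; the plastic allele $a$ draws its phenotype from a random
variable $\Phi_a$ with positive variance. Fitness equals phenotype (constant
environment) or a linear map of phenotype (periodic environment), so the
whole phenotype support must be strictly positive.

Each generation proceeds in a fixed order:

1. the environment for the current generation index is determined;
2. fitness is evaluated for every individual;
3. $N$ parents are sampled with replacement with probability proportional to
   fitness (normalization by mean fitness cancels in proportional sampling,
   so raw weights are used);
4. offspring phenotypes are assigned: $A$-offspring always express $\Phi_A$;
   an $a$-offspring retains its parent's phenotype with probability $p$ (the
   *phenotypic memory*) and otherwise redraws independently from $\Phi_a$.

Two variant inheritance modes are provided. Under **global memory** a single
Bernoulli($p$) is drawn per generation and, on failure, one shared fresh
draw is assigned to every $a$-offspring, so the whole $a$-subpopulation
expresses one phenotype at a time; this is the between-generation-variance
regime in which low-fitness realizations are retained exactly as readily as
high-fitness ones. Under **switching**, the classic two-phenotype switch,
each offspring flips to the other support point with probability $q$.

In the periodic regime two environments alternate every $n$ generations.
Fitness in $E_1$ is the identity $f^1(x) = x$; fitness in $E_2$ is the
reflection around the midpoint $m$, $f^2(x) = 2m - x$. The reflection is an
involution and preserves the phenotypic variance, so each allele has the
same mean fitness in its preferred environment and the analysis isolates the
effect of variance and memory rather than any mean-fitness advantage.

## The analytic approximation chain (constant environment)

For a two-point $\Phi_a$ with support $\{\Phi_{a,min}, \Phi_{a,max}\}$ the
two phenotypes inside the $a$-lineage behave like two alleles under
proportional selection with symmetric switching at rate $\mu = (1-p)/2$.
The chain composed by `plastic_fixation_probability()` is:

* `balance_frequency()` — the stable root $f_{a,max}$ of the
  selection–mutation balance quadratic (checked in the tests against a
  brute-force fixed-point iteration of the one-generation recursion, and
  against the equivalent mean/sd parameterization to $10^{-12}$);
* `effective_selection()` —
  $s_a = (\Phi_{a,min}(1-f_{a,max}) + \Phi_{a,max}f_{a,max})/\Phi_A - 1$;
* `kimura_fixation()` — $(1-e^{-2s_a})/(1-e^{-2Ns_a})$, with the limit
  branch $1/N$ taken for $|s| < 10^{-8}$ where the ratio is numerically
  indeterminate;
* `loss_mutation_probability()` — a lineage introduced at the unfit
  phenotype decays like $e^{-st}$, so its expected cumulative copy number is
  $\sum_t X_t = 1/(1-e^{-s})$ and the chance of at least one phenotypic
  mutation before loss is $P(\eta) = 1-(1-\mu)^{1/(1-e^{-s})}$;
* the uniformly random start gives
  $P_f(a) = \tfrac12 P_f(a_{max}) + \tfrac12 P(\eta)P_f(a_{max})$.

**Choice of the decay coefficient.** The derivation of $P(\eta)$ concerns
the decay of the lineage while it still carries the unfit phenotype, so the
default is $s = 1 - \Phi_{a,min}/\Phi_A$, the selective disadvantage of that
phenotype against the resident. The alternative $s = |s_a|$ is available via
`s_loss = "abs_s_a"`; the two give visibly different $P(\eta)$ and both are
exposed because the choice is genuinely underdetermined by the derivation.

At $\mu = 1/2$ (no memory) the balance sits at exactly $f_{a,max} = 1/2$:
symmetric switching at rate one half equilibrates the two phenotypes
regardless of selection, which is why the memory-free allele is effectively
neutral — its lineage mean fitness equals $\Phi_A$.

## Randomness and reproducibility

All randomness flows through R's RNG, including inside the compiled core.
Replicate $i$ of an ensemble uses the derived stream
`set.seed((master_seed * 48271 + offset + i) mod 2147483629)`; a sweep
gives grid point $j$ the offset $(j-1)\,n_{\mathrm{replicates}}$. The
master seed is scrambled by the MINSTD multiplier so that nearby master
seeds (1, 2, 3, ...) index disjoint replicate streams instead of shifted,
almost fully overlapping ones — without the scramble, two ensembles run at
master seeds differing by $\delta$ share all but $\delta$ of their
replicate streams and their Monte Carlo errors are almost perfectly
correlated. Consequences of the scheme: an identical (configuration,
master seed) pair reproduces every estimate bit-for-bit; any single
replicate can be re-run in isolation; and grid points in a sweep share a
master seed without stream collisions.

When the initial environment is `"random"` it is resolved once per
replicate, with probability one half each, as the replicate's first random
draw.

## Monte Carlo protocol and its defaults

The default protocol is an ensemble of 10,000 replicates with a discard
cutoff of 10,000 generations: replicates that have not absorbed by the
cutoff are excluded from both the numerator and denominator of the fixation
estimate (`p_hat`), and the exact Clopper–Pearson 95% interval is reported.
At the scales exercised in the tests, discards are well below 1% of
replicates. Absorption-time summaries (mean and median over absorbed
replicates) come with every estimate.

For counter-fixation and stationary geometric-mean-fitness runs the
population is first burned in while fixed for the plastic allele, so that
the phenotype distribution reaches its stationary state. The burn-in length
is not prescribed by the model; the defaults are 40 environmental periods
($40n$ generations) in the periodic regime and $10N$ generations in the
constant regime, both configurable. The environment clock keeps running
through the burn-in, so a burn-in of $40n$ generations (an integer number of
full cycles) returns the schedule to its starting phase at the moment the
wild type is introduced.

Stationary geometric mean fitness records the population mean fitness
$\bar w_t$ each generation over windows of one full cycle ($2n$
generations) and returns $(\prod_t \bar w_t)^{1/2n}$, averaged over windows
and replicates. Because the fitness maps are linear, the fitness of the mean
phenotype equals the mean fitness, so the two readings of that quantity
coincide. The default 48 replicates × 8 windows gives a standard error
around $10^{-4}$, far below the curvature of the GM-vs-$p$ curve at the
scales tested.

## Sweeps and the location of the optimum

`sweep_memory()` and `sweep_switching()` evaluate the objective on a grid
(at least 4 distinct points), fit a cubic smoothing spline with smoothing
chosen by generalized cross-validation, and report the argmax on a
1000-point refinement of the grid span, with ties broken toward the smaller
parameter. Three numerical details:

* GCV is not trusted blindly: on grids this small it can degenerate to a
  straight line (effective df 2), which erases an interior optimum the
  data clearly show. The GCV fit is accepted only if its residuals at the
  grid points stay within twice the estimates' median standard error;
  otherwise the effective degrees of freedom are raised stepwise, falling
  back to plain cubic interpolation of the estimates. The fitted curve
  therefore always reproduces the grid estimates to within their own
  noise;
* the argmax is taken on a not-a-knot cubic interpolant of the (smoothed)
  grid values rather than on a natural-boundary spline; natural boundary
  conditions visibly bias the argmax of polynomial test data (measured:
  0.606 instead of 0.600 on an exact parabola);
* values within round-off of the maximum are treated as ties, so a
  constant objective returns the smallest grid point rather than an
  arbitrary interior one.

## Study conditions used in the tests

The end-to-end tests run at desk scale so the full suite completes in
minutes while keeping each check statistically meaningful:

* constant-environment controls at $N = 100$ with 20,000 replicates (the
  neutral control's 3-standard-error band is then $\pm 0.0021$ around
  $1/N = 0.01$);
* analytic-versus-simulation comparisons at $N = 200$, two-point
  $\sigma = 0.05$, 20,000 replicates per memory value;
* periodic sweeps at $N = 200$, uniform $\Phi_a$ with variance $1/300
  \approx 0.0033$ on the standard periodic setting ($\Phi_A = 0.6$,
  $m = 0.7$, invader mean $0.8$), 6,000 replicates per grid point. The
  memory grid for locating optima is denser near $p = 1$ because the
  optimum scales like $1 - p^\* \sim 2/n$ (the two-phenotype analogy to the
  infinite-population result that switching rates evolve toward $1/n$);
  where a tolerance of "one grid spacing" is asserted, a uniform grid
  (spacing 0.14) is used so the tolerance is unambiguous.

What the synthetic ensembles do **not** emulate: overlapping generations,
diploidy or selfing, genetic mutation between the two alleles, more than
two environments or alleles, spatial structure, and any mechanistic model
of how phenotypic states are encoded. Passing tests therefore validate the
population-genetic machinery and its approximations, not predictions about
any particular biological system.

## Degenerate inputs and edge behavior

* A degenerate invader (sd = 0) is allowed in the simulator — it is the
  neutral control — but the analytic chain rejects it: the balance quadratic
  degenerates when the two support points coincide.
* `kimura_fixation()` is exactly $1/N$ for $|s| < 10^{-8}$; as the invader
  variance shrinks, the chain recovers the neutral probability
  continuously.
* Scenario validation rejects any configuration whose phenotype support
  could reach non-positive fitness under either environment map, before any
  replicate runs.
* In YAML configurations a bare `N` key parses as a boolean under YAML 1.1;
  the loader undoes that, so both `N:` and `"N":` work.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(
  N = 200,
  resident = 0.8,
  invader = phenotype_distribution("two_point", mean = 0.8, sd = 0.05),
  memory = memory_model("individual", p = 0.8),
  n_replicates = 20000,
  master_seed = 42)
est <- estimate_fixation(cfg)
est
plastic_fixation_probability(0.8, cfg$invader, phi_A = 0.8, N = 200)
```

At these parameters the simulated fixation probability and the analytic
prediction agree within the Monte Carlo confidence interval. The package
tests probe this agreement at $p \in \{0.5, 0.8, 0.95\}$; at the highest
memory value the prediction sits at the edge of the 20,000-replicate
interval, for the reason discussed under limitations below.

## Known limitations

* The analytic chain is a weak-mutation, fast-equilibration approximation:
  it assumes the two phenotypes inside the $a$-lineage reach balance
  quickly relative to the lineage's sojourn. Forced-start decompositions in
  the test suite show that $P_f(a_{max})$ tracks simulation closely while
  the rescue term $P(\eta)$ is the weak link at small $N$ and high memory
  (at $N = 200$, $p = 0.95$, $\sigma = 0.05$ it overestimates the realized
  rescue probability by roughly a third, leaving the composed prediction at
  the edge of a 20,000-replicate confidence interval). No analytic
  approximation is provided for the periodic regime.
* Spline-located optima inherit Monte Carlo noise; at 6,000 replicates per
  grid point the located $p^\*$ is stable to roughly one grid interval,
  which is the tolerance the concordance checks use.
* The simulator is $O(N)$ memory and $O(N \log N)$ time per generation;
  it is comfortable at $N \le 10^4$ but not tuned for much larger
  populations.
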