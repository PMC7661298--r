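---
title: "Methods: pedigree-based RRS and density-corrected productivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-based RRS and density-corrected productivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salmonrrs)
```

## The scientific problem

Captive-bred (hatchery/ranched) Atlantic salmon that escape or are released
into a river can spawn alongside wild-bred fish. Two questions follow:

1. **Individual fitness.** Do captive-bred spawners leave fewer adult
   offspring than wild-bred spawners? Fitness here is lifetime reproductive
   success (LRS): the number of adult offspring genetically assigned to a
   focal parent in a molecular pedigree built from trap-censused,
   tissue-sampled returning adults.
2. **Population consequences.** Is annual population productivity (adult
   recruits per adult spawner) lower in years when captive-bred fish make up
   a larger fraction of potential spawners, after accounting for density
   dependence?

`salmonrrs` implements both analyses, plus a synthetic-data generator that
reproduces the statistical structure of such a dataset with known truth so
every estimator can be checked by parameter recovery.

## Relative reproductive success (RRS)

### The bias-corrected mean

Incomplete sampling of parents and offspring and a non-zero
parentage-assignment error rate $\epsilon$ inflate observed mean LRS: some
sampled offspring whose links are wrong land on the wrong parents. The
corrected provenance mean is

$$\bar{L}_{corr} = \bar{L} - \frac{S - A}{N}\cdot\frac{\epsilon}{1-\epsilon},$$

where $S$ is the number of offspring sampled, $A$ the number successfully
assigned, and $N$ the number of potential parents
(`unbiased_mean_lrs()`). Cohort RRS is the corrected captive mean divided by
the corrected wild mean, so wild-bred fish have RRS 1 by construction.

Two points were genuinely open and are resolved as package defaults:

* **Which $N$?** The correction is applied separately per provenance, so the
  default divides by the per-provenance parent count
  (`parent_pool = "provenance"`). Because misassigned links land on parents
  of either provenance in proportion to their numbers, the per-provenance
  $N$ slightly overcorrects the rarer provenance when group sizes are very
  unequal; `parent_pool = "pooled"` is provided for that situation. At the
  error rates this kind of pedigree reports (a few percent) the difference
  is far inside the Monte-Carlo noise, which the recovery tests confirm.
* **Counting $A$.** $A$ counts *distinct offspring* assigned, not links: an
  offspring with both parents recovered is still one assigned offspring.
* **Negative corrected means** are possible at extreme $\epsilon$; they are
  reported as-is with a warning (a clamp at zero is available but off by
  default, because truncation would reintroduce bias).

### Permutation tests

Each cohort is tested one-tailed in the a-priori direction "captive-bred
lower", by permuting provenance labels and recomputing the difference in
arithmetic means (`permutation_test()`). Two tail-counting rules are
offered:

* `strict`: $p = \#\{d^* > d_{obs}\}/B$ — the proportion of permuted
  differences exceeding the observed one; can be exactly 0.
* `weak` (default): $p = (1 + \#\{d^* \ge d_{obs}\})/(1 + B)$ — never 0 and
  slightly conservative under ties, which keeps the test valid for discrete
  LRS data. Tail comparisons use a $10^{-12}$ tolerance so that
  floating-point representation of rational mean differences cannot flip a
  tie.

Cohort p-values are combined with Fisher's method,
$\chi^2 = -2\sum\ln p_i$ on $2k$ degrees of freedom
(`fisher_combined()`). A strict-rule zero p-value would make the logarithm
undefined; the substitution policy replaces it by the weak-rule floor
$1/(B+1)$, or by a user-supplied alternative when that is *larger* — the
more conservative candidate always wins — and logs every substitution.

### Overall summaries

The overall RRS is the weighted geometric mean of the cohort estimates
(`overall_rrs()`). Weights are not dictated by the method, so the default is
total fish per cohort (captive + wild), with captive-only and custom weights
available; the scheme used is recorded in the run manifest. Cohorts with
non-positive RRS cannot enter a geometric mean and are excluded with a loud
warning rather than silently patched.

Two companion analyses probe *why* captive-bred LRS is lower:
`zero_lrs_proportion_test()` asks whether captive-bred fish more often leave
no offspring at all (spawning failure), one-sided via `prop.test`; and
`zero_excluded_rrs()` repeats the comparison among fish with LRS > 0
(consistent with transgenerational effects on offspring survival). No
$\epsilon$ correction is applied to the zero-excluded subset: the correction
is defined for the full sample of potential parents, and conditioning on
success changes the sampling frame. Finally,
`mixed_population_reduction()` converts cohort RRS values and head counts
into the percent reduction in mean individual LRS of the mixed population
relative to a hypothetical all-wild population.

## Density-corrected productivity

Productivity of spawning year $t$ is adult-to-adult:
recruits $R_t$ = wild grilse returning in $t+4$ plus wild MSW fish in
$t+5$ (all wild fish assumed to smolt at age 2+; both lags are exposed as
configuration), divided by all potential spawners $S_t$ of both provenances
(`recruits_per_spawner()`). Years missing either recruit year are dropped
and counted. Zero-recruit years make $\log P_t$ undefined; the default
drops them with a warning, and an explicit `log_offset` retains them — the
choice is logged, never silent.

Density dependence is removed non-parametrically: $\log P_t$ is regressed
on $S_t$ with a penalized cubic regression spline of basis dimension 9,
smoothing parameter chosen by generalized cross-validation
(`fit_density_gam()`, via `mgcv`). Nine knots and a penalized fit avoid
committing to a Ricker or Beverton–Holt form while still nesting smooth
monotone curves; an unpenalized basis that small cannot overfit a
multi-decade series badly, and GCV shrinks it further. The residuals are the
density-independent productivity signal. They are then regressed by OLS on
the annual captive-bred proportion (`intrusion_regression()`), with the
slope $\beta$ back-transformed to a percent reduction
$100(1 - e^{\beta x})$ at intrusion level $x$ (`percent_reduction()`).
`density_intrusion_correlation()` checks that the density proxy and the
intrusion proportion are themselves only weakly correlated, which justifies
the two-step residual regression.

The egg-based variant (`ova_productivity()`) converts each census group to
potential egg deposition through a log-log length–fecundity model before
forming the same ratio. The underlying fecundity relationship is
population-specific and unpublished in general, so the function *refuses to
run without explicit coefficients*; `fecundity_model()` carries them plus
the captive-to-wild egg multiplier (default 1.4 — captive-bred females
carry more, smaller eggs per body mass).

## What the generator emulates — and what it does not

`simulate_pedigree()` draws, per cohort, wild and captive potential
spawners (annual totals Poisson-distributed around the configured sizes),
gives each a true offspring count from a hurdle model — zero with
provenance-specific probability, otherwise a shifted negative binomial —
and scales the captive positive-part mean so the ratio of provenance means
equals `true_rrs` exactly at the generating level. Offspring become wild
recruits returning 4 or 5 years later (90% grilse by default). Parents and
offspring are thinned by their sampling fractions, links of sampled
offspring to unsampled parents are lost, and a fraction $\epsilon$ of the
surviving links is reassigned to a uniformly random other sampled parent of
the cohort (provenance-blind by default; within- and between-provenance
misassignment are switches). For a configurable fraction of assigned
offspring the mate is also recovered; mates are drawn size-biased by their
own true offspring count, which preserves the provenance mean ratio in
expectation. All randomness flows from one root seed through fixed
per-stage substreams, so output is byte-reproducible.

Default study conditions: six cohorts of 400 wild and 120 captive spawners,
`true_rrs = 0.36`, zero probabilities 0.55 (wild) and 0.75 (captive),
positive-part mean 2.4 with dispersion 1.5, 90% sampling of parents and
offspring, $\epsilon = 0.02$, 21% two-parent recovery, 90% grilse and a
balanced sex ratio. The hurdle family mirrors the analysis's own separation
of zero and positive LRS; the dispersion and zero probabilities are
realistic free choices, not calibrated claims, since LRS variance tables
are not part of the package's inputs.

`simulate_productivity_series()` draws a stationary AR(1) spawner series
(mean 600, marginal SD 250, lag-1 correlation 0.5; non-positive draws are
resampled with an abort bound), uniform intrusion proportions on
[0.01, 0.59], and
$\log P_t = \log a - \log(1 + S_t/b) + \beta\,p_t + e_t$ with a
Beverton–Holt-shaped density term ($a = 3$, $b = 500$) and Gaussian noise
(SD 0.25). The Beverton–Holt form lives *only* in the generator — the
analysis deliberately avoids fitting any named stock–recruit function.

Not emulated: genotypes and marker-level parentage inference, mature male
parr (precocious males never trapped; both provenances are affected alike),
within-river spatial structure, age-structured maternal effects, and any
correlation between a parent's LRS and its offspring's LRS (so simulated
grand-offspring analyses are null by construction). Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
sampling and error model, not fidelity of any particular river system.

## Numerical and testing choices

* Permutation p-values in package tests use $10^3$–$10^5$ permutations and
  the test-suite recovery runs use 20 replicate seeds with 5,000 spawners
  per provenance (RRS) and 200-year series (intrusion slope); these sizes
  put the Monte-Carlo error of replicate means well inside the tolerances
  asserted, while a production run would use the `n_perm = 10^6` default of
  the command-line wrapper.
* Null calibration of the one-tailed permutation test is checked on 1,000
  replicate null pedigrees (120 spawners each, 999 permutations, weak
  rule); the weak rule's slight conservatism under discrete ties is visible
  but small at that size.
* The GAM linear-nesting property (a spline must reproduce an exactly
  linear series to numerical precision) and the closed-form identities
  $p = P(F_{1,n-2} > F)$, $R^2 = F/(F + n - 2)$ are asserted on every
  fitted `intrusion_regression`.
* `correlation_significance()` and `regression_significance()` recover
  $t$, $p$ and adjusted $R^2$ from printed summary statistics — useful when
  only a published correlation or F ratio is available for cross-checking.

## Known limitations

* Cohort attribution of repeat or delayed spawners uses an explicit
  override table with weights; the method itself does not dictate how a
  multi-cohort fish's LRS should be split, and the override mechanism
  records a choice without claiming fidelity to any one population's
  bookkeeping.
* The $\epsilon$ correction assumes one scalar, provenance-blind error
  rate. Per-provenance error is not modelled (the pedigree supplies a
  single rate); the `error_direction` switch in the generator exists to
  probe sensitivity.
* Sex-specific runs reuse the pedigree-level $S$ and $A$ with sex-specific
  parent counts; fish of unknown sex are excluded from sex-specific runs
  only.
* The productivity analysis requires complete $t+4$/$t+5$ recruit coverage
  and makes no attempt at partial-cohort edge handling or marine-survival
  decomposition.
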