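# salmonrrs

Pedigree-based fitness and productivity analysis for salmon populations
supplemented with captive-bred fish.

When hatchery-reared (captive-bred) Atlantic salmon escape or are released
and spawn alongside wild-bred fish, two questions matter to managers and
evolutionary ecologists:

1. **Do captive-bred spawners leave fewer adult offspring?** Fitness is
   lifetime reproductive success (LRS) — the number of adult offspring
   genetically assigned to a parent in a molecular pedigree built from a
   total trapping census. The headline statistic is relative reproductive
   success (RRS): mean LRS of captive-bred fish divided by that of
   wild-bred fish (wild ≡ 1), per spawning cohort and overall.
2. **Does hatchery intrusion depress population productivity?** Annual
   productivity is adult-to-adult: recruits (wild grilse returning at
   *t* + 4 plus wild multi-sea-winter fish at *t* + 5) per potential
   spawner in year *t*, density-corrected by a penalized-spline fit and
   regressed on the annual proportion of captive-bred spawners.

## What the package computes

* **Bias-corrected mean LRS** per cohort and provenance,
  `raw_mean − ((S − A)/N)·(ε/(1 − ε))`, where `S` offspring were sampled,
  `A` assigned, `N` potential parents, and `ε` is the pedigree
  assignment-error rate (`unbiased_mean_lrs`, `cohort_fitness`).
* **One-tailed permutation tests** of the provenance difference in mean
  LRS per cohort, combined across cohorts by **Fisher's method**
  (`permutation_test`, `fisher_combined`), with a conservative substitution
  policy for zero p-values.
* **Overall RRS** as a weighted geometric mean of cohort estimates, the
  **zero-LRS proportion test**, the **zero-excluded RRS**, and the percent
  **reduction in mean LRS of the mixed population**
  (`overall_rrs`, `zero_lrs_proportion_test`, `zero_excluded_rrs`,
  `mixed_population_reduction`).
* **Density-corrected productivity**: recruits-per-spawner series
  (`recruits_per_spawner`, egg-based variant `ova_productivity`), a
  nine-knot penalized cubic regression spline of log productivity on
  spawner numbers (`fit_density_gam`, via mgcv), OLS of the residuals on
  the captive-bred proportion (`intrusion_regression`), and the
  back-transformed percent reduction `100·(1 − exp(β·x))`
  (`percent_reduction`).
* **Synthetic data with known truth**: hurdle-model offspring counts,
  incomplete sampling, parentage-assignment error and two-parent recovery
  (`simulate_pedigree`); density-dependent productivity with a
  multiplicative intrusion effect (`simulate_productivity_series`).

## Worked example

Simulate a six-cohort pedigree whose generating captive:wild fitness ratio
is 0.36, then run the full RRS analysis:

```r
library(salmonrrs)

sim <- simulate_pedigree(simulation_config(seed = 11))
res <- run_pipeline(sim$fish, sim$parentage, sim$census,
                    n_perm = 10000, knots = 4, seed = 1)
res
#> Cohort fitness table (both, epsilon = 0.02, weak tie rule)
#>   cohort n_captive n_wild raw_mean_captive raw_mean_wild ... rrs    perm_p
#> 1   1977       102    361           0.2941         1.224 ... 0.2356 9.999e-05
#> 2   1978       114    356           0.4912         1.242 ... 0.3911 9.999e-05
#> 3   1979       108    330           0.4630         1.288 ... 0.3560 9.999e-05
#> 4   1980       111    357           0.5135         1.174 ... 0.4339 9.999e-05
#> 5   1981        99    375           0.3030         1.184 ... 0.2520 9.999e-05
#> 6   1982       117    344           0.5812         1.331 ... 0.4318 9.999e-05
#>
#> Overall RRS (weighted geometric mean, total weights): 0.340
#> Fisher's combined probability test: X2 = 110.53, d.f. = 12, p = 4.71e-18
#> Mixed-population mean-LRS reduction: 15.2%
#> Zero-excluded RRS: 0.634 (p = 0.0001)
```

Reading the output: in every cohort the captive-bred mean LRS is far below
the wild-bred mean; the overall weighted geometric mean RRS of 0.340 is
close to the generating ratio 0.36 (single-realization sampling noise);
the combined chi-squared on 12 degrees of freedom (2 × 6 cohorts) is
overwhelming; intrusions of captive-bred fish reduced the mixed
population's mean LRS by about 15% relative to an all-wild population; and
the deficit persists (RRS 0.634) among fish that left at least one
offspring, so it is not explained by spawning failure alone.

The productivity leg, on a 43-year simulated series whose true intrusion
effect is −0.686 on the log scale:

```r
prod <- simulate_productivity_series(n_years = 43, beta_true = -0.686,
                                     seed = 11)
g <- fit_density_gam(prod$series, k = 9)
reg <- intrusion_regression(g)
reg
#> Intrusion regression: slope = -0.467, adj. R2 = 0.08, F(1, 41) = 4.75, p = 0.0351
percent_reduction(reg$slope, mean(prod$series$prop_captive))
#> [1] 12.33737
```

A single 43-year series estimates the slope noisily (the test suite's
recovery check averages 20 replicates); the back-transformed figure says
productivity at the mean intrusion level is ~12% below a pure wild
population's.

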