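# kinabund

Kin-based abundance estimation for harvested mammal populations.

Estimating how many animals live in a hunted population is a core problem of
wildlife management, and for game species it is hard: marked animals cannot
be released back into a hunting bag. Close-kin methods sidestep physical
recapture by treating relatives found in a genetic sample as "recaptures" —
an offspring's genotype marks its parents. They were developed for fish
stocks with discrete generations, but terrestrial game species such as red
deer (*Cervus elaphus*) and wild boar (*Sus scrofa*) have **overlapping
generations**: a sampled animal can be somebody's parent and somebody's
offspring at the same time, which breaks the assumptions those estimators
were built on.

`kinabund` provides the machinery to study exactly how much that matters:

* an **individual-based annual-cycle pedigree simulator** for iteroparous
  mammals (mating, Normal litter sizes, multiple paternity, newborn /
  yearling / density-dependent adult mortality, senescence, a carrying-
  capacity ceiling), with calibrated red deer and wild boar presets;
* **perfect-pedigree sampling**: uniform draws of the standing population
  and exhaustive parent–offspring pair (POP) detection;
* four **POP-based census-size estimators**;
* an **evaluation harness** that runs replicated simulation × resampling
  grids over fecundity, fecundity variance and sampling intensity, and
  summarises relative bias (N̂/N) and precision (CV%).

## The estimators

With a sample of size *n* containing *n*<sub>juv</sub> juveniles,
*n*<sub>adult</sub> adults (*n*<sub>adult,f</sub> female,
*n*<sub>adult,m</sub> male), *n*<sub>f</sub> females, and observed pair
counts *h* (all POPs), *h*<sub>mother</sub>, *h*<sub>father</sub>
(mother-/father-side POPs) and *k*<sub>md</sub> (mother–daughter pairs):

| method | estimate | target |
|---|---|---|
| CKMR (naive close-kin mark-recapture) | N̂ = 2 · *n*<sub>juv</sub> · *n*<sub>adult</sub> / *h* | adults |
| g-CMR (genetic CMR, per-sex Lincoln–Petersen) | N̂ = (*n* · *n*<sub>adult,f</sub>/*h*<sub>mother</sub> + *n* · *n*<sub>adult,m</sub>/*h*<sub>father</sub>) · *n*/*n*<sub>adult</sub> | total |
| Moment | N̂ = *n*<sub>f</sub>(*n*<sub>f</sub> − 1)/*k*<sub>md</sub> | breeding females |
| CRE (Creel–Rosenblatt) | N̂ = B<sub>s</sub> + B<sub>u</sub> (sampled breeders + inferred unsampled mates) | adults |

Because generations overlap, POPs *among adults* are counted alongside
adult–juvenile pairs. Degenerate samples (no POPs) are flagged undefined
rather than raising errors, so failure rates can be reported per scenario.

## Worked example

```r
library(kinabund)

params <- species_params("wild_boar")
ped <- simulate_pedigree(params, n_years = 200, seed = 42)
truth_sizes(ped)
#>   n_total n_adult n_breeding_females
#> 1     498     185                127

s <- draw_sample(ped, fraction = 0.3, seed = 7)     # 149 animals sampled
relative_bias(estimate_all(s, ped), truth_sizes(ped))
#>   method           target n_hat defined h_total n_true  bias
#> 1   CKMR            adult   252    TRUE      40    185 1.363
#> 2   gCMR            total  1219    TRUE      40    498 2.447
#> 3 Moment breeding_females   594    TRUE      40    127 4.679
#> 4    CRE            adult    55    TRUE      40    185 0.297
```

This simulated boar population holds 498 animals, 185 of them mature. The
30% sample contains 40 verified parent–offspring pairs; from these, naive
CKMR estimates 252 adults (relative bias 1.36, a 36% overestimate of the
185 true adults), while CRE detects 55 breeders (bias 0.30, a deep
underestimate at this sampling intensity — CRE is reliable only with ~50%+
coverage). Repeating the sampling 100 times separates bias from noise:

```r
recs <- resample_population(ped, 0.3, n_resamples = 100, seed = 7)
recs$population <- 1L
summarize_bias(recs)
#>   method mean_bias sd_bias cv_pct n_undefined mean_pops
#> 1   CKMR     1.637  0.3040   18.6           0      35.1
#> 2    CRE     0.271  0.0397   14.7           0      35.1
#> 3 Moment     6.480  4.3522   67.2           0      35.1
#> 4   gCMR     2.944  0.6720   22.8           0      35.1
```

`cv_pct` is the coefficient of variation of N̂/N across resamples — the
precision metric against the usual 20% management-utility threshold.
Experiment grids (`run_species_comparison()`, `run_fecundity_sweep()`,
`run_sd_sweep()`) return a `kin_experiment` with `tidy()`/`glance()`
methods and `autoplot()` figures; `bin_by_pops()` conditions the summaries
on the observed number of POPs.

A thin command-line interface (`inst/cli/kinabund`, or
`kinabund::cli_main()`) exposes `simulate`, `estimate`, `experiment` and
`summarize` subcommands over pedigree TSV / config YAML files, writing a
JSON manifest alongside every output for exact re-execution.

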