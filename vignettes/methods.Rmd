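---
title: "Simulating close-kin abundance estimation in harvested mammals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating close-kin abundance estimation in harvested mammals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`kinabund` asks a sharply posed question: if we could reconstruct a perfect
pedigree from genetic samples of a hunted ungulate population, how well
would parent–offspring-pair (POP) estimators recover its census size? This
vignette documents the demographic model, the estimators, the evaluation
design, and — most importantly — the choices we made where the design was
genuinely open, so results can be interpreted (and challenged) precisely.

## The demographic model

The simulator is individual-based with an annual cycle and overlapping
generations. A population starts as `carrying_capacity` founders with ages
uniform on 1…`max_lifespan` and independent Bernoulli(`sex_ratio`) sexes.
Each year, in fixed order:

1. **Mating and births.** Every female at or above `female_maturity` breeds
   if at least one male at or above `male_maturity` is alive. Litter size is
   a Normal(`fecundity_mean`, `fecundity_sd`) draw rounded to the nearest
   integer and truncated at zero. Each female's litter is sired by one
   uniform-random mature male; a `multi_mate_fraction` share of females
   instead draw a Poisson(`partner_lambda`) partner count, truncated below
   at 2 so that "multiply mating" females have at least two partners, and
   each of their offspring picks its sire uniformly from the partner set
   (within-litter multiple paternity). Males are unlimited in matings
   (polygyny); there is no mate-choice, dominance or spatial structure.
2. **Newborn mortality** (`newborn_mortality`, Bernoulli per age-0 animal).
3. **Yearling mortality** (`yearling_mortality`, per age-1 animal).
4. **Density-dependent adult mortality and ceiling regulation** (below).
5. **Senescence** at `max_lifespan`.

Ages are implicit (year − birth year), so survivors age as the calendar
advances. Founders carry no parent links and therefore can never appear in
a POP.

### Density dependence: a design decision

The literature gives point mortality rates for juveniles but describes
adult mortality only as density-dependent with a long-run average (0.315
red deer, 0.360 wild boar — stored as `adult_mortality_ref`). The mechanism
matters more than it may seem. A pure ceiling that removes the annual
excess above `carrying_capacity` from adults first is untenable for a
high-fecundity species: the wild boar's juvenile surplus exceeds its entire
adult pool, so adults-first removal extirpates every adult each year, males
never reach maturity (3 years), and the population boom-busts. We therefore
use a two-part mechanism:

* adults (age ≥ 2) die at rate `adult_mortality_ref · (N/K)³`, with `N` the
  standing population at the start of the year — a steep density response
  that keeps the equilibrium near `K` while realized adult mortality
  averages near the reference rate;
* any residual excess above `K` is then removed from newborns first, then
  yearlings, then adults: beyond the adult rate, density dependence falls
  on recruitment, as it typically does in ungulates.

This satisfies every structural requirement at once: populations are stable
and never exceed `K` for any fecundity in the 1–14 sweep, the wild boar
persists with a realistic age structure, and the realized adult mortality
(computed by `realized_adult_mortality()` and checked by the test suite over
the final 100 years of replicate runs) sits within ±0.1 of the reference
rates for both presets. The red deer equilibrates slightly below `K`
(~450–475 of 500): with one calf per hind per year its demographic surplus
cannot sustain the reference adult mortality at `N = K`, so the density
response relaxes until births balance deaths. We consider this a feature of
the calibration, not a defect — the alternative (pinning `N` at `K`)
necessarily drives adult mortality away from the literature rates.

### Preset parameters

| field | red deer | wild boar | units |
|---|---|---|---|
| `max_lifespan` | 15 | 12 | years |
| `female_maturity` / `male_maturity` | 2 / 5 | 1 / 3 | years |
| `fecundity_mean` ± `fecundity_sd` | 1 ± 0 | 4.9 ± 2.1 | offspring/female/yr |
| `newborn_mortality` / `yearling_mortality` | 0.2 / 0.335 | 0.539 / 0.585 | probability |
| `adult_mortality_ref` | 0.315 | 0.360 | probability |
| `multi_mate_fraction` (`partner_lambda`) | 0 | 0.44 (2) | — |
| `carrying_capacity` | 500 | 500 | individuals |
| `sex_ratio` | 0.5 | 0.5 | P(female) |

All fields can be overridden individually (`species_params("red_deer",
fecundity_mean = 7)`), which is how the fecundity sweeps are built.

## Sampling and kin counting

`draw_sample()` draws uniformly, without replacement, from the individuals
**alive at the final year** — the full standing population across all
coexisting cohorts, with sample size `round(q · N)` clamped to ≥ 2. POP
detection assumes perfect pedigree reconstruction: `find_pops()` returns
every directed (parent, offspring) pair with both members sampled, tagged
by parent sex and by class (adult–adult when the offspring has itself
reached maturity). Juvenile/adult classification uses the sex-specific
maturity ages, so a 4-year-old red deer stag counts as a non-adult.
Mother–daughter pairs (`k_md`) count daughters of any age, and each
directed parent–offspring link is counted exactly once.

Two modelling assumptions deserve emphasis:

* **Only living animals are sampled.** Real hunting bags consist of dead
  animals, and tissue collections accumulate over years; a sampling frame
  that includes recently harvested (dead) parents contains many more POPs
  than the standing population alone, because a living animal's parents
  are often already dead in a stationary population. Bias levels under
  bag-style sampling can therefore differ substantially (toward smaller
  estimates) from the standing-population sampling modelled here. The
  stationarity arithmetic is unforgiving: in a stable capped population
  the adult death rate is pinned by recruitment, so no choice of
  regulation mechanism can make most parents of the living be alive.
* **Sampling is uniform.** No sex-, age- or spatially-biased harvest; the
  estimators' behaviour under biased bags is outside this package's scope.

## The four estimators

The estimator surface consumes the sufficient statistics in `kin_counts()`
(CKMR, g-CMR, Moment) or the sampled pedigree itself (CRE); each formula is
isolated behind its own function so variants (e.g. a Chapman correction)
can be swapped without touching the harness. No small-sample correction is
applied; degenerate samples (zero POPs, no juveniles, fewer than two
females) return `defined = FALSE` and are reported as failure rates rather
than dropped silently or raised as errors. Because generations overlap,
adult–adult POPs are included in every pair count.

The test suite validates each estimator against independent generative
oracles in which its assumptions hold exactly: two-generation populations
for CKMR and CRE (all POPs adult–juvenile), closed-parentage populations
for g-CMR (every individual's parents are alive candidates), and closed
female populations for the Moment estimator (every ordered pair of females
is a mother–daughter pair with probability 1/(N<sub>F</sub> − 1)). At
census sampling the estimators are exact in these designs; under partial
sampling their means lie within three Monte-Carlo standard errors of the
truth over 500 replicates.

## Evaluation design

`relative_bias()` divides each estimate by the true size of its own target
class — adults for CKMR and CRE, the total for g-CMR, breeding females for
the Moment estimator — all counted among the living at the final year.
Precision is the coefficient of variation of N̂/N across the resamples of
one population (SD/mean × 100), averaged (± SD) across replicate
populations; a pooled-CV alternative is available via
`summarize_bias(pooled_cv = TRUE)`. Undefined estimates are excluded from
means and reported as `n_undefined`; the accounting per cell always
reconciles to populations × resamples.

Every quantity is a pure function of a `scenario_config()`: one root seed
is split into deterministic child streams (`child_seed()`) for
initialisation, every simulated year, and every resample, so experiment
tables are bit-reproducible and populations are reused across sampling
fractions without leaking randomness between stages.

**Problem sizes.** The package defaults to a reduced desk scale of 30
populations × 30 resamples of 200-year, K = 500 populations; the test suite
uses 30 × 30 for the species comparison, a 5 × 5 fecundity × sampling grid
at 20 × 30, and 10-seed banks for calibration checks. These scales hold the
Monte-Carlo standard error of a mean bias to a few percent; the full
100 × 100 scale is a configuration choice, not a code path.

**Numerical details worth knowing.** Litter sizes use R's round-half-even;
partner counts are capped at the number of living mature males; sample
sizes are rounded to the nearest integer with a floor of 2; the Moment
estimator is undefined rather than infinite at `k_md = 0`; fecundity-SD
insensitivity is asserted as a ≤ 25% relative spread of mean bias across
SD ∈ {0, 2, 4} within each method × intensity cell, which is the resolution
the reduced scale supports.

## What the generator does and does not emulate

It emulates: overlapping generations with realistic age structure,
iteroparity, polygyny and (for boar) multiple paternity, density-dependent
population regulation calibrated to literature adult-mortality rates, and
harvest-like proportional sampling of 10–90% of the population.

It does not emulate: genotyping or pedigree-reconstruction error (perfect
kin assignment is assumed throughout), dead-animal sampling frames,
sex-/age-/trophy-biased harvest, spatial structure or dispersal,
environmental stochasticity, or year-to-year correlation in individual
breeding success beyond what the annual lottery induces. Passing tests
therefore demonstrate internal correctness of the estimators and simulator
and the direction of structural biases under ideal sampling of the living
— not field performance, which the limitations above will generally make
worse (kin-detection error) or different (bag composition).

## Known limitations

* CKMR, g-CMR and Moment estimates are strongly sensitive to how many
  parents of sampled animals are themselves sampleable; under the
  standing-population frame used here they overestimate in stationary
  populations because many parents are dead (few "recaptures"), while CRE
  — which counts detected breeders rather than scaling by recaptures —
  underestimates at low coverage. Comparisons with studies that sample
  accumulated hunting bags should account for the frame difference.
* The density-dependence mechanism, though calibrated, is one of several
  defensible choices; estimator bias levels (not the qualitative CRE
  coverage-dependence) shift with the resulting age structure.
* CV summaries at 10% sampling rest on small POP counts and are themselves
  noisy; the reduced grid reports them per population before averaging for
  exactly this reason.
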