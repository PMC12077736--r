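---
title: "An annual stage- and age-structured life cycle model for anadromous lampreys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An annual stage- and age-structured life cycle model for anadromous lampreys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lampresim)
```

## The model

`lampresim` simulates an anadromous lamprey population on an annual time
step through six serial life stages: spawning adults, eggs, freshwater
larvae (ammocoetes, ages 0--10), transformers (macrophthalmia), ocean
juveniles (ocean ages 0--10) and in-river adults (river ages 0--2).
Lampreys are semelparous: spawners are removed after reproducing. Each year
the stages advance in a fixed within-year order:

1. **Spawning.** Each in-river adult age class spawns with probability
   $\eta_a$ ($\eta_2 = 1$ is structural: nobody holds more than two years).
   Non-spawners hold in the river with no mortality (the model has no
   holding-mortality parameter). The egg-producing spawner pool is the
   female subset of the spawning adults, drawn binomially with the female
   sex ratio; this pool is also the spawner abundance the package reports.
2. **Egg production.** Individual fecundity is negative binomial with mean
   $\lambda$ and shape $k = \lambda^2 / (\sigma^2 - \lambda)$
   (moment matching). The total over $n$ females is drawn in one step as
   $\mathrm{NB}(nk, n\lambda)$, exactly the distribution of the
   per-individual sum.
3. **Egg survival.** Beverton--Holt density dependence,
   $\pi = 1 / (1/S_{egg} + n_{egg}/K_{egg})$, followed by a binomial draw.
4. **Hatchery additions.** Released age-1 to age-10 larvae and transformers
   join the population before density dependence and before downstream
   passage, with no survival penalty.
5. **Larval density dependence.** All age-1+ larvae are pooled and passed
   through sequential summer and winter Beverton--Holt survivals (each with
   optional extra mortality and its own capacity). The realized fraction
   $\pi_{dd}$ then multiplies each age's density-independent survival
   $\pi_{di,l}$. Age-0 larvae experience $\pi_{di,0}$ only.
6. **Transformation.** Surviving larvae of ages 2--10 transform with
   age-specific probability $\delta_l$; non-transformers advance one age by
   *subtraction*, so transformed + advanced = survived exactly, draw by
   draw. $\delta_{10} = 1$ is enforced: there is no age-11 larval class.
7. **Downstream migration.** Transformers pass the product of per-barrier
   downstream passabilities; a requested number (capped at availability) is
   translocated below all barriers with a translocation survival instead.
8. **Ocean entry.** One beta-distributed survival per year, shared by the
   whole cohort, then a binomial draw.
9. **Ocean residence.** One river-entry and one yearly-ocean survival are
   drawn per year. Each ocean age class attempts upstream return with
   $\zeta_j \cdot \pi_{entry.river}$; only successful returners leave the
   sea pool, so fish that attempted return and died at the river mouth
   remain in the pool for the ocean-survival draw (the literal reading of
   the transition equations; combined with $\zeta_6 = 1$ this lets a
   trickle of fish stay at sea beyond six ocean years). Age-10 juveniles
   are never advanced: those that do not return die.
10. **Upstream migration.** As downstream, with the upstream barrier list
    and adult translocation (capped at that year's available migrants).

### Stochastic and deterministic modes

Every transition goes through a single draw abstraction. In stochastic mode
counts are integers and the model has both demographic stochasticity
(binomial/negative-binomial draws) and environmental stochasticity (the
three yearly beta survival draws shared across individuals). In
deterministic mode every draw returns its exact expectation and counts are
propagated as real numbers with *no rounding*; rounding would perturb the
nearly constant stable states the deterministic map reaches and is
deliberately avoided. Deterministic trajectories match stochastic means
within Monte-Carlo error over short horizons (verified in the test suite at
3 SE); over long horizons the nonlinearity of the density dependence makes
the stochastic mean sit slightly below the deterministic path, which is
expected and not an error.

Reproducibility uses L'Ecuyer-CMRG streams: one stream per replicate, one
substream per (replicate, year). A replicate's trajectory therefore does
not depend on how many replicates are run or in what order, and the same
seed is bit-reproducible.

## Default parameterization

The defaults are a Pacific lamprey (*Entosphenus tridentatus*)
parameterization assembled from published estimates and expert judgment:
fecundity 127,000 +/- 33,500 eggs; sex ratio 0.5; egg survival 0.02 with
capacity 575 million eggs (575 eggs/m^2 over 1 km^2 of spawning habitat);
larval capacities 1.3 million (0.13 larvae/m^2 over 10 km^2); age-specific
larval survivals 0.33--0.8; transformation probabilities
(0, 0, 0.002, 0.042, 0.555, 1, ...); ocean entry survival 0.46 +/- 0.09;
upriver probabilities (0, 0.02, 0.05, 0.1, 0.15, 0.45, 1, ...); yearly
ocean survival 0.7 +/- 0.1; river entry survival 0.67 +/- 0.09; spawn
probabilities (0.05, 0.7, 1); translocation survival 0.99; default
single-barrier passabilities 0.9 downstream and 0.6 upstream (the latter
the mean of six printed per-dam passage extremes, see
`upstream_passage_default()`). `capacity_from_density()` converts an areal
density (per m^2) and a habitat area (km^2) to a capacity, applying the
1e6 m^2/km^2 factor exactly once; `compose_egg_survival()` rebuilds the
0.02 egg survival from its observable components (~0.018 before rounding).

Two readings of the printed defaults needed a decision. The egg capacity is
given in one place as 10 million and in another as 575 million; only the
latter is consistent with the stated density x area derivation, so 575
million is the default. And the spawner count: the egg total is summed over
the *female* spawner pool (spawning adults times the sex ratio), and the
package reports exactly that pool as "spawners". Under the defaults the
deterministic model settles at about 201 reported spawners (402 spawning
adults); the reported variable is the one consistent with the published
stable abundance of roughly 200.

## Dynamics under the defaults

From an arbitrary start the deterministic map approaches a fixed point
through a damped oscillation with a roughly 7-year period (the generation
time). The amplitude is a few percent of the equilibrium just after a
50-year burn-in and below one part in $10^6$ per year after about 160
years. Consequently, "the population forgets its initialization after a
50-year burn-in" holds in the stationary sense: trajectories started from
200--3,200 initial spawners agree to well under 1% in the final decade of a
100-year run, while in the first years after burn-in a residual transient
of a few percent remains. Tests and the acceptance checks therefore measure
initialization-independence on the stationary regime.

One behaviour worth knowing: raising egg or larval survival does *not*
necessarily raise the equilibrium spawner count. Larger young cohorts
depress the pooled density-dependent survival shared with the older,
nearly-transformed ages, and the net equilibrium effect can be slightly
negative. This compensation is built into the pooled Beverton--Holt step
and is a genuine property of the model, not an artifact. Barrier additions
always lower the equilibrium, and survivals outside the density-compensated
freshwater phase (ocean entry, yearly ocean, river entry) always raise it.

## Management scenarios

`scenario_presets()` encodes the five case-study scenarios: baseline; one
upstream barrier with passability 0.6; the barrier plus yearly
translocation of up to 100 adults (survival 0.99); the barrier plus yearly
hatchery release of 1,000 transformers; and the barrier plus both. With 100
stochastic replicates of 100-year runs, the barrier roughly halves the
spawner median, each single remedy recovers part of the deficit, and the
combination approaches (though in our runs does not fully reach) the
baseline; the package asserts this ordering, with the combined scenario
within 25% of baseline, rather than exact equality, since the remedies
offset most but not all of the barrier's deficit in replicate medians.

## Global sensitivity analysis

Two 44-parameter Latin hypercube designs (100 points, one draw per
equal-probability stratum per column, via the `lhs` package) drive
deterministic 100-year runs (50 burn-in); the response is the spawner count
in the last year. The *broad* design samples every probability uniformly on
(0, 1), fecundity normally (127,000 +/- 33,500), and capacities uniformly
(eggs: 1e5--1e12; larvae: 1e4--1e8). The *restricted* design replaces the
uniform probabilities with moment-matched betas centred on the defaults
(means too close to the support edges replaced by 0.05/0.9; sd 0.1, sex
ratio 0.05, egg survival 0.04). The 44 varied columns include the
transformation probabilities for ages 0, 1 and 10 and are counted even
though the model never lets ages 0--1 transform and forces age 10 to
transform: inert columns are part of the design, and their importance is
correctly estimated as noise around zero.

Importance is the out-of-bag permutation importance of a
`randomForest` regression (the %IncMSE convention: per-tree OOB MSE
increase after permuting a column, averaged over trees, normalized by the
SD of the per-tree differences), repeated over 100 forests of 501 trees
with 8 candidate variables per split, and aggregated into a mean and a
1.96 x SE confidence interval. Two caveats the tests encode:

* Repeated forests on *one* dataset converge to that dataset's
  idiosyncratic importances, so a "pure noise centres on zero" check is
  only valid across independently regenerated datasets; the suite tests it
  that way.
* With a single 100-point design, the set of parameters whose mean
  importance is positive fluctuates across design seeds. The *count* of
  positive-importance parameters is stable at roughly 15--20 of 44
  (matching the published 17 within its stated +/- 3), and the strongest
  signals are robust (egg survival and yearly ocean survival dominate the
  restricted design in our runs), but sign statements about weak
  predictors -- fecundity in particular, whose variation is only +/- 26%
  against responses spanning many orders of magnitude -- are chance-level
  across design realizations. The acceptance suite states this check
  faithfully and we report it as not reproducible rather than tuning
  toward it.

## Problem sizes and numerical choices

The shipped study sizes are the published ones: 100 replicates x (50 + 50)
years for the stochastic analyses, 100-point designs with 100 forests of
501 trees for the sensitivity analyses; the whole acceptance computation
runs in well under a minute on one CPU. Degenerate inputs are defined
explicitly: an empty age-1+ larval pool gives $\pi_{dd} = 1$ (nothing to
kill, avoids 0/0); zero females produce zero eggs; extinction is absorbing.
Translocation requests are clamped to each year's availability for both
life stages. Binomial draws fall back to a clipped normal approximation
only beyond $2^{31} - 1$ individuals (unreachable except under extreme
user-set capacities). Moment matching is validated at construction:
negative binomials require $\sigma^2 > \mu$, betas
$\sigma^2 < \mu(1 - \mu)$, with errors naming the offending field.

## What the generator does and does not emulate

Synthetic populations from `run_simulation()` reproduce the stage
structure, density dependence, demographic and environmental
stochasticity, and management operators described above. They do not
represent growth or body size (so fecundity is size-independent),
temperature- or density-dependent sex ratios, meta-population exchange
between streams, or within-year detail beyond the two-season density
dependence. Passing tests therefore validate the simulator's internal
consistency and its agreement with the published default behaviour -- not
the fidelity of any particular real stream, for which users must supply
their own parameter estimates.

## A minimal session

```{r example, eval = FALSE}
params <- lamprey_params()
sim <- run_simulation(params, sim_config(years = 50, burn_in = 50,
                                         replicates = 100, seed = 1))
summarize_replicates(sim, "spawners", "median")

cmp <- run_scenarios(params, scenario_presets(), sim_config(seed = 1))
cmp$final_medians

design <- latin_hypercube_design(gsa_presets()$restricted, 100, seed = 1)
y <- run_gsa(design, params)
head(random_forest_importance(design$matrix, y))
```
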