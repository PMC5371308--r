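---
title: "A bioenergetic individual-based model of a marine central place forager"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bioenergetic individual-based model of a marine central place forager}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpforage)
```

## The system being modelled

A lactating otariid female (the parameterisation follows the Antarctic fur
seal at the Kerguelen archipelago) rears a single pup over a 120-day season.
She is a central place forager: she alternates multi-day foraging trips at
sea, where she feeds on vertically migrating mesopelagic fish, with one- to
three-day visits to the colony, where she fasts and suckles the pup. Prey
are only reachable at night (8 h of a 24-h cycle), when they rise towards
the surface. The simulation asks how breeding success responds to the
abundance, spatial aggregation, and distance of the prey field, to the
female's body length, and to her ability to memorise feeding locations.

One simulation covers three phases:

1. a 15-day prospecting pass around the island, during which the female
   explores and memorises the location of rich cells;
2. birth, followed by a 5- to 7-day perinatal fast ashore during which the
   pup gains 1.5 kg;
3. the 2880-hour rearing period proper, an hourly loop of movement,
   fishing, provisioning and mortality.

The prospecting pass is treated as behavioural initialisation: it seeds the
female's spatial memory, while her energy clock starts from the measured
initial condition (the length-mass regression was estimated on females
weighed just before departure) at the beginning of the rearing period, and
survival is accounted from that point. A consequence of this reading is
that females cannot die before birth; mortality begins with the rearing
loop.

## The resource landscape

The environment is a static 100 x 100 grid of 10 km cells with the island
at its centre. Maps are realisations of a stationary Gaussian random field
(white noise smoothed by a Gaussian kernel; the kernel scale grows with the
aggregation level), truncated at zero, squared, masked, and normalised:

* cells on the 50-km shelf around the island and cells beyond the 500-km
  range limit hold no prey;
* between the shelf edge and the distance to the resource `Dist`, cells are
  retained with probability rising linearly from 0 to 1 (Bernoulli
  thinning), so `Dist` is the inner limit of the richest zone;
* beyond `Dist` the field amplitude tapers linearly (by `ring_taper`)
  towards the range limit, concentrating the best feeding grounds in a ring
  just outside `Dist`, which is where simulated fishing effort accumulates;
* surviving cells are rescaled so that their mean abundance equals the
  configured level (90, 180, 270 or 360 g of catchable prey per fishing
  hour; 1 map unit = 36.67 g h^-1).

Squaring the truncated field is a deliberate choice: it leaves roughly half
of the in-range cells empty while concentrating abundance into patch cores
several times richer than the average non-zero environment. A thinner tail
makes the bioenergetics of the foragers infeasible (see below), and the
resulting patch geometry still reproduces the published patch census.

Aggregation is expressed through two coupled knobs, a smoothing scale and a
truncation offset, both linear in the aggregation level. They were
calibrated once against the two printed anchors -- more than 500 patches of
about 1.5 cells at level 0, about 10 patches of about 67.4 cells at level
10 -- and then frozen. A "patch" is operationally a 4-connected component
of cells at least 1.5 x the mean non-zero abundance; the published source
does not define the term, and with this family of fields a threshold tied
to the mean separates patch cores cleanly from the background.

## Energetics

All state is carried as energy (MJ); mass is energy divided by the tissue
energy content (10.59 MJ kg^-1 for the female, 8.24 for the pup).

* **Metabolism.** 6.09 W kg^-1 at sea (0.0219 MJ kg^-1 h^-1); ashore a
  resting fraction (0.3) of that. The ashore fraction is not published and
  is absorbed by the milk-rate calibration.
* **Drag.** Horizontal displacement costs 0.041 MJ km^-1 for an 85-cm
  female, scaling with the squared length ratio (cross-sectional area of a
  streamlined body), which places a 145-cm female at 0.119 MJ km^-1,
  matching the published endpoint. Costs accrue per km actually travelled;
  fishing hours involve no horizontal displacement.
* **Intake.** A fishing hour yields the cell abundance converted at
  36.67 g per map unit and 4 kcal g^-1. A single feeding cannot exceed 7%
  of the energy held at the end of the former night, and body energy can
  never exceed the storage ceiling `E_max` = 1.07 x the initial mass-energy.
  We read the ceiling as a fixed physiological storage capacity: if it is
  instead re-anchored each dawn to current mass, daily net gain is capped at
  7% of current energy, which is below the daily cost of being at sea for
  any female in the modelled size range -- no population can then persist,
  and the published final masses (1.065 x the initial mass for the
  reference female) are exactly what a fixed ceiling produces. Likewise the
  satiation cap is applied per feeding (as the parameter table states), not
  summed per night, because a nightly 7% cap is arithmetically incompatible
  with the published trip statistics.
* **Pup.** A fasting pup loses 0.12% of its energy per hour (2.8% per
  day). While the female is ashore the pup suckles: each shore hour
  transfers `milk_rate` x the female's surplus above her lethal floor, with
  the pup capped at 18 kg. `milk_rate` is the model's single provisioning
  constant; it was calibrated once so that the reference condition weans
  pups near the published 11 kg, then frozen.

## Hourly behaviour at sea

Decisions requiring prey sensing happen at night. The movement modes are:

* **commuting** (departure without a usable memory): a nearly straight leg
  along a heading that rotates systematically between naive departures,
  ending at the first profitable night cell or at dawn;
* **transit** (with probability equal to the trip fidelity): straight
  towards the memorised reference cell, timed so arrival falls at night;
* **search**: a correlated random walk whose turning spread gives a lag-1
  heading autocorrelation of 0.302, pulled towards the richer of the last
  two visited cells (gradient taxis, weight 0.8);
* **homing**: straight back to the island, with opportunistic night
  fishing en route.

The probability of fishing a cell is logistic in abundance with slope 2,
centred on a condition-dependent threshold `th_t` that runs from the
profitability floor (1.5 map units) when the female is at her lethal energy
floor up to the mean non-zero abundance when she is satiated. The
interpolation is convex (`th_exponent` = 0.25), so females stay selective
for rich cells until reserves genuinely run low; a linear map lets females
park on barely profitable cells and starve slowly.

A trip ends when (i) the female is within 4% of her storage ceiling
(nothing more can be gained at sea), (ii) the nightly return decision
fires -- a probability combining a steep exponential in the energy margin
above what the journey home requires (her lethal floor, plus travel, plus
two shore days when a pup waits) and a duration ramp `(ts / T_max)^4` --
or (iii) the 7-day trip ceiling is reached. A provisioning female who has
caught nothing by dawn and knows of no feeding area aborts cheaply, and a
female whose reserves fall below 78% of her trip-start reference while
fasting ashore departs early rather than starving beside her pup.

Spatial memory has two layers. Within a trip, every female backtracks to
the best cell she has fished when the current ground is clearly poorer
(working memory). Across trips, a `Mem1` female remembers the reference
cell that maximises abundance net of the travel cost of reaching it
(0.036 map units per km); the published fishing maps show that, among
equally rich zones, the ones closer to the island are the ones exploited.
Trip fidelity saturates in the best gain rate achieved so far, so one
failed trip does not erase trust in a proven feeding area.

## Mortality

Each hour, each animal dies with probability given by a normal CDF of its
percentage of a reference energy, centred at 70% (females) and 56% (pups).
The published spread of 0.02 is ambiguous; we use 0.5 percentage points, a
sharp but smooth threshold between the step function the literal reading
implies and the much flatter 2-point alternative. The female's reference is
her initial energy; the pup's reference is its highest post-suckling
energy. A running maximum (rather than the literal "energy after the last
suckling") is required for pups to starve at all under failing
provisioning: with a reference that ratchets downward, a pup loses at most
a few percent of its reference between visits and can never reach the
lethal fraction, contradicting the published near-certain pup death under
low abundance.

Pair success is `SP = (1 - D_f)(1 - D_p)`, computed per replicate map and
reported from the across-map mortalities so that the identity stays exact.

## The experiment layer

`run_condition()` crosses map replicates with seal replicates under
deterministic sub-seeds (reproducible and order-independent);
`summarize_condition()` aggregates per map first, then across maps, with
behavioural statistics taken over females that completed the rearing
period. `design_grid()` enumerates the full factorial (8 aggregation x 4
abundance x 9 distance x 5 length x 2 memory = 2880 conditions; with 10
maps and 50 seals, 1,440,000 runs). The cost/benefit ratio is
`R = E / SP`, with `E` the mean total energy spent over the rearing period;
`bootstrap_optimum()` fits quadratic and cubic curves of `R` over body
length, takes the argmin of the better-fitting minimum, and bootstraps
run-level records (1000 resamples) for a 95% interval;
`optimal_length_regression()` fits the optimal-length-versus-distance line
whose slope, multiplied by the speed at which the feeding grounds shift,
predicts the body-length drift that would maintain the optimum.

Only the quadratic expression for `R(length)` is published; the cubic
companion is our choice of a smooth second candidate. The survivor filter
for behavioural statistics is "female alive at day 120"; pup masses are
averaged over surviving pups.

## Problem sizes

The test suite runs the reference condition at the published replication
(10 maps x 50 seals), the distance and aggregation sweeps at 5 maps x
15-20 seals per cell, the optimality analysis at 6 distances x 5 lengths x
40 runs, and the patch census at 50 maps per level. The acceptance script
uses 10 x 50 for the reference and distance conditions, 10 x 20 per
aggregation level, 150 runs per optimality cell and 100 maps per patch
census. With the compiled hourly loop a full simulation takes well under a
millisecond, so these sizes are a matter of statistical resolution, not
cost.

## What the generator does and does not emulate

The landscape generator reproduces controlled mean abundance, tunable
patchiness with the published patch census at both extremes, and the
radial accessibility structure around the colony. It does not emulate
bathymetry, anisotropy, temporal prey dynamics, depth structure, or
competition among foragers; maps are static and each female forages alone.
Passing tests therefore speak to the internal consistency of the
behavioural-energetic machinery on such landscapes, not to predictions for
any real colony.

## Known limitations

The published account fixes the physiological constants and the decision
contracts but not the return-probability surfaces, the suckling equation,
or the landscape covariance details, all of which live in unavailable
supplementary material. Those components are re-derived here from the
stated anchors. The resulting simulator reproduces the qualitative
structure of the published results -- pair success maximised at
intermediate aggregation, trip distance rising near-linearly with the
distance to the resource, fishing effort concentrated on the richest
accessible cells, memory mattering most under unfavourable conditions --
but its cycles are leaner than the published ones: simulated females make
more and shorter trips with fewer fishing events each, and a larger
fraction of pairs fails at the reference condition. The energy budget
implied by the published constants sits close to break-even per foraging
cycle, so colony-level survival is very sensitive to the unpublished
decision surfaces; the acceptance script reports the corresponding
quantities exactly as the model produces them. The optimal body length
rises with distance, but the fitted slope is flatter than published and
noisy at desk-scale replication, because the cost side of `R = E/SP` grows
with length faster than survival improves when intake per fishing hour is
independent of body size.
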