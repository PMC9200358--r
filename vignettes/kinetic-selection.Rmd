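---
title: "Kinetic selection in a germinal-centre agent-based model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic selection in a germinal-centre agent-based model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kineticGC)
```

## The question the model asks

Affinity is a ratio: `K_A = k_on / k_off`. Two B-cell clones with identical
affinity for an antigen can therefore have completely different binding
kinetics — one binds rarely but almost never lets go, the other binds
instantly and releases almost immediately. Germinal-centre (GC) selection
is usually described as affinity-based, which would make these clones
interchangeable. This package simulates a GC reaction in which they are
*not* interchangeable: when the antigen-extraction process can be
interrupted by bond rupture, clones with low dissociation probability gain
a decisive advantage.

Three antigen-collection mechanisms are implemented as per-time-step
stochastic state machines over the states FREE, BOUND, EXTRACTING and
REFRACTORY:

* **Scenario 0** (reference): a free centrocyte (CC) at an FDC binding
  site binds with probability `affinity * P_C` and then extracts to
  completion. `P_C = min(1, C_Ag / S_Ag)` is the local antigen
  concentration factor.
* **Scenario 1**: binding occurs with `P_a * P_C`; in the next step the
  bond either dissociates (probability `P_d`) or extraction starts; during
  extraction every time step first applies a rupture test with probability
  `P_d`, then a completion test with probability `P_finish`.
* **Scenario 2**: as Scenario 1 without the rupture test.

The per-interaction capture probabilities have closed forms
(`captureProbability()`): `affinity * P_C`, and
`P_a P_C (1-P_d)` without rupture; with rupture the geometric series over
extraction durations closes to
`P_a P_C (1-P_d) * (1-P_d) P_finish / (1 - (1-P_d)(1-P_finish))`.
These closed forms are *oracles*: the test suite verifies that the
stochastic machine reproduces them to within binomial sampling error.

## Shape space and the kinetic decomposition

Cells live on an unbounded integer lattice (default 4 dimensions) with the
antigen at a fixed coordinate. The L1 distance `d` maps to affinity
through a Gaussian weight with width `Gamma = 2.8`,
`affinity = exp(-d^2 / Gamma^2)`; affinities below `3e-4` are truncated to
zero. The distance is decomposed through a per-clone angle `Theta` into an
association distance `d sin(Theta)` and a dissociation distance
`d cos(Theta)`:

```
P_a = exp(-d^2 sin^2(Theta) / Gamma^2)
P_d = 1 - exp(-d^2 cos^2(Theta) / Gamma^2)
```

so that `P_a (1 - P_d) = affinity` holds identically (the suite checks the
identity to 1e-12 absolute). `Theta` is clonal and immutable: somatic
hypermutation (SHM) moves a cell by exactly one grid point (uniform over
the `2 * nDims` unit moves), changing `d` but never `Theta`. Consequently
Clone-L (`Theta = 90`) has `P_d` pinned at 0 and can only evolve its
association rate, Clone-H (`Theta = 0`) has `P_a` pinned at 1, and Clone-M
(`Theta = 45`) moves both.

The founder distance is 5, the unique integer distance whose affinity
(0.0412) rounds to the documented founder value 0.04; all founders share
one shape-space coordinate (drawn uniformly from the L1 sphere of radius 5
per run) so that clonal differences are purely kinetic.

```{r}
founderPhenotypes()
```

## The agent-based GC reaction

The GC is a sphere of radius 160 um discretised at 5 um (about 137,000
sites, ~17 nL), split at the equator into a dark zone (DZ, `z > 0`) and a
light zone (LZ). Steady-state chemokine fields are pre-computed once per
run by solving the discrete diffusion–degradation equation
`D lap(c) - k c + s = 0` with unit sources (CXCL12 at 200 random DZ
stromal sites, CXCL13 at the FDC somata) by conjugate gradient; the ratio
`D/k` (default 64) sets a ~40 um decay length so gradients are detectable
across each zone. Cells walk persistently: one lattice step with
probability `speed * dt / 5 um` (0.18 per step for B cells at 7.5 um/min,
dt = 7.2 s), re-orienting every ~90 s either along the local gradient
(probability 0.5) or uniformly. Sites are exclusive — no two motile cells
share a lattice site; FDC dendrites do not block movement, otherwise their
sites would be unreachable binding sites.

The lifecycle follows the classic DZ/LZ cycle. Three founders (one per
clone) seed the DZ and expand through 6 divisions (7 h cycle, +/-25%
uniform jitter so division waves desynchronise). Each daughter mutates
independently with probability 0.5 per division; the dynamic
(affinity-dependent) mutation probability of the wider model family is
deliberately excluded. Exhausted centroblasts become centrocytes,
chemotax into the LZ, and search antigen under a 42-min deadline: a CC
with nothing collected at the deadline dies. Ag-carrying CCs seek T
follicular helper (Tfh) cells for up to 3 h; a Tfh helps exactly one
neighbour per step — the one presenting the most collected antigen, ties
uniform; cells with zero antigen never receive help. A CC is positively
selected after 30 min of cumulative help, re-enters the DZ with 2
divisions, and at each antigen-carrying division the split is asymmetric
with probability 0.72 (dominant daughter receiving 72%); the dominant
daughter of an asymmetric division leaves the GC as an output cell (OC;
memory/plasma not distinguished; OCs never die). All other daughters
continue cycling.

**Tfh contact model.** The description above leaves the contact mechanics
open, and they matter: with purely diffusive encounters a CC could never
accumulate 30 min of contact inside a 3 h window (Tfh occupy well under 1%
of LZ sites). We therefore model contacts as bound states, as the
base-model family does: a seeking CC arriving next to a Tfh engages and
holds position; the Tfh freezes while helping and polarises its help to
the strongest presenter among its contacts each step; an engaged CC that
receives no help for 6 min detaches and cannot re-engage for 3 min. The
patience and re-engagement constants were set once from minutes-scale
T-B contact biology; both are exposed in `lifecycleParams()`.

**Update order.** Within a step: motility for all agents in RNG-shuffled
order, collection updates, Tfh help, lifecycle transitions. The shuffle
removes systematic position bias while keeping runs bit-reproducible: all
randomness flows from one xoshiro256++ stream seeded by the run seed (plus
R's RNG, seeded identically, for the one-off stroma placement), and
replicate `i` of a configuration uses the counter-based child seed
`(masterSeed + 1000003 (i-1)) mod (2^31 - 1)`.

## Numerical and bookkeeping choices

* Site antigen is held in integer units (3000 per FDC spread over the
  ~49 sites of each FDC's soma plus six 40-um arms); one unit transfers
  per completed extraction. With exclusive site occupancy this makes
  mid-extraction depletion unreachable, but the degenerate branch (abort
  without antigen) is implemented and tested anyway.
* The rupture test precedes the completion test within an extraction step,
  so the survival factor after `N` extraction steps is exactly
  `(1-P_d)^N` including the completing step; the alternative ordering is
  available via `collectionParams(ruptureBeforeCompletion = FALSE)` for
  sensitivity analysis.
* The 72-s refractory starts at every dissociation, with or without
  antigen.
* An antigen ledger tracks every unit: sites + live cells + exported OCs +
  apoptotic losses must equal the initial load exactly (tested to 1e-8);
  cell bookkeeping closes as founders + divisions = alive + OCs +
  cumulative apoptosis.
* Time series are sampled hourly by default; a 21-day run is exactly
  252,000 steps of 7.2 s.

## What the small configurations emulate — and what they do not

`smallGCConfig()` (60-um sphere, 1 FDC, 10 Tfh, 4 expansion divisions,
2 days) exercises every pipeline stage in well under ten seconds and is
the fixture behind most tests. The scientific checks in the suite use
three scales, chosen to keep the default run affordable: clone
exchangeability under Scenarios 0 and 2 on a mid-size GC (60 um, 8 FDC,
20 Tfh, 6 days, 5 replicates); the Scenario-1 competition and the
affinity ordering at the default geometry over 10 days and 5 replicates;
and the reference affinity level at full scale (21 days, 5 replicates).
Passing these shows that the *mechanisms* behave as described under the
stated conditions — it does not calibrate the simulator against any
experimental GC data, and the three-clone founder set is an intentionally
extreme, low-diversity caricature of a real repertoire.

## Known limitations

* The simplified lifecycle (fixed post-selection division count, one
  helper signal integrated linearly) produces a weaker selection gradient
  than the full base-model machinery with antigen-graded division numbers.
  The measurable consequence, computed by the day-21 affinity check in the
  acceptance tests, is that living-cell mean affinity plateaus well below
  the ~60% level the full model family reaches without dynamic mutation
  probability. The clonal-competition conclusions (which compare clones
  within a scenario) are insensitive to this plateau; the absolute
  affinity level is not.
* Because free centrocytes re-attempt binding every time step while parked
  on an FDC site, the per-dissociation refractory taxes high-`P_d` clones'
  throughput even in Scenario 2, where per-attempt capture probability is
  clone-equal. This leaves a mild Clone-H deficit in Scenario-2 output
  counts (not statistically separable at the replicate scales used) and a
  residual Clone-H affinity elevation there.
* Chemokine receptor desensitisation is reduced to zone-dependent
  chemotaxis weights (centroblasts toward CXCL12, centrocytes toward
  CXCL13).
* Antibody feedback, memory/plasma fate split, mutation classes
  (lethal/silent) and any effect of SHM on `Theta` are out of scope.

## A minimal run

```{r, eval = FALSE}
cfg <- smallGCConfig(scenario = 1, nReplicates = 3, masterSeed = 1)
runs <- runReplicates(cfg)
aggregateReplicates(runs)
dominanceReport(runs)
```
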