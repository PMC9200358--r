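# kineticGC

Agent-based simulation of **kinetic selection** in germinal centres (GCs),
for computational immunologists studying affinity maturation and anyone
asking whether GC selection can discriminate between B-cell clones of
*identical affinity* but different binding kinetics.

Affinity is the ratio of kinetic rates, `K_A = k_on / k_off`, so equal
affinities hide very different phenotypes: a clone may bind antigen rarely
but essentially never release it, or bind instantly and release at once.
`kineticGC` simulates a 21-day GC reaction on a 3D lattice — centroblast
proliferation with somatic hypermutation in the dark zone, competition for
FDC-presented antigen and Tfh help in the light zone, recycling, and
output-cell export — under three antigen-collection mechanisms:

| Scenario | binding | pre-extraction unbinding | rupture during extraction |
|---|---|---|---|
| 0 (reference) | `Affinity · P_C` | — | — |
| 1 | `P_a · P_C` | `P_d` | `P_d` per time step |
| 2 | `P_a · P_C` | `P_d` | — |

Kinetics derive from an abstract shape space: with L1 distance `d` to the
antigen and weight width `Γ = 2.8`,

```
Affinity = exp(−d²/Γ²) = P_a · (1 − P_d)
P_a = exp(−d² sin²Θ / Γ²),   P_d = 1 − exp(−d² cos²Θ / Γ²)
```

where the angle `Θ` is fixed per clone: Clone-L (Θ = 90°, `P_d ≡ 0`),
Clone-M (Θ = 45°), Clone-H (Θ = 0°, `P_a ≡ 1`). Hypermutation moves a
cell one grid point, changing `d` but never `Θ`. Closed-form
per-interaction capture probabilities (including the geometric-series
closure of rupture-before-completion for Scenario 1) serve as oracles for
the stochastic engine. The time loop runs in compiled code
(252,000 steps of 7.2 s at full scale) and is bit-reproducible given a
seed.

## Worked example

Founder phenotypes — three clones, one affinity, three kinetic splits:

```r
library(kineticGC)
founderPhenotypes()
#>   cloneId thetaDeg distance         pA        pD   affinity
#> 1 Clone-L       90        5 0.04122232 0.0000000 0.04122232
#> 2 Clone-M       45        5 0.20303280 0.7969672 0.04122232
#> 3 Clone-H        0        5 1.00000000 0.9587777 0.04122232
```

The Scenario-1 capture probability per binding attempt collapses for the
fast-unbinding Clone-M founder:

```r
captureProbability(1, pA = 0.2030328, pD = 0.7969672)
#> [1] 0.0004158292
```

against `0.0412` for Clone-L (`P_d = 0` makes eventual extraction
certain) — a ~100-fold advantage that drives the clonal competition. A
small three-replicate Scenario-1 run shows it end to end in seconds:

```r
cfg <- smallGCConfig(scenario = 1, nReplicates = 3, masterSeed = 1)
runs <- runReplicates(cfg)
runs[[1]]
#> GCResult: Scenario-1, seed 1
#>   final (t = 48 h): Clone-L CB+CC=12 OC=15; Clone-M CB+CC=0 OC=0; Clone-H CB+CC=0 OC=0
#>   16 Tfh-phase centrocyte record(s), 15 output cell(s)

table(dominanceReport(runs)$dominant, useNA = "ifany")
#> Clone-L    <NA>
#>       5       1

oc <- do.call(rbind, lapply(runs, ocLog))
tapply(oc$affinity, oc$clone_id, length)
#> Clone-H Clone-L
#>       2      45
```

Clone-L holds the GC on almost every sampled replicate-day (the `<NA>` is
an early all-zero tie) and produces nearly all output cells, while the
fast-binding clones die out — the kinetic-selection signature. Full-scale
runs use `gcConfig()`; `aggregateReplicates()`, `dominanceReport()` and
`affinityCurves()` compute replicate envelopes, daily dominance and
affinity-maturation curves. A YAML-configurable command-line front end
lives at `inst/scripts/gc-sim.R` (`run` and `summarise` subcommands).

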