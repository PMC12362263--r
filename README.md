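# relmass

Simulation of stimulus-equivalence learning with projective-simulation
agents, Network Enhancement consolidation, and Relational Density Theory
metrics.

## What this package is for

Stimulus equivalence (SE) is the emergence of untrained conditional
discriminations — reflexivity, symmetry, transitivity — after only a subset
of relations has been directly trained. `relmass` simulates matching-to-sample
(MTS) experiments with a reinforcement-learning agent whose memory is a
weighted directed graph of *clips* (one per observed stimulus), and
instruments each run with the higher-order quantities proposed by Relational
Density Theory (RDT): per-class relational **density**, **volume**, and their
product, relational **mass**. It is intended for behavioural and
computational-modelling researchers who want a transparent, fully seeded
testbed for SE training structures and RDT measurement choices.

## The model

**Choice.** On each trial the agent sees a sample stimulus and a comparison
set (all stimuli carrying the correct comparison's role letter, across
classes, so untrained foils appear). It picks comparison *c_j* for sample
*c_i* with softmax probability

    p(c_j | c_i) = exp(beta * h(c_i, c_j)) / sum_k exp(beta * h(c_i, c_k))

with temperature `beta_h` during training and `beta_t` during testing.
Missing edges score at the initial weight `h0`, so novel comparisons are
choosable at chance.

**Learning.** The chosen edge is updated by the damped reinforcement rule

    h <- h - gamma * (h - 1) + lambda

with `lambda = +1` on a correct match and `-1` otherwise; the reverse edge
receives the same reward (mirrored reinforcement, the minimal mechanism by
which symmetry arises during training). Blocks repeat until block accuracy
reaches the mastery criterion (0.9), then the next phase begins.

**Consolidation.** Derived relations are introduced by a Network Enhancement
diffusion step: a K-nearest-neighbour transition matrix `P` (optionally the
symmetric localized kernel `T`) drives the iteration

    W <- alpha * kernel %*% W %*% kernel + (1 - alpha) * kernel

to its fixed point; the output is rescaled to the input's h range and written
back, preserving directly trained edges. Enhancement runs either once at the
end of training or at every mastery point (the two experimental conditions).

**Metrics.** Four volume measures (true and empirical nodal distance, class
size, number of relations) and three density measures (mean intra-class
transition probability, class accuracy, mean edge weight) are snapshotted
every trial; Pearson correlations of every density x volume pairing quantify
the inverse density-volume relationship predicted by RDT.

## Worked example

```r
library(relmass)
config <- make_fixture("cotter_stewart")   # 4 classes, 5 phases, 16 members
agent  <- run_agent(config, seed = 2)
print(agent$phase_stats, row.names = FALSE)
```

```
          phase trials_per_block blocks_used final_accuracy converged
    Phase 1: AB               48           6      1.0000000      TRUE
    Phase 2: BC               48           5      0.9166667      TRUE
    Phase 3: CD               24           5      0.9583333      TRUE
    Phase 4: DE               24           4      0.9166667      TRUE
 Phase 5: Mixed               72           1      0.9583333      TRUE
```

The agent needs five to six 48-trial blocks to master the early phases and
passes the mixed phase in a single block, because every relation it contains
was already trained. After the end-of-training enhancement:

```r
n_relations_total(agent$space)                               # 188
true_nodal_distance(agent$space, 1, config$classes)          # 5
mean_transition_probability(agent$space, 1, 0.1, config$classes)  # 0.1165
round(agent$test_accuracies, 3)
#   A-C   C-A   C-B   B-A   D-C   E-D   A-E   E-A
# 0.312 0.562 1.000 1.000 1.000 1.000 0.125 0.125
```

Enhancement has grown the 96 trained/incorrect relations to 188, collapsing
class 1's true nodal distance from 10 to 5; the intra-class transition
probability (~0.12) reflects the enlarged relation set. Symmetry probes
(C-B, B-A, D-C, E-D) are perfect; multi-node transitive probes remain weak at
the default K = 1 localisation (see the methods vignette for why).

Cohort-level experiments:

```r
cohort <- run_cohort(config)               # 15 seeded agents
cmp    <- compare_conditions(config)       # both enhancement schedules
write_cohort_results(cohort, "results/")   # trial logs, series, manifest
```

A thin command-line wrapper is installed at `inst/cli/relmass.R`
(`run`, `replicate`, `metrics`, `fixture` subcommands).

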