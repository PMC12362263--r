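---
title: "Simulating stimulus equivalence and relational density with relmass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating stimulus equivalence and relational density with relmass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relmass)
```

## The model and its assumptions

`relmass` simulates matching-to-sample (MTS) experiments with a
projective-simulation agent. The agent's memory — its *clip space* — is a
weighted directed graph with one clip per stimulus it has observed. Three
rules drive everything:

1. **Choice.** Given a sample and a comparison set, the agent samples a
   comparison with softmax probability
   $p(c_j \mid c_i) = e^{\beta h_{ij}} / \sum_k e^{\beta h_{ik}}$,
   restricted to the comparison set. Edges that do not yet exist are scored
   at the resting weight $h_0$, so unfamiliar comparisons are chosen at
   chance rather than never.
2. **Learning.** The traversed edge is updated by
   $h \leftarrow h - \gamma (h - 1) + \lambda$, where $\lambda$ is $+1$ for
   a correct match and $-1$ otherwise. The damping term pulls weights back
   toward the resting value 1; with $\lambda = 0$ the rule has fixed point 1
   for any $\gamma \in (0, 1]$. The reverse edge receives the same reward
   (*mirrored reinforcement*), which is the minimal mechanism by which
   symmetry relations appear during training rather than only after
   consolidation. h-values are unbounded in both directions; repeatedly
   punished foil edges go negative and stay there.
3. **Consolidation.** Network Enhancement (below) periodically rewrites the
   clip space, introducing derived (transitive/equivalence/reflexive)
   relations that training alone cannot create.

Training proceeds in phases; a phase's block (each trained pair presented
`presentations_per_pair` times, shuffled) repeats until block accuracy
reaches the mastery criterion. Test (entailment) trials use the testing
temperature and deliver no feedback.

The model assumes stimuli are abstract, interchangeable labels with no
perceptual structure: everything an agent knows is in its edge weights. It
has no response latency, no attention or motivation dynamics, and no
within-trial time course.

## Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `gamma` | damping toward the resting h-value (per update) | 0.001 | slow forgetting |
| `beta_h` | training softmax temperature (1 / h-units) | 0.1 | lower = slower learning |
| `beta_t` | testing softmax temperature | 4 | near-argmax at trained weights |
| `h0` | initial / assumed-missing edge weight | 1 | the damping target of the update rule |
| `mirror_updates` | reinforce the reverse edge too | `TRUE` | source of trained symmetry |
| `K` (`k_neighbors`) | neighbours kept in the enhancement kernel | 1 | see the K = 1 caveat below |
| `alpha` | diffusion retention weight | 0.7 | strictly inside (0, 1) |
| mastery criterion | block accuracy gate | 0.9 | per-block, not sliding-window |
| `max_blocks` | bound on blocks per phase | 50 | non-convergence is flagged, never truncated silently |

The defaults are the study conditions of the built-in `cotter_stewart`
fixture: four classes in a linear A-B-C-D-E series (classes 1-2 with five
members, 3-4 with three), D3/D4/E3/E4 present only as comparison foils,
phases AB/BC (48 trials per block), CD/DE (24), and a 72-trial mixed phase,
followed by entailment probes; 15 agents per condition.

### Why damping is per-update, not per-trial

A global forgetting variant (every stored edge damped once per trial) is
available via `agent_params(global_damping = TRUE)` but is off by default.
With $\gamma = 0.001$ and the roughly 750 trials that precede the mixed
phase, per-trial decay of all weights shrinks $h - 1$ by about 40%,
which drags mixed-phase accuracy far below what a mastery-gated design
produces: the relations entering the mixed phase were all trained to
criterion moments earlier and should still be near their trained strength.
The update rule already contains its own damping term for the edge it
touches, and that literal reading reproduces single-block mixed-phase
mastery.

## Network Enhancement

One application builds the nonnegative weight matrix $W$ over all clips
(negative h-values clamp to 0; node order is alphabetical so K-NN ties break
deterministically), then:

1. `knn_transition_matrix()`: $P_{ij} = W_{ij} / \sum_{k \in N_i} W_{ik}$
   for $j$ among the $K$ strongest neighbours of $i$ (self excluded), else
   0; rows with no neighbour mass become uniform so isolated clips stay
   well-defined.
2. The kernel is made *lazy*: $\tilde P = (P + I) / 2$. This mirrors the
   dominant-diagonal step of the reference Network Enhancement
   implementation, and it is not optional decoration: a linearly trained
   MTS graph is bipartite (role letters alternate along A-B-C-D-E), and for
   a bipartite kernel every term of the diffusion fixed point
   $(1-\alpha) \sum_k \alpha^k P^k P P^k$ preserves edge parity — an
   odd-path derived relation such as A-to-C could *never* form. Holding
   half the walk mass on the node breaks the parity and lets transitive
   mass flow. Disable with `ne_params(self_anchor = FALSE)` to study the
   bare equations.
3. For the symmetric variant (SNE), `local_network()` computes
   $T_{ij} = \sum_k P_{ik} P_{jk} / \sum_v P_{vk}$ (zero columns skipped);
   the directed variant (DNE, the default — it forms classes more cleanly)
   uses $\tilde P$ directly.
4. `diffuse()` iterates
   $W_{t+1} = \alpha \, \mathrm{kernel} \, W_t \, \mathrm{kernel} +
   (1 - \alpha) \, \mathrm{kernel}$ until $\max |\Delta W| <$ `tolerance`
   (default 1e-8, within 100 iterations; the map is a contraction with
   factor $\alpha$ for row-stochastic kernels, so about 50 iterations
   suffice at $\alpha = 0.7$).
5. Write-back: the output is rescaled to $[0, \max W]$ so the training
   temperature keeps its meaning. Entries below the fixed-point error bound
   `max_delta / (1 - alpha)` are numerical residue of the truncated
   iteration and are clamped to zero — materialising them would create
   epsilon relations that score *below* the missing-edge default $h_0$ and
   invert choices. Directly trained edges (baseline and mirrored symmetry)
   keep their trained values; other edges are only ever raised
   (`h <- max(h, enhanced)`), never reset: consolidation introduces derived
   relations, it does not undo differential feedback, and in particular it
   must not erase learned punishments at every mastery point.

The scheduling conditions: `end_of_training` applies enhancement once, after
the last phase and before testing; `during_training` applies it at every
mastery point (five times in the built-in design).

### The K = 1 caveat

With mirrored reinforcement, forward and reverse trained weights are nearly
equal, so at $K = 1$ the strongest-neighbour map tends to pair stimuli into
mutual two-cycles (A with B, C with D). Diffusion mass then circulates
inside the cycles and long transitive relations form only where the chain
happens to break asymmetrically. This is a property of one-neighbour
localisation, not a bug: at $K \ge 2$ the kernel spans both neighbours of
every interior node and transitive relations form robustly (the test suite
covers both regimes). Entailment accuracies at the default $K = 1$ are
accordingly strong for one-step symmetry probes and near chance for
multi-node probes.

## Relational Density Theory metrics

Per class and per trial the package records four volume measures — **true
nodal distance** (summed intermediate-node counts on shortest paths in the
*current* network, any relation above threshold, direction-agnostic;
disconnected pairs contribute the finite penalty `members - 1` so series
stay plottable), **empirical nodal distance** (same idea on the *trained*
structure only: a pure function of the training protocol, independent of
h-values), **class size** (roster members observed so far; comparison-only
foils never count), and **number of relations** (directed intra-class edges
above threshold) — and three density measures: **mean transition
probability**, **class accuracy** (cumulative), and **mean h-value**.
Relational mass is the density x volume product, and
`mass_correlations()` reports the per-class, per-agent Pearson coefficient
of every density x volume pairing, then averages (zero-variance series give
a missing coefficient, never 0).

The mean transition probability deserves a precise statement, because the
phrase admits several readings. The implemented measure takes the softmax
distribution (at `beta_h`) over the class's own relation set — every stored
edge between class members, reflexive included — and reports the average
probability *under* that distribution, $\sum_e p_e^2$. With comparable
h-values this is exactly the reciprocal of the number of intra-class
relations, hence roughly 1 / class size early in training; it falls as
training or enhancement adds relations and responds to `beta_h` through the
sharpening of the distribution. A single just-observed stimulus with no
relations rests on itself (degenerate distribution), producing the
characteristic spike at 1.0 at class onset. Two rejected alternatives — the
per-edge softmax against each source's outgoing edges, and the per-pair
transition mass — both *rise* within training phases as trained edges
sharpen, which destroys the inverse density-volume relationship the measure
exists to track and contradicts its documented 1-over-n behaviour.

A noteworthy artefact the metrics expose: when a later-phase stimulus first
appears as an untrained comparison, its class pairs are briefly connected
only through punished inter-class edges or not at all, so the true nodal
distance spikes before direct training pulls it back down.

## Numerical and design choices

- Edge-existence threshold `h0 + 1e-9`: a relation exists once reinforced
  above rest; enhancement-derived edges count as soon as they rescale above
  it.
- K-NN ties break by alphabetical label order; matrix node order is also
  alphabetical, making every enhancement application deterministic.
- Shortest paths treat relations as undirected (equivalence is
  bidirectional); the trained-structure metric counts an intermediate node
  per path step, which on simple trained paths automatically satisfies the
  classical "at least two trained relations" qualification.
- Entailment probes default to 4 presentations per tag instance
  (unspecified in the source design; configurable).
- Cohort agent $i$ runs with seed `base_seed + i`, so any agent is
  re-runnable in isolation and trajectories are invariant to cohort size.
- The comparison set of every trial is all same-letter stimuli across
  classes (4-alternative MTS in the built-in design), which is how the
  comparison-only foils D3/D4/E3/E4 enter.

## What the fixtures emulate — and what they do not

The built-in configurations generate abstract stimulus labels from the
design; there is no external data. Passing tests therefore demonstrate that
the *mechanisms* behave as specified under the study conditions — mastery
gating, enhancement scheduling, metric arithmetic, the inverse
density-volume relationship — not that human participants would produce the
same numbers. Real MTS data differ in at least response latency (absent
here by construction), participant attrition, perceptual similarity between
fabricated stimuli, and session effects.

Problem sizes: the test suite and the acceptance script run the full
two-condition, 15-agent replication (roughly 850 training trials per agent
with per-trial metric snapshots, about 25,000 trials per condition pair),
which completes in under a minute on a single core; unit tests use 6- to
10-stimulus designs.

## Known limitations

- Counterconditioning (reversal) phases and per-relation resistance are out
  of scope; relational mass is computed at class level only.
- At the default $K = 1$, multi-node derived relations are sparse (see the
  caveat above).
- The enhancement write-back scale is a modelling choice (the source
  designs leave it unstated); the rescale-to-input-range policy keeps the
  training temperature meaningful but other conventions are conceivable.
- No generalisation mechanism: stimuli never share features, so relational
  framing beyond equivalence cannot emerge.
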