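---
title: "Modelling the evolution of turn-taking and contest strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of turn-taking and contest strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the model addresses

Socio-ecological theory usually explains group structure through scramble
and contest competition: where resources are monopolizable, stable dominance
hierarchies are expected. But two individuals can also *cooperatively
partition* a resource by taking turns — alternating who behaves dominantly —
without repeated costly fights. This package implements an evolutionary
agent-based model in which such higher-level conflict strategies (how to
adjust escalation behaviour across repeated conflicts) coevolve with
within-fight behaviour (how long to persist in an escalated fight), so that
fighting costs and the quality of opponent assessment are evolved outcomes
rather than fixed species attributes.

## Model structure

Three nested time scales:

1. **Generations.** A conflict phase, fitness-proportional reproduction with
   mutation, death of all parents, and migration of offspring into randomly
   assigned groups of fixed size.
2. **Repeated conflicts.** Per generation, `n_conflict_rounds` rounds in
   which every dyad of every group contests one resource of benefit `b`.
   Escalation decisions are simultaneous Bernoulli draws on the
   dyad-specific willingness `w`; one lone escalator takes the resource
   uncontested, no escalator means a coin flip (and, deliberately, no
   experience update), two escalators fight.
3. **Within-fight rounds.** Both fighters pay `exp(s_opp - s_self)` per
   round, accumulate noisy evidence of being weaker in a decision variable
   `d` (reset to zero every fight; no cross-fight carry-over), and concede
   when `d` exceeds the heritable threshold `T`. Only the 0/1 outcome of a
   fight feeds back into future behaviour, through the willingness update
   with heritable factor `U`.

The two heritable parameters span the strategy space: `U < 0` with small `T`
is the turn-taking corner (each win switches the roles, fights are conceded
almost immediately), `U > 0` with larger `T` the contest corner (dominance
stabilizes and fights are informative about strength).

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `benefit` | fitness units per resource | 1 | the swept variable; turn-taking evolves only for small values |
| `initial_fitness` | starting fitness (fitness units) | 100 | bounds total affordable fighting; the floor at 0 forces give-up and disables escalation |
| `sigma_eps` | SD of per-round strength-perception noise | 1 | sets how many rounds of evidence an accurate assessment needs |
| `mutation_prob` | probability of redrawing (U, T) jointly | 0.001 | rare mutation; selection dominates |
| `U_init`, `T_init` | founder values | ±1, 0 | the two initial conditions of the main design |
| `n_conflict_rounds` | conflicts per dyad per generation | 10 | relationship length; more rounds favour contest |
| `n_groups`, `group_size` | population structure | 1000, 10 | full scale; the `desk` preset lowers groups to 200 |
| `n_generations` | evolutionary time | 5000 | full scale; `desk` uses 1000 |
| `max_fight_rounds` | fight-length safety cap | 10000 | unreachable at `sigma_eps >= 0.5`; breaches counted, resolved by coin |

## Numerical and procedural choices

Where the underlying description leaves micro-order open, the package fixes
it as follows (these choices are also the ones the tests pin down):

* **Costs** are charged every fighting round including the round of
  conceding; total cost is exactly `length × per-round cost`.
* **The fitness floor** is evaluated after the round's cost deduction;
  strictly negative fitness (`F < 0`) triggers a forced give-up, `F = 0`
  does not. A forced give-up permanently disables escalation and zeroes the
  individual's whole willingness map, and any individual whose fitness ends
  a conflict negative is treated the same way. A disabled individual's
  willingness stays zero (later updates cannot revive it), but it may still
  win no-escalation coin flips.
* **Simultaneity.** Give-up decisions use end-of-round state; if both
  concede in the same round (including a voluntary give-up coinciding with
  the opponent's forced one) the winner is a fair coin.
* **Willingness updates** both use the pre-conflict value and each
  individual's own `U`; the strict `d > T` comparison and the four-branch
  update are exact, and the update provably maps [0,1] into [0,1].
* **Dyad order** within a conflict round is freshly randomized; order could
  matter only through the fitness floor.
* **Selection** samples parents with replacement proportional to fitness
  clamped at zero, within the natal group; if a whole group is at zero the
  draw is uniform (logged design fallback).
* **Migration** is a single global permutation of all offspring into
  equal-size groups — satisfying "random group" plus exact size
  conservation without rejection sampling.
* **Founders** are initialized exactly like offspring (strength uniform on
  [0,1], fitness `F0`, willingness 1) with `U = U_init`, `T = T_init`;
  variation then enters through mutation only.

## Measurement layer

Metrics use only conflicts with at least one escalator (coin-flip conflicts
carry no relationship information). The **directional consistency index**
pools over dyads: `sum(H - L) / sum(H + L)` with `H`/`L` the wins in the
more/less frequent direction; the unweighted per-dyad mean is also reported,
since the index's standard usage is ambiguous between the two. **Linearity**
is Landau's `h`, with undecided dyads (ties, including zero interactions)
resolved uniformly at random over `n_randomizations = 2000` repeats and
averaged — the randomization treatment of unknown relationships; the exact
historical variant is not recoverable from the cited sources, so this
convention is pinned by tests against a brute-force triad-count oracle.
**Strategy classification** uses mean final-generation `U`: at or below
−0.5 is turn-taking, at or above +0.1 contest, otherwise ambiguous. The
thresholds are configurable conventions; evolved populations in practice sit
near −1 or clearly above +0.3, so the bands are wide relative to observed
clusters.

## What the synthetic data is and is not

Two kinds of synthetic input exist. The simulator itself generates all data
from the stated world (no empirical input): its defaults are the published
parameterization, and the `desk` preset (200 groups, 1000 generations)
only reduces replication — chosen because the slowest qualitative
transition observed (turn-taking collapsing to contest at benefit 5)
completes within the first ~150 generations, leaving a 6-fold margin.
Separately, `synthetic_interactions()` produces idealized interaction logs
(alternating, despotic, random) used to pin the metrics to their fixed
points. A green desk-scale test establishes that the mechanism produces the
qualitative regimes (bistability at small benefits, contest-only at large
benefits, frequency-dependent invasion barriers); it does not reproduce
full-scale quantitative values such as exact evolved `T` per benefit, which
have wider between-run spread at 200 groups.

## Open choices decided here

* Metrics are computed on the final generation (all of its conflict
  rounds), not pooled across generations; per-generation means of `U`, `T`,
  fitness and fight statistics are always recorded.
* In competition experiments "equal numbers of each strategy per group" is
  implemented as identical within-group composition (`k` of strategy A in
  every group), swept over all `k`, since the frequency axis of interest is
  the within-group count.
* Strategy profiles for competition experiments are the evolved means
  derived from this package's own sweep runs
  (`derive_strategy_profiles()`), as the published means are not printed.
* The two simulation engines (compiled core, default; plain-R reference
  driving the exported per-operation functions) implement the identical
  model and are compared statistically in the tests; they do not share an
  RNG stream, so cross-engine runs are not bit-identical, but each engine
  is bit-reproducible from its seed.

## Known limitations

* No generalized winner–loser effects, eavesdropping, coalitions, or
  updating of `T` from experience — outcomes only feed the dyadic
  willingness.
* Asexual, non-overlapping generations; no within-generation death (an
  individual at negative fitness stops escalating but persists).
* The plain-R engine is for validation and small experiments; sweep-scale
  work should use the default compiled engine.
* Fight lengths at `sigma_eps = 0` with exactly equal strengths terminate
  only via the fitness floor (or the length cap); this is unreachable under
  the studied noise levels but is why the cap exists.
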