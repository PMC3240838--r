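# turntaking

An evolutionary agent-based simulator of conflict strategies in group-living
animals, for behavioural ecologists and evolutionary game theorists studying
how dominance relationships — or their cooperative alternative, turn-taking —
emerge from repeated dyadic conflicts when fighting costs and opponent
assessment are themselves products of evolution.

## The model

Individuals live in stable groups and repeatedly contest a resource of
benefit *b*. Each individual *i* holds a dyad-specific *willingness to
escalate* $w_{i,j} \in [0,1]$: in a conflict, both members of a dyad
simultaneously decide (Bernoulli in $w$) whether to escalate. If neither
escalates, a random individual takes the resource; if one escalates, it takes
the resource; if both escalate, a costly fight decides.

Fights follow sequential-assessment dynamics. Each fighting round, individual
*i* pays a cost $c_i = e^{s_j - s_i}$ (strengths $s \in [0,1]$; the weaker
pays more), receives a noisy estimate of relative strength
$\Delta s = s_i - s_j + \varepsilon$, $\varepsilon \sim N(0, \sigma_\varepsilon^2)$,
and subtracts it from a decision variable $d$ (evidence of being weaker,
reset to 0 each fight). An individual concedes when $d$ exceeds its heritable
*giving-up threshold* $T \in [0,5]$, or is forced to concede when fitness
drops below zero (which also permanently bars it from escalating).

After any conflict with at least one escalator, both members update their
willingness using a heritable *update factor* $U \in [-1,1]$:

| role   | $U > 0$            | $U < 0$              |
|--------|--------------------|----------------------|
| winner | $w + U(1-w)$       | $w + Uw$             |
| loser  | $w - Uw$           | $w - U(1-w)$         |

Positive $U$ stabilizes dominance (winners embolden, losers withdraw);
negative $U$ makes roles alternate. Generations consist of a conflict phase,
fitness-proportional reproduction ($P_i = F_i / \sum_j F_j$, negative fitness
clamped to zero) with joint mutation of $(U, T)$ at probability 0.001, death
of parents, and random migration of offspring into equal-size groups.

The measurement layer computes the directional consistency index (DCI),
Landau hierarchy linearity with randomization over undecided dyads, fight
lengths, and classifies evolved populations as *turn-taking* (strongly
negative mean $U$, low $T$) or *contest* (positive mean $U$, high $T$).

## Worked example

```r
library(turntaking)

# Two desk-scale runs at a small benefit, started from opposite corners
r_tt <- run_simulation(sim_preset("desk", benefit = 1, U_init = -1, seed = 3))
r_ct <- run_simulation(sim_preset("desk", benefit = 10, U_init = 1, seed = 4))

tail(r_tt$summary, 1)[, c("mean_U", "mean_T", "mean_fight_length")]
#>         mean_U      mean_T mean_fight_length
#> 1000 -0.997877 0.006653076          1.981782
classify_strategy(r_tt$individuals$U)
#> [1] "turn_taking"

tail(r_ct$summary, 1)[, c("mean_U", "mean_T", "mean_fight_length")]
#>         mean_U   mean_T mean_fight_length
#> 1000 0.5719256 1.730939          7.348066
classify_strategy(r_ct$individuals$U)
#> [1] "contest"
```

At benefit 1 with a turn-taking start the population stays at $U \approx -1$,
$T \approx 0$: dyads alternate who takes the resource, fights are rare and
short (mean length under 2 rounds, almost all from the one opening fight per
dyad), and dominance is directionally inconsistent (group-mean DCI 0.002
via `group_metrics()`). At benefit 10 every start evolves the contest
strategy: positive $U$, a high giving-up threshold ($T \approx 1.7$) and
long fights (~7 rounds) that reliably identify the stronger individual,
producing stable, unidirectional relationships (group-mean DCI 0.949).

The experiment drivers reproduce the analysis designs:
`main_sweep()` (benefit 1–10 × initial $U \in \{-1, 1\}$),
`derive_strategy_profiles()` + `competition_experiment()` /
`competition_curve()` (invasion analysis at fixed strategy frequencies),
and `sensitivity_sweep()` (noise SD, conflict rounds, group size). A CLI
wraps all of them:

```sh
Rscript inst/cli/turntaking sweep --preset desk --seed 1 --replicates 2 --out results/
```

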