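# opponentSR

Opponent dual-system reinforcement learning with successor and individual
state representations, in dynamically changing reward environments.

## The scientific problem

The basal ganglia's direct and indirect pathways are thought to learn
preferentially from positive and negative dopamine signals (reward
prediction errors), and different cortical inputs may supply those
pathways with *different state representations*. This package simulates
an agent composed of two parallel learning systems to ask when such an
"opponent" arrangement is advantageous. Each system represents states
either

- **individually (IR)** — one tabular value per state, or
- **through the successor representation (SR)** — each state encoded by
  its expected discounted future occupancy of every state,
  σ(S_i, S_j), with a learned linear read-out,

and each system has its own learning rates for positive versus negative
temporal-difference reward prediction errors (TD-RPEs), α⁺ and α⁻. The
two system-specific values are averaged into an **integrated value**
V(S), used for softmax action selection
(P(S_i) ∝ exp(βV(S_i))) and for the single TD-RPE shared by both
systems:

```
δ = γ V(S')  − V(S)        (ordinary move)
δ = reward   − V(S)        (at the rewarded state; no successor term)
```

IR systems update `V(S) ← V(S) + α± δ`. SR systems TD-learn their
occupancy features,
`σ(S, S_j) ← σ(S, S_j) + α_SRfeature (1{S = S_j} + γ σ(S', S_j) − σ(S, S_j))`,
and update the read-out weights `w_j ← w_j + α± σ(S, S_j) δ`, so the
system value is `V_sys(S) = Σ_j w_j σ(S, S_j)`.

The test bed is a 5×5 grid world: 500 reward-free steps, then nine
500-step epochs in which a reward relocates stochastically among nine
candidate states (60% at an epoch-specific "special" candidate, 5% at
each of the other eight) every time it is consumed. Six task variants
manipulate those dynamics, and three two-stage decision tasks probe
generalisation. The central finding this package reproduces: **an
appetitive SR-based system (high α⁺/α⁻) paired with an aversive IR-based
system (low α⁺/α⁻) performs best** in the original dynamic task, and
this advantage reverses or disappears when the task's reward dynamics
change.

## Worked example

```r
library(opponentSR)

# appetitive SR (ratio 4) + aversive IR (ratio 0.25)
spec <- agent_spec("SR", "IR",
  alpha1_pos = 0.8, alpha1_neg = 0.2,
  alpha2_pos = 0.2, alpha2_neg = 0.8,
  beta = 5, gamma = 0.7)
run <- run_navigation(spec, "original", seed = 1)
run
#> <nav_run> variant: original  seed: 1  total rewards: 147
tabulate(run$placement_epochs, 9)
#> [1] 19 18 18 17 14  9 16 25 11   # rewards per placement epoch
```

147 rewards over the 4500 rewarded steps means one reward every ~31
steps (the theoretical ceiling is 900: at least 4 moves plus the
teleport step per reward). Sweeping both systems' α⁺/α⁻ ratios with the
sum of rates fixed at 1 (100 simulations per condition):

```r
sw <- sweep_ratio_grid("SR", "IR", n_sims = 100, master_seed = 101)
sw[which.max(sw$mean), c("ratio1", "ratio2", "mean", "sem")]
#>   ratio1 ratio2   mean  sem
#>        5    0.2 125.66 1.75
sw$mean[sw$ratio1 == 4 & sw$ratio2 == 0.25]   # appetitive SR + aversive IR
#> [1] 122.15
sw$mean[sw$ratio1 == 0.25 & sw$ratio2 == 4]   # the mirrored combination
#> [1] 71.52
```

The best cells sit where the SR ratio is high and the IR ratio low; the
mirrored combination collapses. The numbered scripts under `analysis/`
walk through the full set of analyses (single runs, ratio and free-rate
sweeps, repeated-sweep best-condition frequencies, learning curves,
value snapshots, task variants, two-stage tasks), writing their tables
under `results/`.

## Package layout

- `R/`, `src/` — the package: grid and task environments (`nav_task`,
  `nav_step`), two-stage tasks (`twostage_task`, `run_twostage`), the
  dual-system agent (`agent_spec`, `agent_step` and the per-update
  operations), runs and sweeps (`run_navigation`, `sweep_ratio_grid`,
  `sweep_free_rates`, `best_condition_frequency`), analysis helpers
  (`learning_curves`, `value_snapshot`), and I/O (`load_config`,
  `export_sweep`, `write_manifest`).
- `analysis/` — numbered narrative drivers over the package.
- `vignettes/opponent-learning.Rmd` — the methods vignette: model
  equations, update ordering, task construction, seed discipline, and
  design decisions.
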