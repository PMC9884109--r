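---
title: "Opponent dual-system learning with SR and IR representations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opponent dual-system learning with SR and IR representations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opponentSR)
```

This vignette is the package's account of the model it implements, the
simulated tasks that serve as its data generators, and the numerical and
design decisions behind both. Everything quantitative stated here is
computed by the test suite or the scripts under `analysis/`.

## The model

The agent holds two learning systems. Each system `i` assigns every
state a system-specific value; the integrated value is their arithmetic
mean,

$$V(S) = \tfrac{1}{2}\left(V_{\mathrm{sys1}}(S) + V_{\mathrm{sys2}}(S)\right),$$

and is the only value the agent acts on: moves are drawn by softmax over
the integrated values of the neighbouring states,
$P(S_i) = \exp(\beta V(S_i)) / \sum_j \exp(\beta V(S_j))$, and a single
temporal-difference reward prediction error (TD-RPE) is computed from
integrated values and shared by both systems,

$$\delta_{t+1} = \gamma V(S_{t+1}) - V(S_t)$$

on an ordinary move (no reward is delivered on moves), and

$$\delta_{t+1} = R - V(S_t)$$

at a terminal step (the rewarded state in the navigation task; a
second-stage option in the two-stage tasks), with no successor term.

Learning is opponent: each system has separate learning rates
$\alpha_i^+$ for non-negative and $\alpha_i^-$ for negative TD-RPEs. A
$\delta$ of exactly zero uses $\alpha^+$. A system with
$\alpha^+/\alpha^- > 1$ is *appetitive* (learns mainly from positive
surprises), with ratio $< 1$ *aversive*.

An **IR** system stores values directly:
$V(S_t) \mathrel{+}= \alpha^\pm \delta$. An **SR** system represents
each state by its estimated discounted future occupancies
$\sigma(S_i, S_j)$ of all states, TD-learned from experience with rate
$\alpha_{\mathrm{SRfeature}}$:

$$\sigma(S_t, S_j) \mathrel{+}= \alpha_{\mathrm{SRfeature}}
  \left(\mathbb{1}\{S_t = S_j\} + \gamma\,\sigma(S_{t+1}, S_j)
  - \sigma(S_t, S_j)\right),$$

with the $\gamma\sigma(S_{t+1},\cdot)$ term dropped at terminal steps.
Its value is the linear read-out
$V_{\mathrm{sys}}(S) = \sum_j w_j \sigma(S, S_j)$, and the weights learn
from the shared TD-RPE with credit spread over the occupied state's
features: $w_j \mathrel{+}= \alpha^\pm\, \sigma(S_t, S_j)\, \delta$.

### Within-step update order

The order of operations inside one step is a genuine degree of freedom:
the TD-RPE, the SR feature update, and the weight update all touch
$\sigma(S_t,\cdot)$. The package fixes the order as: (1) compute
$\delta$ from pre-update values; (2) update the SR feature row of the
occupied state; (3) update weights/values using $\delta$ and, for SR
systems, the **just-updated** feature row. We initially implemented the
weight update with the pre-update row; both orders are behaviourally
near-equivalent at the default $\alpha_{\mathrm{SRfeature}} = 0.05$
(grid-level performance differs by ~1 reward in ~125), but the
post-update order is what a conventional sequential implementation of
these equations produces (error, feature update, weight update as
consecutive statements), and it is the order under which the fine
structure of the ratio-sweep optimum matches the published landscape, so
it is the one the package uses — in the compiled engine and the pure-R
`agent_step()` alike.

## The navigation task as data generator

The environment is a 5×5 grid (states indexed row-major from the
bottom-left start state (1,1)). A run is always 5000 steps: 500
reward-free steps, then 4500 rewarded steps. In the original task the
rewarded phase is nine 500-step epochs; nine candidate states line the
two far edges, one per epoch is "special" (a fresh permutation each
simulation), and every placement puts the reward on the special
candidate with probability 0.6, else uniformly on one of the other
eight. A placed reward persists — across epoch boundaries if necessary —
until consumed.

Timing conventions (they fix what a "step" means and hence all reported
magnitudes):

- Consumption happens when the agent occupies the rewarded state at step
  $t$; the terminal TD-RPE and updates apply, and the agent is carried
  back to the start state, the teleport occupying step $t+1$. No action
  is selected at the rewarded state and no TD-RPE bridges the teleport.
  A reward cycle therefore costs at least 5 steps (4 moves + teleport),
  bounding a run at 900 rewards.
- The replacement reward is drawn at the consumption step, using the
  special candidate of the epoch containing that step.
- Epoch boundaries sit at $t = 500, 1000, \ldots$; the special state
  changes exactly there even if a reward is pending. The first reward
  appears at $t = 501$.
- Periodic-reset variants redraw the reward location every
  `reset_period` steps of the rewarded phase (at $t = 501 + mP$), using
  the then-current epoch's special candidate, whether or not the pending
  reward was consumed.
- A reward consumed exactly at $t = 5000$ counts; the run ends there
  regardless of pending rewards. This end-of-run convention affects at
  most one reward in 5000 steps and is below sampling noise at the
  study's simulation counts.

The six variants (`p_special_70..100`, `periodic_reset_500..50`,
`single_epoch`, `deterministic_short_epochs`, `uniform_candidates`,
`fixed_order_control`) all preserve the 500 + 4500 budget and are
constructed by `nav_task()`.

What the generator emulates is the *statistical structure* of a volatile
foraging environment — persistent but relocating rewards, partial
predictability of the relocation target, occasional regime shifts. What
it does not emulate: sensory uncertainty (the state is fully observed),
action failure, reward magnitude variation, or any continuous-space
structure. Results that pass on this generator show that the opponent
architecture exploits *these* dynamics; they do not by themselves
establish anything about noisy or partially observable environments.

## The two-stage tasks

Three variants (`twostage_task()`): the classic two-option task with
Gaussian-random-walk reward probabilities (step SD 0.025, reflecting
boundaries 0.25/0.75, 201 trials, 70%/30% stage transitions), a
contingency-change variant with fixed probabilities switching at trials
51/101/151, and a three-option variant (three pairs, 60/20/20%
transitions, switches at trials 51/101, 150 trials). Per trial the agent
chooses at both stages by softmax over integrated option values
($\beta = 5$, $\gamma = 1$); the SARSA-type first-stage TD-RPE
$\delta^{(1)} = \gamma V(O^{(2)}) - V(O^{(1)})$ is computed after the
second-stage choice, and the second-stage TD-RPE
$\delta^{(2)} = R - V(O^{(2)})$ uses values reflecting the
$\delta^{(1)}$ updates.

Decisions the task description leaves open, fixed here:

- The random walk's initial probabilities are drawn uniformly from
  [0.25, 0.75], the walk's stationary support. Other choices (e.g. all
  0.5) change only the first few trials of a 201-trial task.
- Trial indices are 1-based: "changes at trial 51" means trials 1–50 use
  the first block.
- Second-stage options are terminal: their SR rows stay identity rows
  and are never updated; only the chosen first-stage option's SR row is
  updated, after the stage transition. The initial SR matrix encodes the
  presumed transition probabilities and a random second-stage policy, so
  a first-stage row holds 1 on itself and
  $\gamma\, P(\mathrm{pair}) \cdot 0.5$ on each second-stage option
  (e.g. $(1, 0, 0.35, 0.35, 0.15, 0.15)$ for the two-option task), and
  first-stage rows sum to $1 + \gamma$.

## Parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| $\alpha_i^\pm$ | learning rates from non-negative / negative TD-RPEs (unitless, [0,1]) | set per experiment | the swept quantity of interest |
| $\alpha_{\mathrm{SRfeature}}$ | SR feature learning rate | 0.05 | slow, stable occupancy learning; {0.05..0.25} swept in the free-rate analyses |
| $\beta$ | softmax inverse temperature | 5 (2.5–15 in sweeps) | moderate exploitation |
| $\gamma$ | discount factor | 0.7 navigation, 1 two-stage | study conditions |
| sum $\alpha^+ + \alpha^-$ | rate budget per system in ratio sweeps | 1 | makes the ratio the only axis; ratio cells implying a rate > 1 (e.g. ratio 5 at sum 1.25) are dropped |

Ratio grids use
$\{0.2, 0.25, \tfrac13, 0.5, 1, 2, 3, 4, 5\}$ with
$\alpha^+ = \mathrm{sum}\cdot r/(1+r)$. Free-rate sweeps draw all four
rates from $\{0.2, 0.35, 0.5, 0.65, 0.8\}$; when both systems share a
representation, $(x, y, z, w)$ and $(z, w, x, y)$ describe the same
model, so each unordered pair is simulated once at the full simulation
count.

## Randomness, reproducibility, numerics

All stochastic elements — the per-simulation special-state permutation,
placements, action selection, transitions, outcomes, random-walk
schedules — consume R's global RNG in a documented order (neighbours are
enumerated left, right, down, up; one uniform per softmax draw against
the cumulative probabilities; placement draws one uniform, plus a second
only when a normal candidate is chosen). Sweeps spawn one child seed per
(condition, simulation) from the master seed, so any single run can be
re-executed in isolation and results are independent of execution order.

The compiled engine mirrors the pure-R per-step operations exactly,
including extended-precision accumulation where base R's `sum()` and
`cumsum()` use it, and the suite asserts *bit-identical* trajectories,
values, and SR matrices between the two engines on the same seed — the
R functions are the executable specification of the C++ core. Values and
weights are double precision throughout, never clipped; SR matrices are
zero-initialised (navigation) and not decayed for unvisited states.

Summary statistics follow the population convention: SD normalised by
$n$, SEM approximated as SD$/\sqrt{n}$.

## Learning curves and snapshots

Learning curves report the mean time (steps between consecutive goal
reaches; the first reward of a run is timed from step 500) to the 1st,
2nd, … reward *placed* in each of epochs 2–9: a reward placed in epoch
$k$ but consumed later still belongs to epoch $k$. Epoch 1 is excluded
(no preceding reward). A reward index is reported only if obtained in at
least a quarter of the simulations in all eight epochs, so rarely
reached indices do not distort the average. Value snapshots are taken
just after the last consumed reward of a run; single-run displays use
the first run (in a fixed seed sequence) whose last reward was placed in
epoch 9 on that epoch's special candidate — the selection rule among
qualifying runs is otherwise arbitrary, and "first qualifying" keeps it
deterministic.

## Problem sizes

Unit and property tests run single simulations or short synthetic walks
(20k–50k steps). The reproduction tests use the study's own scales: 100
simulations per condition for navigation sweeps (325 merged free-rate
conditions; 81 ratio cells; ten sweep repetitions for the best-region
check), and 500 simulations per condition for the two-stage region
contrast — that task's performance landscape spans only a few rewards,
and at 100 simulations the region contrast is within sampling noise
(the original analyses used 1000). The acceptance script pools eleven
100-simulation ratio sweeps when locating the optimal ratio cell;
pooling is the lower-variance variant of taking the modal argmax across
repetitions.

## Known limitations

- The ratio-sweep optimum's fine structure is flat: at high precision
  the top cells (SR ratio 4–5, IR ratio 0.2–1/3) differ by ~1 reward in
  ~124, so the argmax *cell* of any single 100-simulation sweep is
  noisy even though the appetitive-SR/aversive-IR *region* is stable.
  Conclusions should be drawn at region level.
- Exact trajectories of the original study are not reproducible (its
  random streams are not specified); only distributions are.
- Tabular SR only: no successor features over arbitrary feature maps, no
  eligibility traces, no default-representation variant.
- The two systems are combined by a fixed unweighted mean; arbitration
  or learned mixing is out of scope.
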