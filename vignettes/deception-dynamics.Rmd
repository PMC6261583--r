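---
title: "Modelling deception in an evolutionary iterated prisoner's dilemma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling deception in an evolutionary iterated prisoner's dilemma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deceptIPD)
```

## The model

`deceptIPD` simulates a population of agents that repeatedly play the
prisoner's dilemma and evolve. Each agent carries a three-locus heritable
genome — an IPD strategy, a deception behaviour, and a mutation
probability — plus two experiential fields that are not inherited: a
bounded, identity-free memory of the last three opponent moves, and a
cumulative score. Payoffs are the classic non-negative values T = 5
(temptation), R = 3 (reward), P = 1 (punishment), S = 0 (sucker), which
satisfy T > R > P > S and map onto donation-game parameters as T = b,
R = b − c.

Seven strategies are supported: AllC, AllD and Random ignore the memory;
TFT copies the most recent remembered opponent move; TF2T defects only
after two remembered defections; Pavlov plays win-stay/lose-shift (a win
is having received T or R, i.e. the opponent cooperated); Probabilistic
cooperates with probability equal to the remembered cooperation fraction.
Empty-memory defaults are the standard conventions: TFT, TF2T and Pavlov
cooperate, Probabilistic uses 1/2. Memory is *identity-free*: an agent
remembers outcomes, not who produced them, so the moves of successive
opponents share one memory. This is the channel through which deception
and defection propagate socially: one defection observed poisons the
victim's behaviour towards its *next* partners.

### Deception operators

Four operators model information-theoretic attack classes on the victim's
pre-move state:

* **Degradation** — hides information in noise: every remembered opponent
  move is resampled as a fair coin flip.
* **Corruption** — substitutes a plausible false message: every remembered
  Defect is rewritten as a Cooperate.
* **Denial** — disables collection: the victim does not observe the
  attacker's move this round (the capacity-equation limit W → 0).
* **Subversion** — alters the processing algorithm: the victim's strategy
  is permanently set to AllC.

Degradation and Corruption are the operators used in the shipped
experiments; Denial and Subversion are implemented and unit-tested but
excluded from experiment configurations (Denial is structurally
self-defeating in the IPD — an agent known to deny is best met with
defection — and Subversion realistically requires a priming Corruption
campaign that is out of scope).

### The encounter protocol

Every encounter resolves one PD round in one of four cases. With no
deceiver, both agents select moves from their true memories. With one
deceiver, the victim's *counterfactual* move is first selected from its
unaltered memory and the baseline payoffs saved; the operator is then
applied to the victim's stored state (the edit persists beyond the
round), the victim selects from the altered state, and payoffs follow
from the actual moves. With mutual deception both baselines are saved,
both operators applied simultaneously, and both moves re-selected. A
deceiver always pays the configured cost, success or not, and a deception
is recorded *successful* only when the deceiver's gross payoff strictly
exceeds its baseline. Against memory-insensitive victims (AllC, AllD)
deception therefore always fails and costs.

Two protocol details are worth making explicit. First, the memory edit is
not undone after the round: the operator corrupts stored state, then the
opponent's actual move is appended (evicting the oldest entry), so
deception leaves a lasting trace in the victim. Second, under Denial the
victim's pre-move state is untouched, so its actual move is its
counterfactual move; re-drawing a stochastic strategy there would
manufacture spurious success/failure flags out of RNG noise.

### One generation

A tick (one generation) consists of: a uniformly random perfect matching
of the 50 agents; each pair playing a *match* of
`rounds_per_encounter = 6` consecutive rounds (deceivers deceive, pay,
and are success-scored on every round); removal of the two agents with
the lowest cumulative score (ties uniform at random); and replacement by
two offspring bred from a score-weighted parent (weights max(score, 0),
uniform fallback) and a second uniformly chosen parent, via two-point
crossover on the ordered 3-locus genome followed by per-locus mutation at
the offspring's own mutation probability (strategy → uniform over all
seven; deception → uniform over the run's allowed set; mutation
probability → Gaussian perturbation, sd 0.01, clipped to [0, 1]).
Capping turnover at two agents per generation deliberately bounds the
rate at which an invading behaviour can diffuse.

## Parameters that matter, and why these defaults

* **`rounds_per_encounter = 6`** (rounds per match, dimensionless). The
  match length sets the balance of power between retaliation and
  exploitation and is the one structural parameter the behaviour of the
  system is genuinely sensitive to. With single-round encounters,
  identity-free memory makes both players' cooperation probabilities a
  property of the shared environment, so defection is pointwise dominant
  and cooperation always collapses; with ten or more rounds per match,
  within-match retaliation is so strong that defectors can never invade.
  Six rounds — twice the memory depth — reproduces the intended regime:
  cooperation is stable enough to persist, yet exploitative and deceiving
  lineages can invade and coexist in a noisy polymorphism.
* **`initial_mutation_prob = 0.02`** (per locus, per offspring). Sets
  both the waiting time for deceiving genotypes to arise and the standing
  "mutation load" of deceivers present for reasons other than selection.
  With two offspring per generation, a deception flip probability of
  mp/2, and neutral lineage lifetimes of a few tens of generations, the
  load is roughly `2 * mp/2 * lifetime / 50` of the population; keeping
  it below one agent equivalent (0.02) requires mp below roughly 0.015 to
  0.02, so that deceiver persistence measures selection, not mutation
  pressure.
* **`newborn_score = "parent_mean"`**. Offspring start at the mean of
  their parents' cumulative scores. Culling compares cumulative scores,
  so a score-zero newborn is almost surely one of the two lowest once
  incumbent scores have grown, which freezes the incumbent population
  and makes invasion impossible; score inheritance (as agent-copying
  primitives in agent-based platforms typically behave) restores lineage
  turnover while keeping fitness cumulative. The score-zero
  `"zero"` initialisation remains available.
* **`cost`** (score units per round, per deceiving player). The swept
  treatment variable. Degradation experiments sweep 0.05–0.3; corruption
  experiments sweep 0–1.2.
* **`memory_depth = 3`**, population 50, 5001 generations: the study
  conditions; deeper memory mainly slows the simulation without changing
  the retaliation structure, since the influential strategies look back
  at most two moves.

## Experiment drivers and outcome measures

`run_sweep()` runs a seeded grid (cost × replicate, per-run seeds derived
from one master seed) and persists per-run CSVs plus an index.
`classify_equilibrium()` labels a run's outcome as collapse to a
non-cooperative equilibrium, stable cooperative equilibrium, cyclical
polymorphism, or stable polymorphism, from the cooperative-strategy
fraction (cooperative = TFT, TF2T, AllC, Pavlov, Probabilistic;
exploitative = AllD, Random):

* *Collapse* and *fully cooperative* are level tests on the final 500
  ticks (thresholds 0.05 and 0.95 — one-agent resolution at n = 50 is
  0.02, so 0.05 separates "essentially extinct" from small persistent
  minorities).
* *Cyclical* requires a dominant narrowband oscillation. A raw
  periodogram peak-to-median test cannot be used here: for white or red
  noise the maximum of exponentially distributed ordinates grows like
  log n, and an AR(1) census would be misread as cyclic from its red
  spectrum alone. The detector therefore smooths the periodogram
  (modified Daniell spans 9, 9) and compares each ordinate to a local
  running-median baseline (window 31): smooth red spectra give ratios
  near 1, genuine narrowband cycles give ratios far above the declared
  threshold of 3. At these settings the noise ceiling across seeds is
  about 2.3 and injected oscillations score above 10.
* `collapse_tick()` reports the start of the *terminal* below-threshold
  stretch (at least 100 ticks, running to the horizon): collapse is an
  absorbing outcome, and the transient cooperative dips of corruption
  diffusion cycles must not count.
* `establishment_tick()` scans 500-tick windows for the earliest point
  where the cooperative fraction has left the founding all-cooperative
  phase (window mean at most 0.9) and is stationary (fitted linear change
  at most 0.1 over the window, no dominant oscillation). At low deception
  cost individual runs are bimodal — some never leave the cooperative
  phase within the horizon, others are invaded and settle with a small
  cooperative minority — so establishment times are summarised over the
  runs that do establish.
* `stable_diffusion_fraction()` calls a run's deceiving trait "stably
  diffusing" when it recurrently establishes itself: at least two
  episodes above a 0.1 fraction after tick 500, or one persistent episode
  covering at least half the remaining horizon (a never-ending invasion
  is the limiting case of recurrence). The episode criterion is a
  declared operational proxy; the behaviour it formalises is the repeated
  release-and-decay cycles seen in the corruption experiments.

## The bilinear diffusion model and its fitting

For m behaviour-group fractions \(s_k\) the compartment model is

\[\dot s_k = \sum_j \beta_{jk}\, s_j + \sum_{i \le j} \mu_{ijk}\, s_i s_j,\]

with spontaneous per-capita rates β and meeting-driven rates μ — the
same bilinear structure as SIR-type contagion models, with the strategy ×
deception behaviour groups as compartments. Given a run's time series,
the design matrix F holds the m fractions and their m(m+1)/2 distinct
pairwise products (lexicographic order), and the coefficient matrix A
solves the least-squares problem \(A = (F^\top F)^{-1} F^\top \dot s\)
per target trait, computed by QR decomposition.

Numerical choices:

* **Derivatives.** Central differences at interior points (one-sided at
  the ends) are the default; a `"forward"` option returns the raw
  increments \(s_{t+1} - s_t\), which are the *exact* derivatives of the
  discrete-time process and of the forward-Euler synthetic generator.
  Parameter-recovery tests use forward differences for this reason;
  fits to simulation output use the default.
* **Rank deficiency is structural, not exceptional.** When fractions sum
  to one at every tick, each linear column equals the sum of its product
  columns, so F can never have full column rank on on-simplex data (and
  near-extinct compartments zero further columns). `fit_rates()` then
  returns the minimum-norm least-squares solution via SVD with a warning.
  Individual rate coefficients are only identified up to the null space
  of F; the predicted derivative field \(E = F A\), the reconstruction,
  and all conservation diagnostics are invariant to that choice.
* **Conservation as a model check.** Because the observed derivative rows
  sum to zero, their least-squares projection does too, so integrating
  \(E\) from the initial census conserves the total fraction to numerical
  precision; `reconstruct_and_check()` reports the number of stable
  decimal places. Gross violations would indicate a broken design or
  derivative convention, not statistical misfit.
* **Decay transients.** `fit_decay()` estimates exponential decay rates
  of single-trait episodes by log-linear least squares, as a control
  comparison for the post-bloom decay of deceiver populations.

`generate_synthetic_series()` integrates a known rate matrix by forward
Euler (erroring with the offending tick if a trajectory leaves [0, 1])
and optionally adds Gaussian observation noise; it is the recovery oracle
for the fitting stack.

## Information-theoretic measures

The library layer provides the quantitative machinery the deception
classes are defined against: Shannon capacity \(C = W \log_2(1 + S/N)\)
(Degradation raises N; Denial sends W → 0), information content
\(I(m) = -\log_2 p(m)\), compression-based difference/similarity
\(D(X,Y) = (K(XY) - \min(K(X),K(Y))) / \max(K(X),K(Y))\), \(S = 1 - D\)
(with gzip at maximum level as the default size function K — results are
compressor-relative, so tests assert orderings and tolerances, not exact
values), Kullback–Leibler divergence and mutual information in bits
(with the standard 0·log(0/q) = 0 convention). The similarity measure is
the quantitative face of Corruption — a successful corruption is a false
message maximally similar to a real one — but the discrete memory
rewrite, not the similarity score, is what the simulation executes.

## What the synthetic generator emulates, and what it does not

The simulator emulates a small, fully engaged population (the scale of a
highly engaged social-media discussion group) in which popularity of a
behaviour translates into reproduction. It does not model network
topology, variable population size, identity or reputation tracking,
victim detection of failed deception, compound or chained attacks, or
cost-dependent deception effectiveness. Passing tests therefore show
that the deception operators, cost accounting and evolutionary dynamics
behave as specified under random mixing — not that the quantitative cost
thresholds transfer to structured real-world networks.

Two calibration facts shape how results should be read. Runs at a given
cost are *bimodal*: replicate averages smooth over runs that stay
cooperative and runs that are invaded, so per-run outcome measures
(collapse tick, establishment tick, diffusion episodes) are summarised
with their supports, not just their means. And deceiver re-emergence
after a bust is mutation-limited (it requires the joint
exploitative-strategy × deception genotype), which makes recurrence
measures noisier at high cost than their replicate-averaged appearance
suggests.

## Problem sizes

The shipped experiment protocols use the full study conditions:
population 50, 5001 generations, 30 replicates per condition, six
degradation costs (0.05–0.3) and thirteen corruption costs (0–1.2). The
compiled engine runs a full 5001-generation simulation in well under a
second, so the complete acceptance battery (about 700 runs) completes in
a few minutes on one core. Unit tests use reduced populations (10) and
horizons (tens to hundreds of ticks) except where a protocol is being
reproduced end-to-end.

## Known limitations

* The match length and mutation probability of the original study are
  not recoverable from its description; the defaults here were fixed
  once, by the qualitative-regime argument above, and all quantitative
  outcomes are conditional on them.
* Score-proportional parent selection with cumulative scores makes
  selection intensity grow slowly over a run as score spreads widen;
  this is faithful to the cumulative-fitness design but means early and
  late invasions are not exchangeable.
* With 50 agents, census fractions move in steps of 0.02; spectral and
  trend diagnostics on 500-tick windows are correspondingly coarse.
* The equilibrium classifier's thresholds (0.05/0.95 levels, ratio 3,
  500-tick windows) are operational choices; labels near a boundary
  should be read with their underlying fractions.
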