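---
title: "Evolving compact control rules for random Boolean networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving compact control rules for random Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbncontrol)
```

## The control problem

NK random Boolean networks are minimal models of gene-regulatory dynamics:
N binary nodes, each wired to K randomly chosen input nodes (self-loops
allowed) and equipped with a random Boolean function.  Under synchronous
updating every trajectory eventually enters a *state cycle* — an attractor —
and the `2^N` states partition into basins of attraction.  The control
question this package addresses is: from an arbitrary state, steer the
network into a *chosen* target attractor using single-bit interventions,
where after every intervention the network immediately performs one natural
update of its own.

A controller here is a set of ternary condition–action rules.  A condition
is a string over `{0, 1, #}` matched against the network state (node 1 is
the leftmost character, `#` matches either bit); the action is the index of
the node to flip, with action 0 meaning "leave the network alone".  Because
of the wildcards a handful of rules can cover large regions of the state
space — typically far fewer rules than states.

```{r motif}
xor <- motifNetwork("XOR")
mapStateSpace(xor)
```

The 3-node XOR ring above is the worked example used throughout the tests:
it has a fixed point `000` (basin 2) and a 3-cycle (basin 6), and a single
bit flip suffices to move between the basins in either direction.

## The learning system

Rules are discovered by an accuracy-based learning classifier system of the
XCS family, built on the standard Butz–Wilson algorithmic skeleton: a
population of at most `popSize` micro-classifiers, match sets, a
fitness-weighted prediction array, action sets, Widrow–Hoff reinforcement
updates with the two-tier (MAM) startup rule, accuracy-based fitness, a
niche genetic algorithm with two-point crossover and subsumption, and
roulette deletion.  Three design points deserve explicit mention.

**Reward.**  The environment pays
`1000 * (steps - interventions) / steps` when the trial reaches the target
and 0 otherwise, where the reinforcement program's step counter increments
once per reward calculation — once per decision cycle, i.e. per natural
update.  The reward is thus 1000 for a trial controlled without
intervention, spans the whole `[0, 1000]` range (a trial whose every cycle
intervened earns 0), and decreases with the fraction of cycles that
intervened.  Two counters coexist deliberately: the *reported* step
statistic (the AS column of the results table) counts interventions *and*
natural updates — a non-zero action contributes 2 such steps — while the
reward denominator uses decision cycles only.  Folding interventions into
the reward denominator would bound every successful payoff below by 500
and neuter the action chooser's 500 threshold.  Because the same rule
participates in action chains of different lengths, its payoff fluctuates;
the accuracy parameters below are deliberately tolerant of that
fluctuation.

**Action selection.**  During learning the chooser is deterministic rather
than probabilistic: if the best entry of the prediction array exceeds 500
the system exploits (takes the argmax, ties to the smallest action index),
otherwise it explores uniformly among the represented actions; exactly 500
explores.  Evaluation always uses the greedy mode.  The probabilistic
`pExplore` chooser of standard XCS is recorded in the parameter set but not
implemented.

**Covering.**  Covering fires while the match set represents fewer than
`thetaMna` *distinct actions* (not fewer than `thetaMna` rules): the
default `thetaMna = 6` equals the number of actions for a 5-node network,
and each covering rule deliberately picks an action not yet present.

### Parameters

`xcsParams()` carries the full ledger with the tuned defaults used for the
N = 5, K = 2 experiments: `popSize = 790`, `gamma = 0.76`, `thetaMna = 6`,
`pHash = 0.4`, `predictionInit = 7.4`, `errorInit = 1.0`,
`fitnessInit = 0.03`, `eps0 = 18.5`, `thetaGa = 260`, `thetaDel = 32`,
`beta = 0.01`, `alpha = 0.087`, `nu = 0.01`, `chi = 0.711`, `mu = 0.263`,
`delta = 0.05`, `thetaSub = 31.579`, both subsumption flags on.  The
combination of a large error threshold `eps0` with a nearly flat accuracy
power law (`alpha = 0.087`, `nu = 0.01`) keeps classifiers whose payoff
fluctuates across action chains reproducible instead of driving their
accuracy to zero.

### Numerical choices

Several details are underdetermined by the standard descriptions; the
package fixes them as follows and keeps them covered by tests:

* Truth-table row indexing reads a node's input bits in stored order, first
  input as the most significant bit.  Any fixed convention works; this one
  is documented in `booleanNetwork()`.
* In the reinforcement update the prediction error moves towards
  `|P - p|` computed with the *pre-update* prediction, and fitness uses a
  plain rate-`beta` update (no MAM), per the Wilson scheme.
* GA children inherit the *mean* of the parents' prediction, error and
  fitness (no additional fitness discount) and their own parent's
  action-set-size estimate; they are absorbed by an experienced, accurate,
  strictly-more-general parent when GA subsumption is on.
* "More general" is strict: more `#` symbols and literal agreement
  elsewhere, same action.  Identical conditions never subsume; duplicate
  insertions merge numerosities instead.
* A trial truncated at `maxSteps` performs a terminal-style update of the
  current action set with payoff target 0 (plus the usual GA trigger
  check), so unsuccessful chains receive the zero signal.
* Start states inside the target cycle are excluded from training sampling
  and from evaluation averages (a zero-step trial would make the reward
  undefined).
* `maxSteps` defaults to 100 — generous for 32-state networks, where
  controlled trajectories need well under 20 steps.
* Training counts *trials*, evaluating after `minTrials = 250,000` and
  every `evalInterval = 10,000` thereafter, and stops at the first
  evaluation that reaches the target from every start state.
* All randomness flows through R's RNG, including inside the compiled
  trial loop, so `set.seed()` fully determines a run.

## Rule compression

A trained population controls the network but is far larger than necessary.
`compactRuleset()` implements Wilson-style compaction: sort
macroclassifiers by numerosity (ties by fitness, prediction, condition,
action — a deterministic chain, since the sources are silent on ties), then
evaluate every prefix of the sorted list as a standalone greedy controller.
Among the prefixes that reach the target from *every* start state, the one
with the minimum average number of interventions is returned, ties to the
smaller prefix.  Note the selected set minimises interventions, not size:
when a deep prefix shaves the average intervention count, the reported
compact set can be much larger than the smallest covering prefix — the same
mechanism that occasionally produces very large compact sets in practice.

## A worked run

```{r worked, eval = FALSE}
set.seed(1)
net <- generateRandomNetwork(5, 2)
ss <- mapStateSpace(net)
target <- selectTarget(ss, "smallest_basin")
task <- controlTask(net, target)
training <- runTraining(task, xcsParams())     # 250,000 trials
compact <- compactRuleset(training$population, task)
compact
```

The chunk above is the full published protocol for one run (a few seconds
of compute); `runExperiment()` wraps it for several networks and runs and
writes the `Net / Run / CR / AS / AI / Time` results table, where CR is the
compact rule count, AS the average steps and AI the average interventions
over all start states.

## What the generator emulates — and what it does not

The synthetic networks are exactly the study conditions: uniform random
wiring with K distinct inputs per node (self-loops allowed, no rejection
beyond requiring at least two attractors for control experiments) and
uniform random truth tables, simulated synchronously.  Real gene-regulatory
networks differ in ways the model deliberately ignores: biased or canalyzing
update functions, heterogeneous in-degree, asynchronous or probabilistic
updating, and states that are not directly observable or writable.  Passing
tests therefore demonstrate that the learning system controls *synchronous
NK dynamics at desk scale*; they say nothing about robustness to noisy or
partially observable dynamics.

## Problem sizes used by the test suite

The unit tests run on the 3-node motifs and on random networks with up to
10 nodes, with shortened training schedules (hundreds of trials on the
8-state motifs, where coverage is reached almost immediately).  The
acceptance suite additionally runs the full-scale protocol — five
independent 250,000-trial trainings on a generated 5-node network — which
completes in well under a minute of CPU time.  Exhaustive state-space
mapping is guarded at N ≤ 24 simply because `2^N` successor entries must be
enumerated.

## Known limitations

* Overgeneral `#####` rules with high numerosity dominate many trained
  populations; they do not prevent control, but they dilute the numerosity
  ordering that compression relies on, which is why the compact-set size
  varies considerably between runs.
* Exhaustive enumeration appears in three places (state-space mapping,
  evaluation from every start state, prefix search), limiting the approach
  to desk-scale networks.
* Only one bit may be flipped per intervention, every node is controllable,
  and the network itself is static; multi-bit actions, restricted control
  nodes and dynamic topologies are out of scope.
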