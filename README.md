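# rbncontrol

Evolving compact control rules for NK random Boolean networks with an XCS
learning classifier system.

## The problem

NK random Boolean networks — N binary nodes, each updated synchronously by a
random Boolean function of K randomly wired inputs — are minimal models of
gene-regulatory and other complex-system dynamics.  Every trajectory falls
into an attractor (a repeating state cycle), and the `2^N` states partition
into basins of attraction.  Practitioners studying network controllability
ask: *from an arbitrary state, how do we steer the system into a chosen
target attractor using minimal interventions*, when each intervention may
flip only a single node and the network immediately takes a step of its own
dynamics afterwards?

`rbncontrol` answers this with *learned* controllers: sets of ternary
condition–action rules

```
condition ∈ {0,1,#}^N  :  action ∈ {0,1,…,N}
```

where the condition is matched against the network state bit string (`#` is
a wildcard), the action names the node to flip (0 = do nothing), and the
rule set is discovered from scratch by an accuracy-based learning classifier
system (XCS): reinforcement learning estimates each rule's discounted payoff
`P = r + γ·max(prediction array)`, a niche genetic algorithm with
subsumption discovers generalisations, and the environment pays

```
r = 1000 · (steps − interventions) / steps
```

on reaching the target (counting one step per decision cycle), 0 otherwise.
A trained population is then compressed by numerosity-ordered prefix search
into a compact rule set — typically far fewer rules than states — that still
reaches the target from every start state with the minimum average number of
interventions.

The package provides the network generator/simulator and exhaustive
state-space analysis (attractors, basins, DOT export), the full XCS engine
(compiled, seeded through R's RNG), the control environment and training
loop, the rule-compression step, and a reproducible experiment runner with a
small command line front end (`inst/scripts/rbnctl.R`).

## A worked example

```r
library(rbncontrol)

set.seed(1)
net <- generateRandomNetwork(5, 2)      # N = 5, K = 2
ss  <- mapStateSpace(net)
ss
#> State space of a 5-node network: 32 states, 3 attractor(s)
#>   attractor 1: {00001}  basin size 26
#>   attractor 2: {00100}  basin size 4
#>   attractor 3: {01000}  basin size 2

task <- controlTask(net, selectTarget(ss, "smallest_basin"))

set.seed(99)
training <- runTraining(task, xcsParams())   # 250,000+ learning trials
training
#> XCS training: 260000 trials, state space covered
#>   last checkpoint: trial 260000, avg steps 6.065, avg interventions 3.032
#>   population: 48 macro / 790 micro classifiers

compact <- compactRuleset(training$population, task)
compact
#> Compact rule set: 10 rules (CR), avg steps 5.935 (AS), avg interventions 2.968 (AI)
compact$ruleset
#> XCS population: 10 macroclassifiers, 661 micro-classifiers
#> top rules by numerosity:
#>   ##### : 4  [91.85/1.0000]  num=117 exp=429812
#>   ##### : 1  [112.13/1.0000]  num=114 exp=428288
#>   ##### : 5  [117.45/0.9999]  num=111 exp=430153
#>   ...
```

Reading the numbers: the hardest target (the attractor `01000`, basin of
only 2 of the 32 states) is reachable from **every** start state using just
**10** ternary rules (CR); controlled trajectories take on average 5.9
counted steps (AS, interventions + natural updates) and 3.0 bit-flip
interventions (AI).  Rules are written as `condition : action
[prediction/fitness]`; high-numerosity wildcard rules carry the broad
policy, specific rules handle the exceptions.  The same pipeline for
several networks × runs, with per-run artifacts and a `Net/Run/CR/AS/AI/
Time` results table, is available as `runExperiment(experimentConfig(...))`
or from the shell via

```sh
Rscript inst/scripts/rbnctl.R experiment --n 5 --k 2 --runs 5 --seed 1 --out-dir results/
```

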