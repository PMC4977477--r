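# foldprm

Roadmap models of protein folding landscapes, with adaptive, locality-aware
selection of roadmap connection methods.

## The problem

Probabilistic Roadmap Methods (PRMs) model a protein's folding landscape by
sampling conformations of a φ/ψ torsional chain, connecting neighboring
conformations with energetically weighted transitions, and extracting folding
pathways as minimum-weight routes from unfolded states to the native state.
Most of the compute goes into the *connection* phase, and the right
connection method — the pairing of a neighbor-selection distance metric with
a local planner — varies not only between proteins but between *regions of
the same landscape*. `foldprm` implements **Adaptive Neighbor Connection**:
an Exp3-style multi-armed bandit that learns which connection method to use,
either from run-wide history (**ANC-global**) or from the history recorded in
the local neighborhood of each query conformation (**ANC-local**), alongside
the fixed single-metric baselines (Euclidean, rigidity-cluster, lRMSD).

It is aimed at people studying folding mechanisms (e.g. secondary-structure
formation order) with coarse-grained sampling-based models, and at motion
planning researchers who want a compact, fully testable reference
implementation of localized bandit method selection.

## The model in brief

* **Protein model.** Six atoms per residue (N, H, CA, CB, C, O); only φ/ψ
  torsions move. A conformation with non-bonded atoms closer than 2.4 Å
  (sampling) or 1.0 Å (connecting) is infeasible; otherwise

  U<sub>tot</sub> = Σ<sub>constraints</sub> K<sub>d</sub>{[(d<sub>i</sub> − d<sub>0</sub>)² + d<sub>c</sub>²]<sup>1/2</sup> − d<sub>c</sub>} + E<sub>hp</sub>,

  with K<sub>d</sub> = 100 kJ/mol, d<sub>0</sub> = d<sub>c</sub> = 2 Å,
  constraints = backbone bonds plus native hydrogen bonds, and
  E<sub>hp</sub> a step-function hydrophobic contact term.
* **Sampling.** Iterative perturbation from the native state, biased toward
  flexible torsions by a rigid-cluster decomposition; a proposal with energy
  E is kept with probability 1 below E<sub>min</sub> (the open-chain
  energy), linearly decaying to 0 at E<sub>max</sub> = 2 E<sub>min</sub>.
* **Connection.** Straight-line torsional interpolation between k-closest
  neighbors; each direction of an edge is weighted Σ −log P<sub>i</sub>
  with P<sub>i</sub> = e<sup>−ΔE/kT</sup> for uphill steps and 1 otherwise,
  so Dijkstra on edge weights extracts maximum-probability folding paths.
* **Learning.** Each method keeps an exponential weight w<sub>i</sub>;
  selection mixes normalized weights with uniform exploration
  (p\*<sub>i</sub> = (1−γ) w<sub>i</sub>/Σw + γ/m), successful attempts are
  rewarded by where their edge weight falls between the best/worst seen
  (x = α + (1−α)(1 − (y−min y)/(max y−min y))), weights update by
  w ← w·exp(γ x\*/m) with the importance-weighted reward x\* = x/p\*, and
  the final selection probability divides by each method's average
  energy-call cost. ANC-local re-derives these probabilities per query by
  chronologically replaying the 40 nearest recorded attempts.
* **Analysis.** Unfolded states (top energy decile), shortest folding
  pathways, secondary-structure formation order (SSFO) per pathway, the
  30-point SSFO stability stopping rule, pathway quality
  (Σ edge weight × pathway dominance), and per-method usage/success/cost
  reports.

## Worked example

```r
library(foldprm)
topo <- make_toy_protein(14, plan = "two-helix", seed = 1)
fit <- prm_fold(topo, strategy = "anc-local", batch = 15, max_batches = 6,
                seed = 2)
summary(fit)
```

```
Folding roadmap (strategy: anc-local)
  32 nodes, 860 directed edges, 430 attempts, 2 batch(es), stable
  4 folding pathway(s); pathway quality 0
  dominant formation order: H1>H2 (100.0% of pathways)
  node energy: min 632.3, median 712.7, max 840.9 kJ/mol
  E_min (open chain) 6786, E_max 1.357e+04 kJ/mol

Per-method report:
     method attempts successes success_rate usage_pct total_cost
1   cluster      130       130            1      30.2        807
2 euclidean      179       179            1      41.6       1013
3     lrmsd      121       121            1      28.1        668
```

The build stabilized after two batches (the SSFO distribution moved by no
more than 30 points), every extracted pathway forms helix H1 before H2, and
the pathway quality of 0 means the minimum-weight routes from the unfolded
ensemble to native are energetically downhill throughout. The usage split
shows the local learner exercising all three connection methods, with the
per-method energy-call cost that feeds its cost-adjusted selection rule.

`plot(fit)` draws the usage breakdown and the energy profile of the best
pathway. A thin CLI over the same functions lives in
`inst/scripts/foldprm.R` (`fixtures`, `sample`, `run`, `analyze`,
`report` subcommands, YAML run configs).

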