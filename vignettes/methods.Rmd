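---
title: "Methods: roadmap construction and adaptive connection learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: roadmap construction and adaptive connection learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(foldprm)
```

This vignette is the package's own account of its model, its tunable
parameters, the design choices that were genuinely open, and what the test
suite does and does not demonstrate.

## The protein model and its assumptions

A protein of $n$ residues is a torsional linkage: bond lengths and angles
are ideal constants, the peptide bond is held trans, and only the $2n$
backbone dihedrals $(\phi_i, \psi_i)$ move. Each residue contributes six
atoms — N, H, CA, CB, C, O, with glycine carrying an HA marker in the CB
slot. The six-atom identity is a modelling choice of this package: the
standard backbone plus one side-chain marker is the smallest set that
supports steric checks, hydrogen-bond constraints and a hydrophobic contact
term. Coordinates are realized by sequential internal-coordinate placement
from a canonical frame (first N at the origin, first CA on $+x$, first C in
the $xy$-plane), so identical torsions give bitwise-identical coordinates
and plain coordinate RMSD between realizations is only meaningful after
superposition (`lrmsd`). The first residue has no $\phi$ and the last no
$\psi$; both store the placeholder 180° and are excluded from perturbation.

The potential is Gō-like: every constraint of current length $d$
contributes $K_d\{[(d-d_0)^2+d_c^2]^{1/2}-d_c\}$ with $K_d = 100$ kJ/mol
and $d_0 = d_c = 2$ Å, plus a hydrophobic term. Constraints are the
backbone chain bonds together with the native hydrogen bonds, detected once
on the native structure as carbonyl-O/amide-N pairs within 3.5 Å at
sequence separation $\ge 3$ inside annotated segments. Because bonds are
rigid in torsion space, the backbone constraints contribute a constant
offset; they are retained because the open-chain reference energy
$E_{\min}$ absorbs the same offset. The hydrophobic term is a step contact
potential: $-1$ kJ/mol (configurable) for every hydrophobic residue pair
with sequence separation $\ge 3$ whose CB atoms lie within 6 Å. A
continuous distance dependence would be equally defensible; the step form
is the simplest term that preserves the role of hydrophobic collapse in
the energy ranking.

Feasibility is a phase-dependent steric rule: non-exempt atom pairs must be
at least 2.4 Å apart during sampling and 1.0 Å during connection. Exempt
are pairs within three covalent bonds and all amide-H/carbonyl-O pairs. The
H–O exemption is deliberate: in an ideal α-helix the backbone hydrogen
bonds place H$\cdots$O near 2 Å, which the constraint term treats as the
*stabilizing* native contact; without the exemption every well-formed helix
would be rejected as clashing.

## Sampling and rigidity bias

Samples grow as a tree rooted at the native state: a parent is drawn
uniformly from the accepted set, a small torsion subset (10 % of the
torsions by default) is displaced uniformly within
$\pm$`perturb_magnitude` (30° default), and the proposal is kept with
probability 1 if $E < E_{\min}$, $(E_{\max}-E)/(E_{\max}-E_{\min})$ on
$(E_{\min}, E_{\max}]$, and 0 above, where $E_{\min}$ is the open-chain
(all-trans) energy and $E_{\max} = 2E_{\min}$. The ramp's boundary at
$E = E_{\min}$ is assigned probability 1 by continuity from below; the
branch structure leaves it formally uncovered.

Perturbation indices are weighted by a rigidity analysis of the parent: the
package uses a simplified rigid-cluster decomposition — connected
components over the $2n$ torsion units, with edges joining the $\phi/\psi$
units of residues coupled by a currently satisfied hydrogen bond (within
110 % of native length) and chaining consecutive in-segment residues that
both participate in satisfied bonds. Units outside any nontrivial cluster
are "flexible" and carry 4× the sampling weight of rigid units (falling
back to uniform when the distinction vanishes). This stands in for a full
pebble-game rigidity analysis; the downstream consumers (the cluster
distance metric and the perturbation bias) only need a cluster partition,
and the interface accepts a drop-in exact decomposition. The torsion-level
(2n) index domain is an interpretational choice: the cluster metric's
summation bound names $2n$ even where prose says "residues", and torsion
units are what perturbation biasing needs.

## Connection, edge weights and pathways

Connections are attempted to the $k = 20$ nearest prior nodes under the
chosen metric, by straight-line interpolation along the minimal angular
path with at most 5° per-torsion steps (fine enough for steric screening on
chains of this size while keeping each attempt at a few dozen energy
calls). Each attempt yields two directed weights
$\sum_i -\log P_i$ with $P_i = e^{-\Delta E_i / kT}$ for uphill steps and 1
otherwise; $kT$ defaults to 1 in reduced units (the temperature is a free
parameter of the model, not calibrated to Kelvin). Both directions are
stored because folding paths are extracted directionally, from unfolded
states to native; an infeasible intermediate fails the attempt and no edge
is added. Endpoint energies are cached on the nodes, so the recorded
attempt cost — the currency of the learner — counts only fresh energy
evaluations.

"Unfolded" is not observable in this model; the package operationalizes
the unfolded ensemble as the top energy decile of roadmap nodes (minimum
one node, quantile configurable). Pathways are Dijkstra shortest paths on
the $-\log$ weights (through igraph), which is exactly the
maximum-probability path under the step-probability model.

## The learners

Three connection methods compete: k-closest under torsional Euclidean
distance, under the rigidity-cluster distance, and under least RMSD.
Selection is an Exp3-style bandit: weights start at 1, the cost-free
probability is $p^*_i = (1-\gamma)\,w_i/\sum_j w_j + \gamma/m$, a
successful attempt with edge weight $y$ earns
$x = \alpha + (1-\alpha)(1 - (y - \min y)/(\max y - \min y))$ (1 when the
extrema coincide, i.e. the first observation), failures and unchosen
methods earn 0, and the chosen weight multiplies by
$e^{\gamma x^*/m}$ with $x^* = x/p^*_i$. The selection actually used
divides by each method's average energy-call cost and renormalizes,
$p_i \propto p^*_i / c_i$; methods never yet attempted are given the
optimistic unit cost so cost adjustment cannot starve exploration. As
printed, the cost-adjusted rule's denominator indexes the numerator's
probability inside the sum over costs, which would cancel the learned
probabilities entirely; the implementation uses the evidently intended
normalization over $p^*_j/c_j$.

ANC-global keeps one state for the whole run. ANC-local keeps *no*
persistent state: for each query it finds the `nf_local` = 40 recorded
attempts whose query nodes are nearest in torsional Euclidean distance,
replays them in chronological order through a fresh state — re-deriving
rewards from the recorded edge weights, with the min/max extrema tracked
over the replayed records only — and samples from the resulting
probabilities. Replay semantics were an open choice (the alternative being
persistent per-region states); replay was chosen because it re-derives the
local picture from the neighborhood store on every call and needs no
landscape partitioning, which is the point of localizing. Ties in method
sampling are resolved by inverse-CDF in method-id order under the run's
seeded RNG, so builds are byte-reproducible.

Defaults $\gamma = 0.1$, $\alpha = 0.5$ are this package's choices (a
mild exploration floor of $\gamma/m$ and a reward floor that still
separates good from bad edges); both are mandatory, explicit parameters of
every experiment. Failed attempts are rewarded 0 but their cost is
counted — the reward formula is defined only for produced edges.

## Stopping rule and analysis

After every batch (15–20 samples by default) the package extracts all
pathways, computes the secondary-structure formation order of each — a
segment "forms" at the first pathway conformation where at least 70 % of
its native hydrogen bonds are within 110 % of native length; never-formed
segments rank last in native order — and compares the resulting
distribution with the previous batch's. The build stops when no ordering
moves by more than 30 percentage points ("more than": a change of exactly
30 still counts as stable), comparing successive batches only. A
constant-distribution run therefore terminates at the second batch. Quality
is reported as $\sum_e w_e \cdot d_e$ over edges, with $d_e$ the number of
extracted pathways traversing $e$; lower is better, and 0 means every
pathway is downhill throughout.

## What the synthetic fixtures emulate

`make_toy_protein` builds 4–40-residue chains whose native torsions are
Ramachandran ideals per declared segment (helix $-57/-47$, strand
$-119/113$), with seeded-random loops re-drawn until the native is
clash-free. It emulates the *structure* of the real inputs — annotated
segments, native hydrogen bonds, hydrophobic patterns, a clash-free native
with a large energy gap to the open chain — but not their scale (real
benchmark proteins run 52–114 residues), their sequence diversity, or
non-ideal native geometry. `make_two_region_bench` is a mock connection
environment: two regions of torsion space with mirrored method success
profiles (0.9/0.1), region imbalance 70/30 so that the globally best
method is the wrong choice in the minority region, unit costs, and edge
weights uniform on [1, 2]. It isolates the locality phenomenon from
molecular detail. Passing tests on these fixtures demonstrate the
correctness of the machinery and the locality mechanism, not quantitative
agreement with any particular protein's folding behaviour.

## Numerical choices and degenerate inputs

Angles live in $(-180, 180]$ and all angle differences are taken on the
circle (a plain difference would make 359° and 1° distant). Infeasibility
is an $+\infty$ energy sentinel, not an exception, so acceptance
probabilities and transition probabilities degrade to 0 arithmetically.
Degenerate cases are defined, not errored: coincident endpoints
interpolate to a two-row path with no interior points; an all-coincident
coordinate set falls back to centred RMSD in `lrmsd`; an all-rigid or
all-flexible rigidity map falls back to uniform perturbation weights; an
empty attempt history yields uniform method selection; tied dominant
orderings resolve lexicographically with a warning. The stationary
extrema case $\min y = \max y$ rewards 1 (the edge is the best seen).

## Problem sizes used in the tests

The suite exercises 4–14-residue chains, 200-candidate neighbor queries,
500 random graphs of up to 8 nodes against exhaustive path enumeration,
1000-input equation-level comparisons at $10^{-12}$ relative tolerance, a
10,000-step probability-conservation stream, and 20-seed bench
comparisons (500-step stationary, 300-step two-region). These sizes give
tight statistical checks for the properties tested while keeping the whole
suite around a minute of CPU.

## Known limitations

Side chains beyond the CB marker, bond flexibility, solvent and
electrostatics are out of scope, as are approximate nearest-neighbor
structures (search is exact brute force, which is also why chains are kept
small), kinetic rate estimation, and clustering of pathways beyond exact
formation-order grouping. The rigid-cluster decomposition is a documented
simplification of pebble-game rigidity. PDB round trips are limited by the
format's 0.001 Å coordinate precision (≈0.1° in recovered dihedrals).
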