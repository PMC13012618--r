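---
title: "Models and methods behind allonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind allonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

allonet analyses molecular-dynamics ensembles for allosteric signal
transmission: how binding at one site of a protein (for Hsp70
chaperones, the J-domain of a cochaperone docking at the
NBD–SBD interface) changes correlated motions, contact patterns and a
distal conformational equilibrium (there, the threonine of the
nucleotide pocket approaching the ATP γ-phosphate). This vignette is
the package's own account of the models, the parameters that matter,
the numerical choices, and what the synthetic validation does and does
not demonstrate.

## Trajectory model

A `topology` is an ordered atom table (name, element, residue id,
residue name, chain) with derived flags (backbone, heavy, hydrophobic
residue). Residue numbering is always the source file's numbering —
every residue mentioned in a protocol (T199, D35, R167 …) is meaningful
only in author numbering, so nothing is ever re-indexed. A
`frame_ensemble` is an F × A × 3 array in nm (ps for time); PDB
ångströms are converted at the boundary. Frames are equally weighted.

Superposition is a standard least-squares rigid fit (Kabsch, SVD form)
of a fit selection onto a reference frame; the whole frame is moved,
only the fit selection defines the transform. Degenerate (collinear)
fit sets are rejected. The backbone is N, CA, C, O.

Formats: PDB and GRO for structures, DCD and multi-model PDB for
trajectories. XTC is not supported: no installed reader exists in this
language ecosystem and its lossy compression is a poor match for a
reference implementation; DCD covers the binary-trajectory contract.

## Order parameters

* **Subdomain torsion** — the signed dihedral of four group centres of
  mass, the classic collective variable for nucleotide-binding-domain
  lobe rotation (groups IB, IA, IIA, IIB in the chaperone application).
  Centres of mass are mass-weighted; the protocol phrase "centre of
  mass of the backbone atoms" does not state weighting, and
  mass-weighting matches the behaviour of the standard tooling. With
  near-identical backbone-atom masses the difference is far below the
  degree scale of interest; the choice is flagged here for sensitivity
  testing.
* **Dihedrals** follow the IUPAC sign convention, range (−180°, 180°].
  The implementation is cross-checked in the tests against an
  independent formulation and against bio3d.
* **β-content** — for two strand segments, every pair of 3-residue
  windows whose centres lie within the strands cutoff (1 nm) is scored:
  the 6-residue block (N, CA, CB, C, O per residue) is optimally
  superposed on an idealized antiparallel two-strand template and the
  RMSD r enters s through the rational switch
  (1 − (r/r₀)⁸) / (1 − (r/r₀)¹²), r₀ = 0.08 nm, with the n/m limit
  taken analytically at r = r₀. The template
  (`antiparallel_template()`) is an idealized synthetic construction
  (extended strands, alternating pleat, 0.48 nm separation), pinned in
  code so scores are reproducible; glycine receives a virtual CB built
  tetrahedrally from its backbone. This is a scalar secondary-structure
  variable, not a DSSP replacement.
* **PCA** — eigendecomposition of the 3A × 3A coordinate covariance
  about the ensemble mean (unweighted coordinates), after
  superposition. When two systems are compared, fit the PCA on their
  merged ensemble and project each system with `pca_project()`, so both
  live in one eigenbasis.

## Contacts

Five interaction types with criteria in nm/degrees: hydrogen bond
(donor–acceptor heavy distance ≤ 0.35, ∠D–H···A ≥ 150°), ionic
(≤ 0.40), π-stacking (centroids ≤ 0.70, normals ≤ 30°), π-cation
(≤ 0.60, offset ≤ 60°), hydrophobic (heavy pair within Bondi-radius sum
+ 0.05, both residues in {ALA VAL LEU ILE MET PHE PRO TRP}). Donors are
N/O/S atoms with a geometrically bonded hydrogen (first frame, < 0.12
nm); acceptors are oxygens, hydrogen-free nitrogens and sulfur — a
chemical rule rather than a residue table, so ligands work without
special-casing. Intra-residue contacts and backbone–backbone hydrogen
bonds between sequence neighbours are excluded. Without hydrogens,
hydrogen-bond detection is disabled with a warning rather than guessed.

Frequencies are exact frame fractions; differential tables take the
union of keys (absent = 0) and flag |Δ| > 40 percentage points.
Residue roles use the 50% persistence rule, with *any* contact type
counting towards ligand binding (the protocol does not restrict the
type; this is configurable via the table itself).

## Dynamic network

Nodes: one per residue anchored at Cα owning the residue's heavy atoms;
an ATP-like ligand splits into a purine-ring node (anchored at N1) and
a phosphates+ribose node (anchored at the terminal phosphorus); ions
are single-atom nodes. Edges: minimum heavy-atom distance ≤ 0.45 nm in
≥ 75% of frames. Weights: GC = √(1 − exp(−2I/3)) with I estimated by
the Kraskov k-NN estimator (k = 7, Chebyshev metric) on the two 3-D
anchor-displacement series; for jointly Gaussian motion with
per-dimension correlation ρ this equals |ρ| exactly, which is the basis
of the estimator's validation. The estimator runs in a compiled k-d
tree kernel (brute force is quadratic and dominates runtime
otherwise).

Numerical choices: GC is clipped to [10⁻⁶, 1 − 10⁻¹²] before
d = −log GC. The upper clip keeps distances positive for degenerate
(duplicated) series; the lower floor keeps them finite when the MI
estimate of a physically present but uncorrelated edge clips to zero —
an infinite edge weight would break the k-shortest-paths ranking. A
floored edge has d ≈ 13.8, orders of magnitude above any informative
edge, so routing is unaffected.

Paths: optimal paths via Floyd–Warshall (all-pairs matrix retained for
betweenness reuse); ties resolve deterministically by update order. The
20 suboptimal paths are Yen's k-shortest *simple* paths on the same
distances (igraph), verified in tests against exhaustive enumeration.
Occurrence frequency counts the fraction of the 21-path set containing
each node. Communities: Louvain on GC weights under a fixed seed
(order-dependent heuristic; the seed is part of the configuration),
discarding communities below 1% of nodes. Betweenness: node values are
normalized to the fraction of all pairs routed through the node;
community-pair strength sums the edge betweenness of crossing edges
(normalized to max 1) — whether the original protocol aggregated node
or edge betweenness is not stated, so the node-based variant is
available via `method = "node"`.

The sensitivity scan rebuilds the network over cutoffs 0.42–0.48 nm and
persistences 65–85% (the reference pair must be in the grid) and
reports Jaccard similarity to the reference for edge sets, path-residue
sets and path-connection sets, plus per-node occurrence across the
grid. GC values are cached per node pair across grid points.

## Free energies

WHAM solves iteratively for the unbiased density p(ξ) and window
offsets f<sub>i</sub>, with convergence on max |Δ ln f<sub>i</sub>| <
10⁻⁸ (kT), cap 10⁵ iterations, 100 bins over the sampled range by
default. G = −k<sub>B</sub>T ln p, min-anchored; k<sub>B</sub> =
0.008314 kJ·mol⁻¹·K⁻¹, T = 310 K, reported in both kT and kcal/mol
(4.184 kJ). Windows must overlap pairwise along the reaction
coordinate; the gap is named in the error. Replica-exchange provenance
is ignored at analysis time — samples belong to their bias window, as
WHAM assumes.

Errors: moving-block bootstrap per window with block length
⌈τ<sub>int</sub>⌉, where the integrated autocorrelation time sums
empirical autocorrelations until they drop below 0.05. For AR(1) data
with φ = 0.9 this estimates (1+φ)/(1−φ) = 19, and block bootstrap
errors exceed naive resampling severalfold — the behaviour the tests
pin down. Replicate profiles are re-anchored at the full-profile
minimum bin before taking per-bin standard deviations; `delta_g`
propagates replicate densities. Convergence diagnostics re-solve WHAM
on the first fraction of every window on the full profile's bin grid.

State free-energy differences integrate the unbiased density over the
two intervals (for the chaperone application: a "close" state below
0.4 nm and a "far" state above 0.65 nm along the threonine–γ-phosphate
distance) and are therefore invariant to any constant shift of G.

## Synthetic data: what it emulates, and what it does not

The generators provide every input class with machine-readable ground
truth, so each stage is scored against a known answer without any
external download. All of them require a seed and are bitwise
deterministic under it.

* **Planted-path ensembles**: beads on a serpentine lattice (spacing
  0.38 nm), one Cα-like atom per residue, Gaussian displacements with
  σ = 0.03 nm. The planted chain is the middle lattice column — a
  spatially contiguous 6-node route from the bottom row to the top row,
  so the graph genuinely contains alternative routes through the
  lattice. (A chain of sequence-distant residues, e.g. 5 → 25 in steps
  of 4, cannot form a graph path on a linear chain at all: non-adjacent
  beads share no edge. Folding the lattice is what makes the planted
  path a real routing problem.) Along the chain the per-dimension
  correlation is a first-order Markov structure cov = ρ^|i−j| (ρ = 0.8
  by default), which is always positive definite; off-chain lattice
  neighbours get a weak ρ = 0.05 coupling so the background graph still
  carries informative edges; anything else is independent. σ = 0.03 nm
  keeps lattice contacts above the 75% persistence rule with margin.
* **Planted-partition ensembles**: blocks are compact Fibonacci-sphere
  clusters (radius 0.15 nm) 0.62 nm apart — dense within-block contact
  graphs with a few weak bridge edges — and equicorrelated motion
  (ρ = 0.6) inside each block. An earlier two-row-grid layout let the
  modularity optimum split blocks internally; compact clusters express
  the design intent (blocks are densely connected units).
* **Umbrella datasets**: harmonic-plus-harmonic windows are sampled
  exactly from the closed-form Gaussian; double wells use a Metropolis
  chain (burn-in 1000, thinning 20, step 3·√(kT/k)) whose acceptance
  (≥ 5%) and residual lag-1 autocorrelation (< 0.1) are checked, with
  the quartic well U = h((ξ−m)² − a²)²/a⁴. Window layout defaults to
  ten centres spanning 0.3–1.2 nm with k = 1500 kJ·mol⁻¹·nm⁻².
* **Contact scripts** place minimal residue pairs that satisfy or
  violate exactly one criterion (e.g. a serine hydroxyl donating at
  165° vs 140°), 5 nm apart per entry.

None of this mimics real force-field dynamics, solvent, or actual
chaperone structures; the ensembles are acceptance devices. Passing
tests demonstrate that the estimators recover known statistical
structure at realistic sample sizes — not that any biological claim is
reproduced at desk scale, since the original observations derive from
multi-microsecond all-atom simulations that cannot be regenerated here.

## Validation problem sizes and known limitations

The validation suite uses 5000-frame ensembles for network estimation
(20 realizations for path recovery, 10 for community recovery), 5000
samples per window for harmonic WHAM and 20000 for the double well, and
40 bootstrap replicates — sizes at which every statistical check has
comfortable margin while the whole suite stays in the minutes range on
one CPU.

Known limitations worth keeping in mind:

* The GC null is noisy by construction: at ρ = 0 the √-mapping turns
  small positive MI fluctuations into GC values of up to ≈ 0.1 at
  n = 5000, k = 7 (roughly a third of seeds exceed 0.05). Correlated
  pairs are tight (within 0.05 down to ρ = 0.3). Treat small GC values
  as "no detectable coupling", not as precise zeros.
* The KSG estimator has a mild negative bias at high correlation
  (≈ −0.015 at ρ = 0.95, n = 5000).
* Louvain is a heuristic; only its seeded determinism is guaranteed,
  not global modularity optimality.
* Floyd–Warshall is cubic in nodes — fine for residue-scale networks
  (hundreds of nodes), not for atom-scale graphs.
* WHAM assumes decorrelated samples within windows; correlation is
  handled in the error bars (block bootstrap), not in the point
  estimate.
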