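---
title: "Self-supervised geometric representations for protein stability change prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised geometric representations for protein stability change prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gatddg)
```

## The model

Predicting the free-energy change ΔΔG of a point mutation from structure
suffers from two chronic problems: labelled data are scarce (a few
thousand experimental values) and heavily skewed toward destabilizing
mutations, so supervised models overfit and treat a mutation and its
reversal inconsistently. This package separates the problem into a
representation stage that needs no labels and a small regression stage
that uses them.

The representation stage is a graph attention network over heavy-atom
graphs, pretrained on a pretext task whose labels are free: perturb a
random side chain to a rotamer drawn from a rotamer library, and predict
each perturbed atom's displacement from its native position. Solving
this task requires the encoder to internalize local packing — which
conformations are sterically and statistically plausible given the
neighborhood — which is exactly the signal a stability predictor needs.
The regression stage pools the per-atom representations of the mutated
residue and its environment, in both the wild-type and mutant structures,
and feeds the standardized, concatenated blocks to a ten-fold ensemble
of gradient-boosted trees.

Anti-symmetry is addressed structurally rather than as an afterthought:
every training record is paired with its inverse (labels negated), and
the inverse row's features are the direct row's features with the
wild-type and mutant block groups swapped. A model trained on such a
balanced set, with features whose swap symmetry is exact, concentrates
the paired prediction sums near zero; the bias metrics
r^{d−i} and ⟨δ⟩ quantify this on held-out pairs.

## Parameters that matter

* **Graph radius, 12.0 Å** (strict `<`), around the heavy-atom centroid
  of the perturbed/mutated residue, with whole-residue retention: a
  residue contributes all atoms when any atom is inside. The centroid
  choice (rather than Cα) is a design decision; both are defensible and
  the radius dominates.
* **Edge cutoff, 3.0 Å** (strict `<`): covalent bonds plus tight
  contacts/H-bond distances. Edges carry no attributes.
* **Node attributes, 36 components** in a frozen layout (element 4,
  residue type 20 — alphabetical one-letter order, ss8 8 in the order
  H,B,E,G,I,T,S,-, perturbed flag 2, SASA>0, is-Cα). The perturbed flag
  marks *all* atoms of the perturbed residue — the only reading that
  also covers the GLY/ALA identity perturbations — with a
  `flag_moving_only` switch for the narrower convention.
* **Encoder**: 4 layers × 8 heads, LeakyReLU slope 0.2 in the logits,
  ELU activations, mandatory self-loops (so isolated atoms attend to
  themselves and softmax is always defined). Per-head width defaults to
  16 (layer width 128); the published description fixes layers and heads
  but not per-head width, so it is configurable. The displacement head
  is an MLP (input→128→64→1, ReLU). Adam, batch 128 (variable-size
  graphs are batched as disjoint unions — gradients averaged per graph),
  learning rate 0.001, fixed epochs with a best-validation checkpoint.
* **Regressor grid**: the full search space is
  n_estimators {10000, 20000, 30000} × max_depth {5,6,7} ×
  subsample {0.6,0.7,0.8} × colsample_bytree {0.55,0.56,0.57} ×
  learning_rate {0.02,0.05,0.1}, selected by mean validation PCC
  ("highest performance" is otherwise unspecified; RMSE selection is a
  config option). The desk-scale default is the reduced grid
  n_estimators {200,500} × max_depth {5,6} at subsample 0.7,
  colsample 0.56, learning_rate 0.1, with early stopping capped at
  n_estimators.

## The self-supervision engine

χ angles follow the IUPAC quadruples; re-posing rotates, for each χ in
order, the atoms distal to the rotation axis, so backbone and Cβ never
move and intra-side-chain geometry is preserved exactly. The
displacement label is the per-atom Euclidean distance between original
and perturbed positions — for a single atom the "RMSD" of one position
pair reduces to exactly this, which resolves the per-atom vs per-residue
ambiguity in favour of the per-atom reading that the loss indexing
implies. Residues are drawn uniformly with replacement among χ-bearing
residues; prolines are excluded by default because the χ rotation breaks
the pyrrolidine ring closure (a config switch admits them, flagged).

The shipped rotamer table is compact and backbone-independent (1–3
rotamers per residue, means/σ in degrees, probabilities normalized to 1);
a loader accepts full backbone-dependent Dunbrack-format files, keyed by
10° (φ,ψ) bins with nearest-bin lookup, for fidelity runs. The compact
table removes any mandatory download while keeping the sampling
machinery identical.

## Annotations

Secondary structure is a reduced Kabsch–Sander assigner: ideal amide
hydrogens (1 Å from N, anti-parallel to the preceding C=O), the classic
electrostatic H-bond energy with the −0.5 kcal/mol threshold, n→n+4
repeats → H, n→n+3 → G, n→n+5 → I, bridge patterns → B and ladders → E,
H-bonded turns → T, Cα curvature above 70° → S. Overlap resolution uses
the priority H > E > B > G > I > T > S > '-' — a choice, since the
original assigner's tie-breaking is not fully specified; a per-residue
label file can override the assigner entirely, and only the 8-way
one-hot ever reaches the encoder, so bit-exact DSSP parity is not
required.

SASA is Shrake–Rupley with element vdW radii C 1.70, N 1.55, O 1.52,
S 1.80 Å, probe 1.4 Å, and a deterministic generalized-spiral lattice
(default 100 points/atom). The lattice is laid out in the molecule's
principal-axis frame with axis orientations fixed by each axis's extreme
projection, so SASA — and every node attribute derived from it — is
invariant under rigid rotation and translation rather than merely
approximately so. Only the SASA>0 bit enters the encoding, so quadrature
resolution affects features only at the buried/exposed boundary.

## Mutant structures

The reference protocol builds mutant and inverse-mutation structures
with an external modelling suite. Here mutants are built by deterministic
template placement: the side chain is rebuilt from idealized internal
coordinates at the library's highest-probability rotamer, backbone
untouched. This keeps the package self-contained and the features exactly
swap-symmetric; externally modelled mutant PDBs can be supplied instead
(`mut_structure=`). Aromatic and fused-ring internal coordinates are
idealized planar polygons; ring closure is exact for six-membered rings
and approximate for tryptophan's fused system — adequate because
downstream features depend on atom identities, contacts and coarse
binary annotations rather than sub-0.1 Å geometry.

## Standardization and featurization choices

Standardization (zero mean, unit variance per feature) is fit on the
training matrix only — the augmented (direct + inverse) set — and
applied frozen to held-out rows; zero-variance features map to 0 with
their indices recorded. The published formula places std(·) per layer
before the final concatenation; since per-column standardization
commutes with concatenation, standardizing the full vector once is
numerically identical and implemented that way (a config-visible note,
not a behavioural difference). At featurization time the mutated
residue's atoms carry the perturbed flag in both graphs so attention is
drawn to the site; `flag_mode = "none"` disables this.

## The synthetic data generator

Real training data (thousands of curated experimental ΔΔG values with
PDB structures) cannot ship with a package. The generator emulates the
*shape* of that data: ideal-geometry peptides (lengths 10–30, alternating
α-helical and extended backbones), random single-point substitutions,
and labels from a declared rule — weighted hydropathy change, volume
change and wild-type burial plus N(0, 0.25 kcal/mol) noise — whose
parameters are returned as ground truth. Geometry-derived features carry
real signal for this rule (residue identity through the one-hot blocks,
burial through the SASA bits), so end-to-end recovery is a meaningful
test of the plumbing. What passing does **not** show: accuracy on real
thermodynamic data, transfer across protein families, or robustness to
experimental structure noise — those require the full-scale pretraining
corpus and experimental benchmarks, which are out of scope here.

Desk-scale study sizes, chosen once: encoder pretraining on 3 fixture
peptides × 50 perturbations for 30 epochs at head width 8; the ΔΔG
pipeline on 10 peptides × 30 mutations (300 direct records, 600
augmented rows) with an 80/20 pair-level hold-out and the reduced grid.

## Numerical and degenerate-input conventions

* Angles in degrees, IUPAC dihedral sign, wrapped to (−180, 180].
* Boundary conventions strict: an atom at exactly 12.0 Å does not
  trigger residue retention; a pair at exactly 3.0 Å is not an edge;
  ΔΔG = 0 classifies as destabilizing; resolution exactly 2.0 Å fails
  the quality filter.
* Chains shorter than 3 residues get all '-' secondary structure.
* An all-GLY/ALA perturbation dataset is rejected as degenerate (its
  loss would be identically the mean squared prediction).
* MCC is defined as 0 when a confusion-table denominator vanishes;
  r^{d−i} requires ≥ 2 pairs; PCC requires non-constant labels.
* Ensemble folds are assigned at pair level so a direct row and its
  deterministic inverse partner can never straddle train/validation —
  the one leakage channel augmentation creates. Protein-level grouping
  is available but not the default.
* Seeds control everything stochastic: rotamer draws, dataset
  generation, encoder initialization and batching, fold assignment and
  tree fitting (single-threaded).

## Known limitations

Single chains and single-point mutations only; no pH/temperature
covariates; no energy-based repacking or clash resolution after
perturbation (the encoder is expected to learn from raw geometry); the
quality filter's sequence-identity criterion is a metadata predicate,
not an alignment; hydrogen atoms exist only implicitly (ideal amide H
inside the H-bond energy). The encoder here is trained at fixture scale —
representations are far weaker than those from a corpus of thousands of
structures, which is why package-level claims are about contracts and
recoverability, not benchmark accuracy.
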