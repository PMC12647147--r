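---
title: "Multi-scale graph transformers for molecular property prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale graph transformers for molecular property prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and its
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, the numerical choices, and the known limitations.

## The model

A molecule enters the model in four coupled views.

**Atom graph.** Heavy atoms are nodes, covalent bonds are edges; hydrogens
are implicit, encoded as per-atom counts rather than graph nodes (standard
in molecular GNNs, and it keeps the node count compact). Every atom carries
a 136-dimensional feature row; `atom_feature_schema()` documents the block
layout: a 100-wide atomic-number one-hot, degree, formal charge, chirality
tag, hybridization, hydrogen count (each one-hot with an "other" slot), and
aromaticity / ring-membership / ring-size flags. The 136- and 39-wide totals
are binding contracts; the block composition within them is this package's
own design.

**Bond graph.** The line graph of the atom graph: each bond becomes a node,
and two bonds are adjacent exactly when they share one atom. Bond features
(39 per bond) cover bond type, conjugation, ring membership and size,
stereo tag, symmetrized end-atom blocks (so the vector is invariant to bond
direction), the bond order, and the 3D bond length measured from the
embedded conformer. Bond-graph coordinates are bond midpoints, which gives
the bond channel a geometry that transforms rigidly with the atom
coordinates.

**3D conformer.** One conformer per molecule, produced by distance-geometry
embedding and refined with the Universal Force Field (MMFF94 is a config
alternative). Embedding is deterministic for a fixed seed. If embedding
fails, the molecule falls back to a planar 2D layout with z = 0 and carries
a per-record flag — pipelines never silently shrink.

**Fingerprint panel.** Eight families are available
(`fp_families()`); defaults are task-dependent: pharmacophore + circular +
path fingerprints for classification, electrotopological-state +
pharmacophore + circular for regression. Real-valued families are z-scored
with training-set statistics; binary families pass through unscaled.

### Encoder

Each graph channel applies `gcn_layers` graph convolutions
$H^{(l+1)} = \sigma(\hat A H^{(l)} W^{(l)})$ with the symmetric
normalization $\hat A = \tilde D^{-1/2}(A+I)\tilde D^{-1/2}$; these replace
positional encodings by baking local topology into the node states. A
learned CLS (graph-representation) row is prepended, and `encoder_blocks`
blocks follow, each alternating:

1. an **equivariant update** (Full variant only): messages
   $m_{ij} = \phi_e(h_i, h_j, \lVert x_i - x_j\rVert^2)$ over graph
   neighbours, feature update $h_i' = h_i + \phi_h(h_i, \sum_j m_{ij})$,
   and coordinate update
   $x_i' = x_i + \frac{1}{|N(i)|}\sum_j \phi_x(m_{ij})(x_j - x_i)$.
   The CLS row is excluded from geometry; isolated nodes keep their
   position. The degree normalization of $\Delta x$ keeps coordinate
   updates bounded on high-degree nodes (a plain sum is available via
   `egnn_agg = "sum"`).
2. **multi-head self-attention** over all rows including CLS:
   per-head weights $\mathrm{softmax}(QK^\top/\sqrt{d_k})$, concatenated
   heads, output projection, residual connection and row-wise layer
   normalization. The residual + layer norm are needed for trainability.
   Attention weights are retained; the final block's CLS row is the
   interpretability surface.

Because hidden states only ever see squared interatomic distances,
predictions are invariant to rigid rotations and translations exactly, and
permutation equivariance of every layer makes the CLS readout invariant to
atom relabeling; the test suite asserts both at 1e-5 (observed ~1e-14).

The channel embeddings (atom CLS, bond CLS, fingerprint FNN) are
concatenated — no gating — and decoded by a two-layer FNN head.
Classification outputs are per-task probabilities; regression outputs are
de-standardized to original units.

### Variants

`make_variant()` builds the ablation family: `GCN` (convolution stack with
mean-pooled readout), `Atom`, `AtomBond`, `FP`, `AtomBondFP`, `Full`
(everything, including the equivariant update), and `Mini` (`Full` minus
the equivariant blocks — architecturally the same as `AtomBondFP`, kept as
its own name because it answers a different question: what the equivariant
update costs, not what fingerprints add).

### Training

Minibatch Adam (lr 1e-3 by default; optimizer and rate are config-exposed
since the architecture source leaves them open) on masked binary
cross-entropy — missing labels are excluded from both the loss and its
normalization, so records with no observed labels contribute exactly
nothing — or MSE on standardized targets. Early stopping watches the
validation metric with patience 20 by default and restores the best epoch;
on a plateaued metric, ties go to the *later* epoch, so training keeps
refining while validation is flat. Training is fully deterministic given
the seed: identical seeds give byte-identical histories.

The network and its reverse-mode differentiation are implemented in plain R
matrices. Every op's backward pass, and the assembled gradients of all six
variants, are verified against central finite differences in the test
suite.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `hidden_dim` | 256 | width of every channel (divisible by heads) |
| `gcn_layers` | 2 | convolutions before the encoder blocks |
| `encoder_blocks` | 3 | equivariant + attention blocks per channel |
| `attention_heads` | 4 | heads in each self-attention layer |
| `dropout` | 0.1 | applied to attention output and FNN hiddens |
| `lr`, `batch_size` | 1e-3, 32 | Adam settings |
| `patience` | 20 | early-stopping patience (epochs) |
| ratio | 8:1:1 | train/validation/test split |

Splits use floor allocation with the remainder to train (100 molecules →
80/10/10). Scaffold splits group molecules by Bemis–Murcko scaffold
(iterative pruning of terminal atoms), sort groups by descending size with
seeded tie-shuffling, and fill train, then validation, then test — the
usual out-of-scaffold generalization protocol. Acyclic molecules form
singleton groups keyed by their own canonical SMILES: lumping them into one
shared empty-scaffold group would move every acyclic molecule into train
and would break the degenerate case where all-distinct scaffolds should
reproduce random-split sizes.

Label-noise experiments reverse exactly `round(rate × |train ∪ val|)`
randomly chosen labelled train/validation records *after* splitting, so the
test partition is provably clean; missing labels are never flipped.

## The synthetic-data generator

`generate_molecules()` draws from a curated grammar — aromatic and
aliphatic ring scaffolds and acyclic backbones with one or two substituent
slots filled from a 31-member pool — so every emitted SMILES is valid by
construction, de-duplicated by canonical form, and deterministic per seed.
Three label modes:

* `motif_classification` — label 1 iff the molecule contains a substructure
  motif (default: a benzene ring), optionally flipped with a noise
  probability. Matching is labeled subgraph isomorphism (element class,
  aromaticity, bond order), so pyridine does not count as benzene.
* `additive_regression` — a fixed per-element contribution table plus
  Gaussian noise; exactly reproducible at zero noise.
* `geometry_regression` — the radius of gyration of the embedded conformer.
  This mode exists specifically to make the equivariant channel's
  contribution testable: the label is a pure function of 3D geometry, which
  topological fingerprints can only approximate through size proxies.

What the generator does *not* emulate: real assay label distributions and
their class imbalance, activity cliffs, large macrocycles or charged
polypharmacology space, measurement error structure, or the scale of public
benchmarks. Passing tests on these fixtures demonstrates that the machinery
learns, ranks, localizes and degrades as designed — not that it reaches any
particular accuracy on external benchmark suites, which require downloaded
datasets and are out of scope here.

## Desk-scale study conditions

The package's self-checks run at sizes chosen to exercise the claims on one
CPU (stated here as the package's own protocol): the motif learning check
fits the Full variant on 500 generated molecules (hidden 32, 2 blocks) and
requires validation ROC-AUC ≥ 0.9 within 30 epochs; the 3D-sensitivity
contrast fits Full and its EGNN-free ablation on 80 geometry-labelled
molecules for 25 epochs (train-to-convergence; both variants were still
improving at 8) over 5 seeds and compares mean test RMSE; the
interpretability check trains the Atom variant on 200 molecules across 5
seeds and compares mean CLS attention on motif versus non-motif atoms over
all held-out motif-bearing molecules. Configuration defaults stay at the
full-scale values (hidden 256, 3 blocks).

## Numerical choices and degenerate inputs

* Adjacency normalization uses the symmetric form
  $\tilde D^{-1/2}(A+I)\tilde D^{-1/2}$, which preserves symmetry and keeps
  row sums at 1 on regular graphs.
* Attention weights exclude V (standard transformer semantics); softmax is
  computed with row-max subtraction; the BCE loss is evaluated in its
  numerically stable logit form.
* A bondless molecule (e.g. methane) yields an empty bond graph; the bond
  channel then attends over the CLS row alone and stays finite. An empty
  atom graph is a contract violation and errors.
* Glorot-uniform initialization; biases and layer-norm offsets start at 0,
  gains at 1; the CLS embedding starts near 0 (sd 0.02); the coordinate
  head is down-scaled at init to keep early geometry updates small.
* Fingerprint z-scoring guards zero-variance columns (sd set to 1);
  regression target scalers likewise.
* Duplicate records keep the first occurrence; conflicting labels among
  duplicates are messaged, never merged.

## Known limitations

* Chirality and E/Z stereo occupy schema blocks but are not perceived from
  input (always "none"); two enantiomers receive identical features apart
  from their 3D coordinates.
* Aromaticity is a simplified Hückel rule (4n+2 over rings of size 3–7
  found from non-bridge edges); exotic fused or charged aromatics may be
  classified differently than by a full perception model.
* One conformer per molecule; no conformer ensembles.
* The electrotopological-state, pharmacophore-pair, atom-pair and torsion
  fingerprints are this package's implementations of the published
  algorithm families, with their atom-typing schemes documented in code;
  bit-level compatibility with other software's versions of these families
  is not a goal.
* Whether the original architecture applies the equivariant update to the
  bond graph is an open question; this package does, using bond-midpoint
  coordinates, which keeps both channels' geometry consistent.
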