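---
title: "Stereochemistry-aware DDI prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereochemistry-aware DDI prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Most drug–drug interaction (DDI) predictors score a pair of molecules from
their 2D bond graphs. Two molecules that differ only in double-bond geometry
(E/Z isomers) have *identical* 2D graphs, so a purely topological model
assigns them identical representations — yet their pharmacology can differ.
`stereoddi` predicts the probability that a drug pair exhibits a given
interaction type from a fused 2D + 3D representation, and its synthetic
benchmark is built so that this failure mode of 2D models is directly
measurable.

The model is a mapping $f : G \times G \times I \to [0,1]$ from a drug pair
and an interaction type to a probability. Training data are positive triples
$(G_x, G_y, r)$; negatives are corrupted triples.

# Architecture

## 2D topological encoder

Atoms are featurised into 55 descriptors (44-symbol one-hot with an
out-of-vocabulary slot, heavy-atom degree, implicit valence, formal charge,
radical electrons, 5-slot hybridisation one-hot, aromatic flag, total
hydrogen count) and bonds into 6 (type one-hot over
single/double/triple/aromatic, conjugation, ring membership). Hydrogens are
implicit: they appear only in the hydrogen-count/valence descriptors, which
keeps the atom count identical between the 2D graph and the 3D conformer.

The trunk is a 4-layer graph-attention network with 2 heads of 32
dimensions (concatenated to $d = 64$), parameters shared across layers,
each layer followed by LayerNorm and ELU; the raw features pass through a
LayerNorm and a linear projection first. Bond features enter the attention
logits as an additive per-edge term, and every node receives a self-loop
with zero edge features so isolated atoms are well-defined. Three readouts
form a hierarchy: the mean of the first layer's node states (atom level)
and two self-attention poolings of the final states at keep-ratios 0.5 and
0.25 (functional-group and scaffold levels), fused by a two-layer
perceptron into a graph summary. The node states $H^{2D}$ feed the fusion
stage; the hierarchical summaries are an exposed diagnostic readout of the
trunk — downstream scoring consumes the pooled, fused node states, so the
pooling branches receive no gradient from the loss.

## 3D spatial encoder

Conformers are generated from SMILES with OpenBabel's 3D builder and
rotation-augmented by Euler angles drawn uniformly from $[0, 2\pi)$,
composed in the documented order $R_z(\alpha) R_y(\beta) R_x(\gamma)$:

$$X_{aug} = R_\theta X_{init}.$$

Three pathways encode the rotated coordinates: a coordinate encoder
(two-layer perceptron $3 \to d$, with ReLU, LayerNorm and dropout 0.1), a
distance encoder on the centroid distances $d_i = \lVert X_i - c \rVert_2$
with $c$ the geometric centre ($1 \to d/2$), and an angle encoder on the
unit direction vectors $v_i = (X_i - c)/\lVert X_i - c\rVert_2$
($3 \to d/2$). Their concatenation (width $2d$) is fused by a
linear–ReLU–LayerNorm block back to $d$. The distance pathway is exactly
rotation- and translation-invariant; the coordinate and angle pathways are
not, which is what the rotation augmentation regularises. An atom closer
than `epsilon` ($10^{-8}$ Å) to the centroid emits a zero direction vector
(the single-atom molecule is the canonical case).

## Dynamic feature exchange and scoring

For each drug, single-head cross-attention aligns the modalities:
$\alpha = \mathrm{softmax}(H^{2D} W_Q (H^{3D} W_K)^\top / \sqrt{d})$, and a
learnable scalar $\gamma$ (initialised at 0.1 to keep early fusion gentle)
gates bidirectional residual injection
$\tilde H^{2D} = H^{2D} + \gamma\, \alpha H^{3D} W_V$,
$\tilde H^{3D} = H^{3D} + \gamma\, \alpha^\top H^{2D} W_V$. The exchange is
strictly intra-drug; the two drugs of a pair share parameters but never
attend to each other. Global average pooling yields $v^{2D}, v^{3D}$, a
learned linear map of their concatenation yields the drug embedding
$g \in \mathbb{R}^{64}$, and a triple is scored by the RESCAL bilinear form
$s = g_x^\top W_r g_y$ with one learnable $64 \times 64$ matrix per
interaction type; $p = \sigma(s)$. An alternative `cross_modal` scoring
mode ($v^{2D}_x{}^\top W_r v^{3D}_y + v^{3D}_x{}^\top W_r v^{2D}_y$) is
exposed because the bilinear form's operands are ambiguous in this family
of architectures; `fused` is the default.

## Multiscale contrastive objective

A pair representation $f = [g_x ; g_y]$ (width 128) is recomputed from an
independently rotated conformer to give the second view $f'$. At each scale
$s \in \{1, 2, 4\}$, non-overlapping window means along the feature axis
($\mathrm{AvgPool1d}$, window = stride = $s$) are L2-normalised and an
in-batch InfoNCE loss is taken with temperature $\tau$: the positive for
pair $i$ is its second view, the negatives are the other pairs' two views
($2(N-1)$ terms). A batch of one has no negatives and contributes zero. The
temperature is learnable but hard-bounded in $[0.1, 2.0]$ through
$\tau = 0.1 + 1.9\,\sigma(\tau_{raw})$, reconciling "learnable" with a
bounded hyperparameter; the per-scale losses are combined with softmax
weights over three learnable logits. The total objective is

$$L = L_{main} + \gamma(t)\, L_{contrast}, \qquad
\gamma(t) = \gamma_0 (1 - t/T),\ \gamma_0 = 0.1,\ T = 500,$$

with $t$ the epoch counter (the weight anneals per epoch, not per step, and
clamps at zero beyond $T$; $T$ stays 500 even when the training budget is
shorter, so desk-scale runs use only the top of the schedule). $L_{main}$
is mean binary cross-entropy over positives and corrupted negatives
(uniform replacement of one drug slot, rejecting known positives up to 20
redraws, then accepting with a collision flag). The training ratio of
negatives per positive is configurable (`negative_ratio`, default 1; the
packaged learnability experiment uses 2, which stabilises cross-relation
score calibration at small data sizes); evaluation always uses 1:1, and
the in-training validation metrics average over three corruption draws to
damp draw noise.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `d` | 64 | embedding width everywhere (= heads × head_dim) |
| `dropout` | 0.1 | coordinate-encoder dropout (training only) |
| `pool_ratios` | 0.5, 0.25 | keep-fractions of the two hierarchical readouts |
| `scales` | 1, 2, 4 | feature-axis pooling windows of the contrastive loss |
| `tau_bounds` | 0.1–2.0 | hard bounds of the learnable temperature |
| `gamma0`, `T` | 0.1, 500 | contrastive annealing schedule |
| `lr`, `batch_size` | 5e-3, 512 | reference optimiser settings (AdamW, weight decay 1e-3, cosine annealing) |
| `epochs` | 100 | training budget; desk-scale experiments use 35–50 |

The reference optimiser settings presume a benchmark-scale triple table
(~10^5 pairs). The packaged desk-scale experiments (hundreds of triples)
pass smaller batches (8–64) and learning rates (1e-3–3e-3) so that 50
epochs still contain enough optimiser steps to converge; weight decay
excludes biases, LayerNorm gains/offsets, the DFE scalar and the
contrastive scalars.

# The synthetic benchmark

`generate_drug_library()` assembles drugs from small alkyl/aryl backbones,
an alkyl prefix, and one functional group (carboxylic acid, primary amine,
hydroxyl, halide); a configurable fraction are emitted as E/Z isomer pairs
around a C=C double bond. Labels follow a fixed rule book — acid+acid
(type 1), acid+amine (type 2), and the stereo rule cis-isomer+hydroxyl
(type 3) — with a label-flip noise rate; pairs firing no rule are omitted,
matching the positives-only shape of curated DDI tables. Pair counts grow
quadratically, so the generator caps the table (default 800 triples,
stratified by type).

`make_stereo_task()` sharpens the stereo rule into a balanced binary probe:
each example pairs a hydroxyl probe with either the cis (label 1) or trans
(label 0) member of an isomer pair. The two classes have identical 2D graph
multisets *by construction*, so any model without 3D input is forced to
chance — its scores for the two classes are bitwise equal — while the
conformer geometries differ by several tenths of an ångström in
substituent–substituent distances. E/Z isomerism (not enantiomerism)
carries the signal deliberately: centroid-distance features provably differ
between E and Z isomers, whereas this per-atom feature set need not
separate enantiomers (pooled centroid distances and direction cosines are
nearly mirror-symmetric), so enantiomer discrimination is left as an open
experimental question rather than a benchmark property.

What the generator does *not* emulate: real pharmacology (the rules exist
to make learnability decidable), realistic molecule sizes (5–15 heavy
atoms), class-imbalanced interaction vocabularies (86 types in curated
databases vs 3 here), and protonation/tautomer effects. Passing tests
therefore demonstrate that the architecture can extract and use 2D rules
and 3D stereochemical signal at desk scale — not that it reaches
benchmark-database accuracy.

# Numerical and design choices

- **Chemistry perception.** Parsing, hydrogen counting, formal charges,
  mol2 atom typing and 3D building all come from OpenBabel; ring bonds are
  the non-bridge edges of the heavy-atom graph (igraph); aromaticity is
  mol2 `ar` typing restricted to ring bonds (this excludes carboxylate
  resonance, which mol2 also writes as `ar`); conjugation uses a bond-pair
  rule (a multiple/aromatic bond and a neighbouring bond whose far atom is
  π-capable mark both bonds conjugated) that reproduces standard toolkit
  semantics on dienes, amides, acids and isolated alkenes.
- **Conformer determinism boundary.** OpenBabel's rotor search is seeded
  from wall-clock time and cannot be seeded through its API, so conformers
  are memoised per canonical SMILES for the session: within a session every
  run sees identical geometry and training is bitwise reproducible given a
  seed. Across sessions geometries vary slightly; `write_conformer_sdf()` /
  `read_conformer_sdf()` pin them when exact cross-session reproduction is
  needed. On repeated embedding failure the planar 2D layout is used
  (provenance `fallback_2d`) with a warning. The packaged multi-seed
  experiments treat the conformer set as part of each seed's random draw:
  the cache is cleared between seed runs, so the "2-of-3 seeds" logic of
  the stochastic benchmarks covers embedding variability as well, and
  variants compared at the same seed share that seed's conformers (a
  paired design).
- **Attention softmax** is computed per destination node with max-shifted
  exponentials; a node with a single incoming edge gets weight exactly 1.
- **Block-diagonal batching.** All molecules of a batch are encoded in one
  tape; cross-modal attention runs over chunks of ≤64 atoms with
  off-molecule logits masked to −10^30, which is numerically equivalent to
  a per-molecule loop (asserted in the tests to 1e-10).
- **LayerNorm epsilon** 1e-5; **degenerate directions** emit zero vectors;
  **zero vectors** passed to L2 normalisation are returned unchanged with a
  warning.
- **Evaluation mode** uses the unrotated conformer pose and no dropout, so
  prediction is deterministic; the distance pathway is pose-invariant
  anyway.
- **Early stopping** on validation AUROC is available
  (`early_stop_auroc`); "reaches the level within the budget" then stops at
  the epoch the level is reached.
- **Autodiff.** The model trains through a small reverse-mode tape
  (matrices only) written for this package; every op's gradient is verified
  against central finite differences in the test suite, and the fused
  losses (BCE-with-logits, InfoNCE) use hand-derived stable gradients.

# Known limitations

- The hierarchical pooling readouts are diagnostic (no gradient reaches
  them from the scoring loss); wiring the graph summary into the score is
  a possible extension.
- The cross-attention exchange (DFE) and the fused linear both mix the two
  modalities, so ablating DFE leaves a model whose accuracy is within seed
  noise of the full model on the packaged benchmarks; the reference
  ablation literature for this architecture family shows the same
  ambivalence on its new-drug partition. The 3D ablation, by contrast, is
  sharp: on the stereo probe it is at exact chance by construction.
- Desk-scale cold-start generalisation is weak for stereo signal: with tens
  of stereo scaffolds, a model cannot learn a geometry rule that transfers
  to unseen scaffolds, so the packaged cold-start experiments measure split
  algebra and pipeline correctness, not cold-start stereo accuracy.
- Conformer generation is single-conformer; ensembles, charge assignment
  and tautomer enumeration are out of scope.
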