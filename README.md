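# stereoddi

Stereochemistry-aware drug–drug interaction (DDI) prediction in R.

Most DDI predictors score a drug pair from its 2D bond graphs. E/Z
(cis/trans) isomers have *identical* 2D graphs, so a topological model
cannot tell them apart even when their interaction behaviour differs.
`stereoddi` fuses a 2D graph-attention encoder with a 3D conformer encoder
and makes that failure mode measurable: it ships a synthetic,
DrugBank-shaped benchmark whose labels follow known rules, including a
stereochemistry rule that only a 3D-aware model can learn.

## The model

For drugs $x, y$ and interaction type $r$, the model estimates
$p = f(G_x, G_y, r) \in [0,1]$:

- **2D encoder** — atoms are featurised into 55 descriptors and bonds into
  6; a 4-layer graph-attention trunk (2 heads × 32 dims, shared
  parameters, LayerNorm + ELU) produces node states $H^{2D}$, with
  hierarchical self-attention-pooling readouts at atom / functional-group /
  scaffold levels.
- **3D encoder** — an OpenBabel conformer is rotation-augmented
  ($X_{aug} = R_\theta X_{init}$, Euler angles $\sim U(0, 2\pi)$) and
  encoded through coordinate (3→d), centroid-distance (1→d/2) and
  direction-angle (3→d/2) pathways, fused to per-atom states $H^{3D}$.
  The distance pathway is exactly rotation-invariant.
- **Dynamic feature exchange** — intra-drug cross-attention
  $\alpha = \mathrm{softmax}(H^{2D} W_Q (H^{3D} W_K)^\top/\sqrt d)$ with a
  learnable scaling $\gamma$ (init 0.1) injects each modality into the
  other; global average pooling gives $v^{2D}, v^{3D}$, and a linear map
  of their concatenation gives the drug embedding $g \in \mathbb{R}^{64}$.
- **Scoring** — RESCAL bilinear form $s = g_x^\top W_r\, g_y$, one
  learnable $64{\times}64$ matrix per interaction type; $p = \sigma(s)$.
- **Training** — binary cross-entropy against corrupted negatives, plus a
  multiscale in-batch InfoNCE loss over pair representations pooled at
  scales $\{1,2,4\}$ with a learnable bounded temperature
  $\tau \in [0.1, 2]$ and learnable scale weights, annealed as
  $L = L_{main} + \gamma_0 (1 - t/T) L_{contrast}$
  ($\gamma_0 = 0.1$, $T = 500$). AdamW, cosine-annealed learning rate.
  Training runs through the package's own reverse-mode autodiff tape
  (gradients are finite-difference-verified in the tests).

## Worked example

```r
library(stereoddi)

# two E/Z isomers: identical 2D graphs, different 3D geometry
g_cis   <- molecular_graph("F/C=C\\CC", "cis")
g_trans <- molecular_graph("F/C=C/CC", "trans")
g_cis
#> <molecular_graph> cis: 5 atoms, 8 directed edges
identical(g_cis$node_features, g_trans$node_features)
#> [1] TRUE

d_cis   <- as.matrix(dist(generate_conformer("F/C=C\\CC")$coordinates))
d_trans <- as.matrix(dist(generate_conformer("F/C=C/CC")$coordinates))
round(c(cis = d_cis[1, 5], trans = d_trans[1, 5]), 2)   # F..CH3 distance (angstrom)
#>   cis trans
#>  3.97  4.66

# stereochemistry probe: pairing with the cis isomer is an interaction,
# pairing with its trans twin is not -- the 2D inputs are identical
task <- make_stereo_task(200, seed = 4)
cfg <- ddi_config(epochs = 50, batch_size = 8, lr = 3e-3, seed = 1)
fit <- train_ddi(task$registry[, c("id", "smiles")], task$triples, cfg,
                 negatives = task$negatives)
fit
#> <ddi_fit> 1 interaction types, 88 drugs, 50 epochs, final loss 0.7460
evaluate_ddi(fit, task$triples, negatives = task$negatives)
#> # A tibble: 1 x 4
#>     ACC AUROC    AP    F1
#> 1  0.78 0.826 0.823 0.790

# the same model without its 3D pathway is blind to the distinction:
# its scores for the two classes are bitwise equal, so AUROC is exactly 0.5
cfg_2d <- ddi_config(epochs = 50, batch_size = 8, lr = 3e-3, seed = 1, use_3d = FALSE)
fit_2d <- train_ddi(task$registry[, c("id", "smiles")], task$triples, cfg_2d,
                    negatives = task$negatives)
evaluate_ddi(fit_2d, task$triples, negatives = task$negatives)
#> # A tibble: 1 x 4
#>     ACC AUROC    AP    F1
#> 1   0.5   0.5 0.516 0.474
```

The 3D-aware model separates the isomer classes (AUROC 0.83 here) while
the 2D-only ablation sits at exact chance. Conformer generation is
time-seeded inside OpenBabel, so absolute numbers shift a little between
sessions; within a session every run is reproducible from its seed.

Other entry points: `generate_drug_library()` / `generate_ddi_labels()`
(rule-labelled synthetic benchmark), `cold_start_split()` (drug-level
train/S1/S2 splitting), `run_ablation_suite()` (wo_3d / wo_DFE /
wo_contrast variants), `tidy()` / `glance()` / `autoplot()` on fits, and a
thin CLI at `inst/scripts/stereo-ddi` (`synth`, `split`, `train`, `eval`,
`predict` subcommands).

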