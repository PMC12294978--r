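# Independent brute-force oracles used across the suite.

# InfoNCE by explicit per-sample loops over the stated denominator terms
infonce_loop_oracle <- function(F1, F2, tau, s) {
  pool <- function(m) stereoddi::scale_pool(m, s)
  f1 <- t(apply(pool(F1), 1, function(r) r / sqrt(sum(r^2))))
  f2 <- t(apply(pool(F2), 1, function(r) r / sqrt(sum(r^2))))
  n <- nrow(F1)
  if (n == 1) return(0)
  total <- 0
  for (i in seq_len(n)) {
    pos <- exp(sum(f1[i, ] * f2[i, ]) / tau)
    den <- pos
    for (j in seq_len(n)) {
      if (j == i) next
      den <- den + exp(sum(f1[i, ] * f1[j, ]) / tau)
      den <- den + exp(sum(f1[i, ] * f2[j, ]) / tau)
    }
    total <- total - log(pos / den)
  }
  total / n
}

# RESCAL score by explicit double loop
rescal_loop_oracle <- function(gx, W, gy) {
  s <- 0
  for (i in seq_along(gx)) {
    for (j in seq_along(gy)) {
      s <- s + gx[i] * W[i, j] * gy[j]
    }
  }
  s
}

# AUROC via the Mann-Whitney rank-sum identity
auroc_ranksum_oracle <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# tiny deterministic molecular fixtures
fixture_graphs <- function() {
  list(
    methane = molecular_graph("C", "methane"),
    ethane = molecular_graph("CC", "ethane"),
    benzene = molecular_graph("c1ccccc1", "benzene"),
    acetic = molecular_graph("CC(=O)O", "acetic")
  )
}

# small registry + triples for fast training tests
fixture_dataset <- function(n_drugs = 16, seed = 3) {
  spec <- synth_spec(n_drugs = n_drugs, n_types = 3, label_noise = 0,
                     stereo_fraction = 0.25, seed = seed, max_triples = 80)
  reg <- generate_drug_library(spec)
  list(spec = spec, registry = reg, triples = generate_ddi_labels(reg, spec))
}
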