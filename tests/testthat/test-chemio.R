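# Molecule parsing, featurisation widths, conformers, rotations, file IO.

test_that("atom features have width 55 and encode the documented descriptors", {
  gs <- fixture_graphs()
  for (g in gs) {
    expect_equal(ncol(g$node_features), 55L)
  }
  # single-carbon case: one row, heavy degree 0, four hydrogens
  m <- gs$methane$node_features
  expect_equal(nrow(m), 1L)
  expect_equal(unname(m[1, "degree"]), 0)
  expect_equal(unname(m[1, "num_h"]), 4)
  expect_equal(unname(m[1, "sym_C"]), 1)
})

test_that("benzene atoms are six identical aromatic carbons (per-descriptor recomputation)", {
  nf <- fixture_graphs()$benzene$node_features
  expect_equal(nrow(nf), 6L)
  # independent recomputation of each descriptor for an aromatic CH carbon:
  # carbon one-hot, 2 heavy neighbours, 1 implicit H, no charge/radicals,
  # sp2, aromatic
  expected <- c(sym_C = 1, degree = 2, implicit_valence = 1, formal_charge = 0,
                radical_electrons = 0, hyb_SP2 = 1, aromatic = 1, num_h = 1)
  for (i in 1:6) {
    row <- nf[i, ]
    expect_equal(row[names(expected)], expected)
    expect_equal(sum(row), sum(expected))  # all other slots zero
  }
  # one-hot blocks sum to at most one
  gs <- fixture_graphs()
  for (g in gs) {
    expect_true(all(rowSums(g$node_features[, 1:44, drop = FALSE]) <= 1))
    expect_true(all(rowSums(g$node_features[, 49:53, drop = FALSE]) <= 1))
  }
})

test_that("bond features have width 6, both directions, correct flags", {
  gs <- fixture_graphs()
  for (g in gs) {
    expect_equal(ncol(g$edge_features), 6L)
    # every directed edge has its reverse with identical features
    key <- paste(g$edges[, 1], g$edges[, 2])
    rev <- paste(g$edges[, 2], g$edges[, 1])
    expect_setequal(key, rev)
    for (i in seq_len(nrow(g$edges))) {
      j <- which(g$edges[, 1] == g$edges[i, 2] & g$edges[, 2] == g$edges[i, 1])
      expect_equal(g$edge_features[i, ], g$edge_features[j, ])
    }
  }
  # ethane: 2 directed edges, plain single bond
  e <- gs$ethane
  expect_equal(nrow(e$edges), 2L)
  expect_equal(unname(e$edge_features[1, ]), c(1, 0, 0, 0, 0, 0))
  # benzene: 12 directed edges (6 ring bonds), aromatic + conjugated + ring
  b <- gs$benzene
  expect_equal(nrow(b$edges), 12L)
  expect_true(all(b$edge_features[, "bond_aromatic"] == 1))
  expect_true(all(b$edge_features[, "conjugated"] == 1))
  expect_true(all(b$edge_features[, "in_ring"] == 1))
  # acetic acid: C=O and C-OH conjugated, C-C not; nothing in a ring
  a <- gs$acetic
  expect_true(all(a$edge_features[, "in_ring"] == 0))
  cc <- which(a$edges[, 1] == 1 & a$edges[, 2] == 2)
  expect_equal(unname(a$edge_features[cc, "conjugated"]), 0)
})

test_that("atom features agree with an independent RDKit computation", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  script <- '
import json, sys
from rdkit import Chem
out = {}
for smi in ["c1ccccc1", "CC(=O)O"]:
    m = Chem.MolFromSmiles(smi)
    out[smi] = [
        [a.GetSymbol(), a.GetDegree(), a.GetFormalCharge(),
         a.GetNumRadicalElectrons(), str(a.GetHybridization()),
         int(a.GetIsAromatic()), a.GetTotalNumHs()]
        for a in m.GetAtoms()]
print(json.dumps(out))
'
  res <- system2("python", c("-c", shQuote(script)), stdout = TRUE, stderr = FALSE)
  ref <- jsonlite::fromJSON(paste(res, collapse = ""), simplifyVector = FALSE)
  for (smi in names(ref)) {
    nf <- featurize_atoms(smi)
    for (i in seq_along(ref[[smi]])) {
      a <- ref[[smi]][[i]]
      expect_equal(unname(nf[i, paste0("sym_", a[[1]])]), 1)
      expect_equal(unname(nf[i, "degree"]), a[[2]])
      expect_equal(unname(nf[i, "formal_charge"]), a[[3]])
      expect_equal(unname(nf[i, "radical_electrons"]), a[[4]])
      expect_equal(unname(nf[i, paste0("hyb_", a[[5]])]), 1)
      expect_equal(unname(nf[i, "aromatic"]), a[[6]])
      expect_equal(unname(nf[i, "num_h"]), a[[7]])
    }
  }
})

test_that("unparseable SMILES raise an error naming the string", {
  expect_error(parse_molecule("not_a_smiles"), "not_a_smiles")
  expect_error(molecular_graph("C1CC"), "C1CC")
  expect_error(generate_conformer("]["), "\\]\\[")
})

test_that("conformers are reproducible in-session, finite, heavy-atom aligned", {
  c1 <- generate_conformer("CC", "ethane")
  c2 <- generate_conformer("CC", "ethane")
  expect_identical(c1$coordinates, c2$coordinates)
  expect_true(all(is.finite(c1$coordinates)))
  expect_equal(nrow(c1$coordinates), molecular_graph("CC")$n_atoms)
  single <- generate_conformer("C", "methane")
  expect_equal(dim(single$coordinates), c(1L, 3L))
  expect_true(all(is.finite(single$coordinates)))
})

test_that("cis and trans isomers share the 2D graph but differ in geometry", {
  gc <- molecular_graph("F/C=C\\F", "cis")
  gt <- molecular_graph("F/C=C/F", "trans")
  expect_identical(gc$node_features, gt$node_features)
  expect_identical(gc$edge_features, gt$edge_features)
  cc <- generate_conformer("F/C=C\\F", "cis")
  ct <- generate_conformer("F/C=C/F", "trans")
  d_cis <- as.matrix(dist(cc$coordinates))[1, 4]
  d_trans <- as.matrix(dist(ct$coordinates))[1, 4]
  expect_lt(d_cis, d_trans)  # F-F distance strictly smaller in the cis form
  expect_gt(max(abs(as.matrix(dist(cc$coordinates)) -
                    as.matrix(dist(ct$coordinates)))), 0.1)
})

test_that("Euler rotations are proper, preserve distances, and match closed forms", {
  # identity rotation
  X <- generate_conformer("CC(=O)O", "acetic")$coordinates
  expect_equal(random_rotation(X, angles = c(0, 0, 0)), X)
  # closed-form quarter turn about z
  p <- random_rotation(matrix(c(1, 0, 0), 1, 3), angles = c(pi / 2, 0, 0))
  expect_equal(as.numeric(p), c(0, 1, 0), tolerance = 1e-6)
  # orthogonality, unit determinant, rigid motion under random draws
  set.seed(11)
  for (k in 1:10) {
    ang <- runif(3, 0, 2 * pi)
    R <- euler_rotation_matrix(ang)
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-6)
    expect_equal(det(R), 1, tolerance = 1e-6)
    Xr <- random_rotation(X, angles = ang)
    expect_lt(max(abs(as.matrix(dist(Xr)) - as.matrix(dist(X)))), 1e-5)
  }
})

test_that("registries and triple tables round-trip and validate", {
  reg <- tibble::tibble(id = c("a", "b", "c"),
                        smiles = c("CC", "CCO", "CCN"))
  tri <- tibble::tibble(drug_a = c("a", "b", "a"),
                        drug_b = c("b", "c", "c"),
                        type = c(1L, 2L, 1L))
  for (ext in c("csv", "tsv")) {
    rp <- tempfile(fileext = paste0(".", ext))
    tp <- tempfile(fileext = paste0(".", ext))
    write_ddi_table(reg, rp)
    write_ddi_table(tri, tp)
    expect_equal(as.data.frame(read_smiles_registry(rp)), as.data.frame(reg))
    expect_equal(as.data.frame(read_ddi_table(tp, registry = reg)),
                 as.data.frame(tri))
  }
  # .smi format
  sp <- tempfile(fileext = ".smi")
  writeLines(c("CC a", "CCO b"), sp)
  expect_equal(read_smiles_registry(sp)$id, c("a", "b"))
  # unknown drug id in triples
  bad <- tibble::tibble(drug_a = "a", drug_b = "zzz", type = 1L)
  tp2 <- tempfile(fileext = ".csv")
  write_ddi_table(bad, tp2)
  expect_error(read_ddi_table(tp2, registry = reg), "zzz")
  # duplicate registry ids
  dp <- tempfile(fileext = ".csv")
  write_ddi_table(tibble::tibble(id = c("a", "a"), smiles = c("C", "CC")), dp)
  expect_error(read_smiles_registry(dp), "duplicate")
  # missing columns
  mp <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(foo = 1), mp)
  expect_error(read_ddi_table(mp), "missing")
})

test_that("conformer SDF export round-trips coordinates", {
  cfs <- list(generate_conformer("CC", "ethane"),
              generate_conformer("CCO", "ethanol"))
  path <- tempfile(fileext = ".sdf")
  write_conformer_sdf(cfs, path)
  back <- read_conformer_sdf(path)
  expect_equal(names(back), c("ethane", "ethanol"))
  expect_equal(back$ethane$coordinates, cfs[[1]]$coordinates, tolerance = 1e-4)
  expect_equal(back$ethanol$provenance, cfs[[2]]$provenance)
})
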