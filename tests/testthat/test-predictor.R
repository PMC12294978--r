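# Drug-pair scoring: fusion map, RESCAL bilinear forms, negative sampling,
# main-task loss.

test_that("fuse_drug_embedding is the stated linear map", {
  d <- 4L
  p <- list("pred.fuse_W" = matrix(0, 2 * d, d), "pred.fuse_b" = matrix(0, 1, d))
  expect_equal(fuse_drug_embedding(rep(0, d), rep(0, d), p), rep(0, d))
  # identity blocks: g = v2D + v3D
  p[["pred.fuse_W"]] <- rbind(diag(d), diag(d))
  v2 <- c(1, 2, 3, 4); v3 <- c(10, 20, 30, 40)
  expect_equal(fuse_drug_embedding(v2, v3, p), v2 + v3)
  # random case against an explicit matrix-vector product
  set.seed(41)
  p[["pred.fuse_W"]] <- matrix(rnorm(2 * d * d), 2 * d, d)
  p[["pred.fuse_b"]] <- matrix(rnorm(d), 1, d)
  expect_equal(fuse_drug_embedding(v2, v3, p),
               as.numeric(c(v2, v3) %*% p[["pred.fuse_W"]]) + as.numeric(p[["pred.fuse_b"]]))
  expect_error(fuse_drug_embedding(v2, c(v3, 5), p))
})

test_that("rescal_score reduces to known closed forms and the double-loop oracle", {
  g1 <- c(1, 0, 0); g2 <- c(0, 1, 0)
  W <- matrix(0, 3, 3); W[1, 2] <- 2
  expect_equal(rescal_score(g1, g2, 1, list(W)), 2)
  expect_equal(rescal_score(g1, g1, 1, list(diag(3))), sum(g1 * g1))
  expect_equal(rescal_score(rep(0, 3), g2, 1, list(W)), 0)
  set.seed(42)
  for (k in 1:5) {
    gx <- rnorm(64); gy <- rnorm(64); W64 <- matrix(rnorm(64 * 64), 64, 64)
    expect_equal(rescal_score(gx, gy, 1, list(W64)),
                 rescal_loop_oracle(gx, W64, gy), tolerance = 1e-6)
  }
  expect_error(rescal_score(g1, g2, 5, list(W)), "unknown relation")
})

test_that("distinct relation matrices give distinct scores for the same pair", {
  set.seed(43)
  p <- predictor_init(8, n_types = 3)
  gx <- rnorm(8); gy <- rnorm(8)
  s <- vapply(1:3, function(r) rescal_score(gx, gy, r, p), numeric(1))
  expect_gt(min(abs(diff(s))), 1e-8)
})

test_that("negative corruption changes exactly one slot and is reproducible", {
  tri <- tibble::tibble(drug_a = c("a", "b", "c"), drug_b = c("b", "c", "d"),
                        type = c(1L, 1L, 2L))
  drugs <- letters[1:8]
  set.seed(44)
  neg <- sample_negatives(tri, drugs)
  for (i in seq_len(nrow(neg))) {
    changed <- (neg$drug_a[i] != tri$drug_a[i]) + (neg$drug_b[i] != tri$drug_b[i])
    expect_equal(changed, 1)
    expect_false(neg$drug_a[i] == neg$drug_b[i])
  }
  expect_identical(neg$type, tri$type)
  set.seed(44)
  expect_identical(sample_negatives(tri, drugs), neg)
})

test_that("exhausted rejection cap returns a flagged collision", {
  # two drugs, the only pair is a known positive in both orientations
  tri <- tibble::tibble(drug_a = "a", drug_b = "b", type = 1L)
  set.seed(45)
  neg <- sample_negatives(tri, c("a", "b"), max_tries = 20L)
  expect_true(neg$collision[1])
  expect_true(neg$drug_a[1] != neg$drug_b[1])
})

test_that("main loss hits its closed forms and limits", {
  expect_equal(main_loss(c(0, 0), c(0, 0)), log(2), tolerance = 1e-9)
  expect_lt(main_loss(rep(40, 3), rep(-40, 3)), 1e-12)
  expect_equal(main_loss(1, -1), -log(plogis(1)), tolerance = 1e-5)
  expect_equal(main_loss(1, -1), 0.313262, tolerance = 1e-5)
  expect_error(main_loss(numeric(0), numeric(0)))
})

test_that("a few optimisation steps reduce the main loss on a fixed tiny batch", {
  set.seed(46)
  d <- 8L
  params <- c(predictor_init(d, 1),
              list(g = matrix(rnorm(4 * d), 4, d)))
  pos <- cbind(1:2); neg <- cbind(3:4)
  loss_of <- function(p) {
    tape <- stereoddi:::ad_tape()
    P <- stereoddi:::ad_wrap_params(tape, p)
    gx <- stereoddi:::ad_gather(tape, P$g, c(1, 3))
    gy <- stereoddi:::ad_gather(tape, P$g, c(2, 4))
    z <- stereoddi:::ad_bilinear(tape, gx, P[["pred.rel_1"]], gy)
    list(tape = tape, P = P,
         loss = stereoddi:::ad_bce_with_logits(tape, z, c(1, 0)))
  }
  st <- stereoddi:::adamw_state(params)
  losses <- numeric(6)
  for (k in 1:6) {
    r <- loss_of(params)
    losses[k] <- r$loss$value[1]
    stereoddi:::ad_backward(r$tape, r$loss)
    upd <- stereoddi:::adamw_step(params, stereoddi:::ad_collect_grads(r$P),
                                  st, lr = 0.05, weight_decay = 0)
    params <- upd$params; st <- upd$state
  }
  expect_lt(losses[6], losses[1])
})

test_that("tape scores agree with the plain rescal evaluation path", {
  dat <- fixture_dataset(8)
  dd <- stereoddi:::prepare_drug_data(dat$registry)
  cfg <- ddi_config(seed = 2)
  params <- ddi_model_init(cfg, 3)
  ids <- dat$registry$id[1:4]
  enc <- stereoddi:::encode_drugs_eval(params, ids, dd, cfg)
  tri <- tibble::tibble(drug_a = ids[c(1, 2)], drug_b = ids[c(3, 4)],
                        type = c(1L, 2L))
  sc <- stereoddi:::score_triples_eval(params, enc, tri, cfg)
  for (i in 1:2) {
    expect_equal(sc[i],
                 rescal_score(enc$g[match(tri$drug_a[i], ids), ],
                              enc$g[match(tri$drug_b[i], ids), ],
                              tri$type[i], params),
                 tolerance = 1e-10)
  }
  # cross-modal scoring mode follows its stated bilinear coupling
  cfg2 <- ddi_config(seed = 2, score_mode = "cross_modal")
  sc2 <- stereoddi:::score_triples_eval(params, enc, tri, cfg2)
  i1 <- match(tri$drug_a[1], ids); i2 <- match(tri$drug_b[1], ids)
  W <- params[["pred.rel_1"]]
  expect_equal(sc2[1],
               as.numeric(enc$v2D[i1, ] %*% W %*% enc$v3D[i2, ] +
                          enc$v3D[i1, ] %*% W %*% enc$v2D[i2, ]),
               tolerance = 1e-10)
})
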