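# Multiscale InfoNCE: pooling, normalisation, similarity, the loss and its
# oracle, scale weighting, annealing.

test_that("scale pooling computes non-overlapping window means", {
  expect_equal(scale_pool(c(1, 2, 3, 4), 1), c(1, 2, 3, 4))
  expect_equal(scale_pool(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  expect_equal(scale_pool(c(1, 2, 3, 4), 4), 2.5)
  expect_equal(scale_pool(rbind(c(1, 2, 3, 4), c(4, 3, 2, 1)), 2),
               rbind(c(1.5, 3.5), c(3.5, 1.5)))
  expect_error(scale_pool(c(1, 2, 3), 2), "divide")
})

test_that("l2 normalisation produces unit rows and warns on zero input", {
  expect_equal(l2_normalize(c(3, 4)), c(0.6, 0.8))
  u <- c(1, 0, 0)
  expect_equal(l2_normalize(u), u)
  set.seed(51)
  m <- matrix(rnorm(40), 8, 5)
  expect_true(all(abs(sqrt(rowSums(l2_normalize(m)^2)) - 1) < 1e-7))
  expect_warning(z <- l2_normalize(c(0, 0)), "zero")
  expect_equal(z, c(0, 0))
})

test_that("similarity matrix scales cosine similarities by 1/tau", {
  expect_equal(similarity_matrix(diag(3), diag(3), 1), diag(3))
  set.seed(52)
  F1 <- l2_normalize(matrix(rnorm(8), 2, 4))
  F2 <- l2_normalize(matrix(rnorm(8), 2, 4))
  expect_equal(similarity_matrix(F1, F2, 0.5), 2 * similarity_matrix(F1, F2, 1))
  # entry-wise cosine loop
  S <- similarity_matrix(F1, F2, 0.7)
  for (i in 1:2) for (j in 1:2) {
    expect_equal(S[i, j], sum(F1[i, ] * F2[j, ]) / 0.7, tolerance = 1e-10)
  }
})

test_that("InfoNCE vanishes for a single pair and matches closed forms at N = 2", {
  expect_equal(infonce_scale_loss(matrix(1, 1, 4), matrix(1, 1, 4), 1, 1), 0)
  # views of i identical, everything about j orthogonal to i:
  # denominator = e^1 + e^0 + e^0 -> loss = -log(e / (e + 2))
  F1 <- rbind(c(1, 0, 0, 0), c(0, 0, 1, 0))
  F2 <- rbind(c(1, 0, 0, 0), c(0, 0, 1, 0))
  l <- infonce_scale_loss(F1, F2, 1, 1)
  expect_equal(l, -log(exp(1) / (exp(1) + 2)), tolerance = 1e-9)
  expect_equal(l, 0.551444, tolerance = 1e-5)
})

test_that("vectorised InfoNCE equals the per-sample double-loop oracle", {
  set.seed(53)
  for (n in c(2, 4, 8)) {
    for (s in c(1, 2, 4)) {
      F1 <- matrix(rnorm(n * 8), n, 8)
      F2 <- matrix(rnorm(n * 8), n, 8)
      for (tau in c(0.3, 1, 1.7)) {
        expect_equal(infonce_scale_loss(F1, F2, tau, s),
                     infonce_loop_oracle(F1, F2, tau, s), tolerance = 1e-6)
      }
    }
  }
})

test_that("InfoNCE is nonnegative and vanishes as positives align at small tau", {
  set.seed(54)
  for (k in 1:10) {
    F1 <- matrix(rnorm(32), 4, 8)
    F2 <- matrix(rnorm(32), 4, 8)
    expect_gte(infonce_scale_loss(F1, F2, 1, 1), 0)
  }
  F1 <- diag(4)  # mutually orthogonal, perfectly aligned with their views
  expect_lt(infonce_scale_loss(F1, F1, 0.05, 1), 1e-6)
})

test_that("scale weights are a softmax over the logits", {
  expect_equal(scale_weights(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(scale_weights(c(log(2), 0, 0)), c(0.5, 0.25, 0.25))
  set.seed(55)
  w <- scale_weights(rnorm(3))
  expect_equal(sum(w), 1, tolerance = 1e-7)
  expect_true(all(w >= 0))
})

test_that("multiscale combination respects the weights", {
  expect_equal(multiscale_loss(c(2, 2, 2), c(0.2, 0.3, 0.5)), 2)
  expect_equal(multiscale_loss(c(5, 7, 9), c(0, 1, 0)), 7)
  set.seed(56)
  l <- runif(3); w <- scale_weights(rnorm(3))
  expect_equal(multiscale_loss(l, w), sum(l * w))
})

test_that("the annealed weight follows gamma0 * (1 - t/T) with clamping", {
  expect_equal(contrastive_weight(0), 0.1)
  expect_equal(contrastive_weight(500), 0)
  expect_equal(contrastive_weight(250), 0.05)
  expect_equal(contrastive_weight(600), 0)
  g <- contrastive_weight(0:500)
  expect_true(all(diff(g) < 0))
})

test_that("total loss combines the two objectives under the schedule", {
  expect_equal(total_loss(1, 2, 0), 1.2)
  expect_equal(total_loss(1, 2, 500), 1)
  expect_equal(total_loss(1, 0, 100), 1)
})

test_that("the reparameterised temperature never escapes its bounds", {
  expect_equal(tau_from_raw(0), 1.05)
  expect_gt(tau_from_raw(-50), 0.1 - 1e-12)
  expect_lt(tau_from_raw(50), 2 + 1e-12)
  # 100 random gradient steps on tau_raw through the InfoNCE loss
  set.seed(57)
  params <- list(tau_raw = matrix(0, 1, 1))
  st <- stereoddi:::adamw_state(params)
  F1 <- matrix(rnorm(64), 8, 8); F2 <- matrix(rnorm(64), 8, 8)
  for (k in 1:100) {
    tape <- stereoddi:::ad_tape()
    P <- stereoddi:::ad_wrap_params(tape, params)
    tau <- stereoddi:::tau_tape(tape, P$tau_raw, c(0.1, 2))
    l <- stereoddi:::infonce_scale_loss_tape(tape, stereoddi:::ad_const(tape, F1),
                                             stereoddi:::ad_const(tape, F2), tau, 1)
    stereoddi:::ad_backward(tape, l)
    upd <- stereoddi:::adamw_step(params, stereoddi:::ad_collect_grads(P), st,
                                  lr = 0.5, weight_decay = 0)
    params <- upd$params; st <- upd$state
    tv <- tau_from_raw(params$tau_raw)
    expect_gt(tv, 0.1); expect_lt(tv, 2.0)
  }
})

test_that("the tape InfoNCE path agrees with the plain implementation", {
  set.seed(58)
  F1 <- matrix(rnorm(48), 6, 8); F2 <- matrix(rnorm(48), 6, 8)
  for (s in c(1, 2, 4)) {
    tape <- stereoddi:::ad_tape()
    tau_node <- stereoddi:::ad_const(tape, matrix(0.8, 1, 1))
    l <- stereoddi:::infonce_scale_loss_tape(tape, stereoddi:::ad_const(tape, F1),
                                             stereoddi:::ad_const(tape, F2),
                                             tau_node, s)
    expect_equal(l$value[1], infonce_scale_loss(F1, F2, 0.8, s), tolerance = 1e-10)
  }
})
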