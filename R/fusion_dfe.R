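# Dynamic Feature Exchange: single-head bidirectional cross-attention between
# a molecule's 2D node states (queries) and its 3D node states (keys), with a
# learnable scaling factor gating the injected residual, followed by global
# average pooling per modality. DFE is strictly intra-drug: the two drugs of a
# pair pass through it independently with shared parameters.

#' Initialise Dynamic Feature Exchange parameters
#'
#' @param d Node embedding width.
#' @param gamma0 Initial value of the learnable residual scaling factor
#'   (0.1; small so early-training fusion stays gentle).
#' @return Named list with `dfe.W_Q`, `dfe.W_K`, `dfe.W_V` (d x d) and the
#'   scalar `dfe.gamma`.
#' @export
dfe_init <- function(d = 64L, gamma0 = 0.1) {
  p <- list(W_Q = init_matrix(d, d), W_K = init_matrix(d, d),
            W_V = init_matrix(d, d), gamma = matrix(gamma0, 1, 1))
  names(p) <- paste0("dfe.", names(p))
  p
}

dfe_tape <- function(tape, H2D, H3D, P, d) {
  q <- ad_matmul(tape, H2D, P[["dfe.W_Q"]])
  k <- ad_matmul(tape, H3D, P[["dfe.W_K"]])
  logits <- ad_affine_const(tape, ad_matmul(tape, q, ad_transpose(tape, k)),
                            1 / sqrt(d))
  alpha <- ad_softmax_rows(tape, logits)
  v2 <- ad_matmul(tape, H3D, P[["dfe.W_V"]])
  v3 <- ad_matmul(tape, H2D, P[["dfe.W_V"]])
  inj2 <- ad_mul_scalar(tape, ad_matmul(tape, alpha, v2), P[["dfe.gamma"]])
  inj3 <- ad_mul_scalar(tape, ad_matmul(tape, ad_transpose(tape, alpha), v3),
                        P[["dfe.gamma"]])
  h2t <- ad_add(tape, H2D, inj2)
  h3t <- ad_add(tape, H3D, inj3)
  list(alpha = alpha, H2D_tilde = h2t, H3D_tilde = h3t,
       v2D = ad_mean_rows(tape, h2t), v3D = ad_mean_rows(tape, h3t))
}

# Batched DFE over a block-diagonal molecule structure: attention logits
# outside a molecule's own block are masked to -Inf, so the row softmax
# factorises over molecules and one pass handles the whole batch. Equivalent
# to looping dfe_tape over molecules (asserted in the tests).
dfe_batched_tape <- function(tape, H2D, H3D, P, d, graph_index) {
  mask <- matrix(-1e30, length(graph_index), length(graph_index))
  mask[outer(graph_index, graph_index, "==")] <- 0
  q <- ad_matmul(tape, H2D, P[["dfe.W_Q"]])
  k <- ad_matmul(tape, H3D, P[["dfe.W_K"]])
  logits <- ad_affine_const(tape, ad_matmul(tape, q, ad_transpose(tape, k)),
                            1 / sqrt(d))
  logits <- ad_add(tape, logits, ad_const(tape, mask))
  alpha <- ad_softmax_rows(tape, logits)
  v2 <- ad_matmul(tape, H3D, P[["dfe.W_V"]])
  v3 <- ad_matmul(tape, H2D, P[["dfe.W_V"]])
  inj2 <- ad_mul_scalar(tape, ad_matmul(tape, alpha, v2), P[["dfe.gamma"]])
  inj3 <- ad_mul_scalar(tape, ad_matmul(tape, ad_transpose(tape, alpha), v3),
                        P[["dfe.gamma"]])
  list(H2D_tilde = ad_add(tape, H2D, inj2), H3D_tilde = ad_add(tape, H3D, inj3))
}

# Chunked batched DFE: molecules are grouped into chunks of at most
# `chunk_nodes` atoms and each chunk runs one masked attention pass, keeping
# the dense block waste bounded while avoiding a per-molecule op loop.
dfe_chunked_tape <- function(tape, H2D, H3D, P, d, graph_index,
                             chunk_nodes = 64L) {
  sizes <- tabulate(graph_index)
  chunks <- list()
  cur <- integer(0); cur_n <- 0L
  for (m in seq_along(sizes)) {
    if (cur_n + sizes[m] > chunk_nodes && length(cur)) {
      chunks[[length(chunks) + 1L]] <- cur
      cur <- integer(0); cur_n <- 0L
    }
    cur <- c(cur, m); cur_n <- cur_n + sizes[m]
  }
  if (length(cur)) chunks[[length(chunks) + 1L]] <- cur
  h2_parts <- vector("list", length(chunks))
  h3_parts <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    rows <- which(graph_index %in% chunks[[ci]])
    res <- dfe_batched_tape(tape, ad_gather(tape, H2D, rows),
                            ad_gather(tape, H3D, rows), P, d,
                            graph_index[rows])
    h2_parts[[ci]] <- res$H2D_tilde
    h3_parts[[ci]] <- res$H3D_tilde
  }
  # chunks preserve row order, so plain row-concatenation realigns the batch
  list(H2D_tilde = ad_concat_rows(tape, h2_parts),
       H3D_tilde = ad_concat_rows(tape, h3_parts))
}

#' Cross-modal attention matrix between 2D and 3D node states
#'
#' `alpha = softmax_rows((H2D W_Q)(H3D W_K)^T / sqrt(d))`; row i gives the
#' attention of 2D atom i over all 3D atoms of the same molecule.
#'
#' @param H2D,H3D N x d node-state matrices for the same molecule (same atom
#'   ordering; mismatched row counts are a contract violation).
#' @param params Parameters from [dfe_init()].
#' @return N x N row-stochastic matrix.
#' @export
cross_attention <- function(H2D, H3D, params) {
  stopifnot(nrow(H2D) == nrow(H3D), ncol(H2D) == ncol(H3D))
  d <- ncol(H2D)
  tape <- ad_tape()
  P <- ad_wrap_params(tape, params)
  res <- dfe_tape(tape, ad_const(tape, H2D), ad_const(tape, H3D), P, d)
  res$alpha$value
}

#' Bidirectional gated feature exchange
#'
#' `H~2D = H2D + gamma * alpha (H3D W_V)` and
#' `H~3D = H3D + gamma * alpha^T (H2D W_V)`. With `gamma = 0` both outputs
#' equal their inputs exactly.
#'
#' @param H2D,H3D N x d node-state matrices.
#' @param params Parameters from [dfe_init()].
#' @return List with `alpha`, `H2D_tilde`, `H3D_tilde`, `v2D`, `v3D`.
#' @export
dfe_exchange <- function(H2D, H3D, params) {
  stopifnot(nrow(H2D) == nrow(H3D))
  d <- ncol(H2D)
  tape <- ad_tape()
  P <- ad_wrap_params(tape, params)
  res <- dfe_tape(tape, ad_const(tape, H2D), ad_const(tape, H3D), P, d)
  list(alpha = res$alpha$value, H2D_tilde = res$H2D_tilde$value,
       H3D_tilde = res$H3D_tilde$value,
       v2D = as.numeric(res$v2D$value), v3D = as.numeric(res$v3D$value))
}

#' Global average pooling of the two modality node states
#'
#' @param H2D_tilde,H3D_tilde N x d matrices after feature exchange.
#' @return List with vectors `v2D` and `v3D` (column means).
#' @export
pool_modalities <- function(H2D_tilde, H3D_tilde) {
  stopifnot(nrow(H2D_tilde) >= 1, nrow(H3D_tilde) >= 1)
  list(v2D = colMeans(H2D_tilde), v3D = colMeans(H3D_tilde))
}
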