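# 2D topological encoder: LayerNorm on the raw atom features, a linear input
# projection, then a 4-layer graph-attention trunk (2 heads x 32 dims,
# parameters shared across layers by default, ELU + LayerNorm after each
# layer), read out hierarchically: the atom level is the mean of the first
# layer's node states, the functional-group and scaffold levels are
# self-attention (SAGPool-style) poolings of the final node states at two
# ratios, and the three level summaries are fused by a small MLP. Bond
# features enter the attention logits as an additive per-edge term.

#' Configuration for the 2D graph-attention encoder
#'
#' @param n_layers Number of attention layers in the trunk.
#' @param heads Attention heads per layer.
#' @param head_dim Output width per head (`heads * head_dim` is the node
#'   embedding width, 64 by default).
#' @param share_parameters Share one parameter set across all trunk layers.
#' @param pool_ratios Keep-fractions for the functional-group and scaffold
#'   pooling branches (monotonically coarser).
#' @param in_dim Input node-feature width (55).
#' @param edge_dim Edge-feature width (6).
#' @return A `topo2d_config` list.
#' @export
topo2d_config <- function(n_layers = 4L, heads = 2L, head_dim = 32L,
                          share_parameters = TRUE, pool_ratios = c(0.5, 0.25),
                          in_dim = NODE_FEATURE_WIDTH, edge_dim = EDGE_FEATURE_WIDTH) {
  stopifnot(n_layers >= 1, heads >= 1, head_dim >= 1,
            length(pool_ratios) == 2, all(pool_ratios > 0), all(pool_ratios <= 1))
  structure(list(n_layers = as.integer(n_layers), heads = as.integer(heads),
                 head_dim = as.integer(head_dim), d = as.integer(heads * head_dim),
                 share_parameters = isTRUE(share_parameters),
                 pool_ratios = pool_ratios, in_dim = as.integer(in_dim),
                 edge_dim = as.integer(edge_dim)),
            class = "topo2d_config")
}

#' Initialise 2D-encoder parameters
#'
#' @param config A [topo2d_config()].
#' @return Named list of parameter matrices (prefix `topo.`).
#' @export
topo2d_init <- function(config = topo2d_config()) {
  d <- config$d
  layer_params <- function(l) {
    out <- list()
    for (h in seq_len(config$heads)) {
      key <- sprintf("l%d_h%d_", l, h)
      out[[paste0(key, "W")]] <- init_matrix(d, config$head_dim)
      out[[paste0(key, "asrc")]] <- init_matrix(config$head_dim, 1L)
      out[[paste0(key, "adst")]] <- init_matrix(config$head_dim, 1L)
      out[[paste0(key, "aedge")]] <- init_matrix(config$edge_dim, 1L)
    }
    out[[sprintf("l%d_ln_g", l)]] <- matrix(1, 1, d)
    out[[sprintf("l%d_ln_b", l)]] <- matrix(0, 1, d)
    out
  }
  nlp <- if (config$share_parameters) 1L else config$n_layers
  p <- c(
    list(
      in_ln_g = matrix(1, 1, config$in_dim), in_ln_b = matrix(0, 1, config$in_dim),
      in_W = init_matrix(config$in_dim, d), in_b = matrix(0, 1, d),
      sag1_p = init_matrix(d, 1L), sag2_p = init_matrix(d, 1L),
      fuse_W1 = init_matrix(3L * d, d), fuse_b1 = matrix(0, 1, d),
      fuse_W2 = init_matrix(d, d), fuse_b2 = matrix(0, 1, d)
    ),
    do.call(c, lapply(seq_len(nlp), layer_params))
  )
  names(p) <- paste0("topo.", names(p))
  p
}

# one multi-head attention layer over the (batched) graph; edges carry global
# node indices and include self-loops with zero edge features
gat_layer_tape <- function(tape, h, P, layer_key, edges, edge_feat_node,
                           config, n_nodes, return_alpha = FALSE) {
  src <- edges[, 1]
  dst <- edges[, 2]
  heads_out <- vector("list", config$heads)
  alphas <- vector("list", config$heads)
  for (hd in seq_len(config$heads)) {
    key <- sprintf("topo.%s_h%d_", layer_key, hd)
    hw <- ad_matmul(tape, h, P[[paste0(key, "W")]])
    hw_src <- ad_gather(tape, hw, src)
    hw_dst <- ad_gather(tape, hw, dst)
    logits <- ad_add(tape,
      ad_add(tape,
        ad_matmul(tape, hw_src, P[[paste0(key, "asrc")]]),
        ad_matmul(tape, hw_dst, P[[paste0(key, "adst")]])),
      ad_matmul(tape, edge_feat_node, P[[paste0(key, "aedge")]]))
    logits <- ad_leaky_relu(tape, logits, 0.2)
    alpha <- ad_softmax_group(tape, logits, dst, n_nodes)
    weighted <- ad_mul_colvec(tape, hw_src, alpha)
    heads_out[[hd]] <- ad_rowsum_group(tape, weighted, dst, n_nodes)
    alphas[[hd]] <- alpha
  }
  out <- ad_concat_cols(tape, heads_out)
  out <- ad_layernorm(tape, out, P[[sprintf("topo.%s_ln_g", layer_key)]],
                      P[[sprintf("topo.%s_ln_b", layer_key)]])
  out <- ad_elu(tape, out)
  if (return_alpha) list(h = out, alpha = alphas) else list(h = out)
}

# SAGPool-style branch: score nodes with a learnable vector, keep the top
# ceil(ratio * n) nodes per graph, gate them with tanh(score), mean-pool
sag_branch_tape <- function(tape, h, P, pname, graph_index, n_graphs, ratio) {
  score <- ad_matmul(tape, h, P[[pname]])
  sv <- as.numeric(score$value)
  keep <- unlist(lapply(seq_len(n_graphs), function(g) {
    idx <- which(graph_index == g)
    k <- max(1L, ceiling(ratio * length(idx)))
    idx[order(sv[idx], decreasing = TRUE)[seq_len(k)]]
  }), use.names = FALSE)
  gate <- ad_tanh_(tape, ad_gather(tape, score, keep))
  hk <- ad_gather(tape, h, keep)
  gated <- ad_mul_colvec(tape, hk, gate)
  ad_mean_group(tape, gated, graph_index[keep], n_graphs)
}

# full 2D encoder on a batched graph; returns node states and level summaries
topo2d_forward_tape <- function(tape, node_feat, edges, edge_feat, graph_index,
                                n_graphs, P, config, return_alpha = FALSE) {
  n_nodes <- nrow(node_feat)
  # self-loops so every node attends to itself (zero edge features)
  loops <- cbind(seq_len(n_nodes), seq_len(n_nodes))
  edges_aug <- rbind(edges, loops)
  ef_aug <- rbind(edge_feat, matrix(0, n_nodes, ncol(edge_feat)))
  ef_node <- ad_const(tape, ef_aug)

  x <- ad_const(tape, node_feat)
  x <- ad_layernorm(tape, x, P[["topo.in_ln_g"]], P[["topo.in_ln_b"]])
  h <- ad_add_bias(tape, ad_matmul(tape, x, P[["topo.in_W"]]), P[["topo.in_b"]])

  h1 <- NULL
  alpha_out <- NULL
  for (l in seq_len(config$n_layers)) {
    lk <- if (config$share_parameters) "l1" else sprintf("l%d", l)
    res <- gat_layer_tape(tape, h, P, lk, edges_aug, ef_node, config, n_nodes,
                          return_alpha = return_alpha && l == config$n_layers)
    h <- res$h
    if (l == 1L) h1 <- h
    if (!is.null(res$alpha)) alpha_out <- res$alpha
  }

  atom_level <- ad_mean_group(tape, h1, graph_index, n_graphs)
  fg_level <- sag_branch_tape(tape, h, P, "topo.sag1_p", graph_index, n_graphs,
                              config$pool_ratios[1])
  sc_level <- sag_branch_tape(tape, h, P, "topo.sag2_p", graph_index, n_graphs,
                              config$pool_ratios[2])
  lv <- ad_concat_cols(tape, list(atom_level, fg_level, sc_level))
  gs <- ad_add_bias(tape, ad_matmul(tape, lv, P[["topo.fuse_W1"]]), P[["topo.fuse_b1"]])
  gs <- ad_relu(tape, gs)
  gs <- ad_add_bias(tape, ad_matmul(tape, gs, P[["topo.fuse_W2"]]), P[["topo.fuse_b2"]])

  list(H2D = h, atom_level = atom_level, fg_level = fg_level,
       scaffold_level = sc_level, graph_summary = gs,
       alpha = alpha_out, edges_aug = edges_aug)
}

#' Encode a molecular graph with the 2D attention trunk
#'
#' @param graph A [molecular_graph()] (or list of them; they are batched).
#' @param params Parameters from [topo2d_init()].
#' @param config A [topo2d_config()].
#' @return For a single graph: list with `H2D` (N x d node states),
#'   `level_summaries` (3 x d matrix: atom, functional-group, scaffold rows)
#'   and `graph_summary` (length-d vector). For a list input the same, with
#'   `H2D` split per graph and one summary row per graph.
#' @export
encode_topology <- function(graph, params, config = topo2d_config()) {
  single <- inherits(graph, "molecular_graph")
  graphs <- if (single) list(graph) else graph
  stopifnot(length(graphs) >= 1)
  b <- batch_graphs(graphs)
  tape <- ad_tape()
  P <- ad_wrap_params(tape, params)
  out <- topo2d_forward_tape(tape, b$node_feat, b$edges, b$edge_feat,
                             b$graph_index, b$n_graphs, P, config)
  H2D <- out$H2D$value
  if (single) {
    list(H2D = H2D,
         level_summaries = rbind(atom = out$atom_level$value[1, ],
                                 functional_group = out$fg_level$value[1, ],
                                 scaffold = out$scaffold_level$value[1, ]),
         graph_summary = out$graph_summary$value[1, ])
  } else {
    list(H2D = lapply(seq_len(b$n_graphs), function(g) H2D[b$graph_index == g, , drop = FALSE]),
         atom_level = out$atom_level$value, fg_level = out$fg_level$value,
         scaffold_level = out$scaffold_level$value,
         graph_summary = out$graph_summary$value)
  }
}

#' Per-edge attention coefficients of one trunk layer
#'
#' Runs the first attention layer on a graph and returns, per head, the
#' normalised attention weight of every directed edge (self-loops included).
#' Weights into any node are nonnegative and sum to one.
#'
#' @param graph A [molecular_graph()].
#' @param params Parameters from [topo2d_init()].
#' @param config A [topo2d_config()].
#' @return A tibble with columns `head`, `src`, `dst`, `weight`.
#' @export
attention_coefficients <- function(graph, params, config = topo2d_config()) {
  b <- batch_graphs(list(graph))
  n_nodes <- nrow(b$node_feat)
  loops <- cbind(seq_len(n_nodes), seq_len(n_nodes))
  edges_aug <- rbind(b$edges, loops)
  ef_aug <- rbind(b$edge_feat, matrix(0, n_nodes, ncol(b$edge_feat)))
  tape <- ad_tape()
  P <- ad_wrap_params(tape, params)
  x <- ad_const(tape, b$node_feat)
  x <- ad_layernorm(tape, x, P[["topo.in_ln_g"]], P[["topo.in_ln_b"]])
  h <- ad_add_bias(tape, ad_matmul(tape, x, P[["topo.in_W"]]), P[["topo.in_b"]])
  res <- gat_layer_tape(tape, h, P, "l1", edges_aug, ad_const(tape, ef_aug),
                        config, n_nodes, return_alpha = TRUE)
  purrr::map_dfr(seq_along(res$alpha), function(hd) {
    tibble::tibble(head = hd, src = edges_aug[, 1], dst = edges_aug[, 2],
                   weight = as.numeric(res$alpha[[hd]]$value))
  })
}

# concatenate graphs into one node/edge block with a graph index
batch_graphs <- function(graphs) {
  sizes <- vapply(graphs, function(g) g$n_atoms, integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  node_feat <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    e <- graphs[[i]]$edges
    if (nrow(e) == 0) matrix(integer(0), 0, 2) else e + offsets[i]
  }))
  edge_feat <- do.call(rbind, lapply(graphs, function(g) g$edge_features))
  graph_index <- rep(seq_along(graphs), sizes)
  list(node_feat = node_feat, edges = edges, edge_feat = edge_feat,
       graph_index = graph_index, n_graphs = length(graphs), sizes = sizes)
}
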