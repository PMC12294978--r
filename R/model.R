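# Model assembly: one configuration object, one parameter store spanning all
# components, and the end-to-end differentiable forward pass for a batch of
# interaction triples.

#' Full model configuration
#'
#' Collects the component configurations, the optimiser settings and the
#' ablation switches in one object. Defaults follow the reference training
#' recipe: 4-layer shared-parameter graph-attention trunk with 2 heads of 32
#' dims, d = 64 spatial encoder, scales {1,2,4} with annealing horizon
#' T = 500 epochs and initial contrastive weight 0.1, AdamW with weight decay
#' 1e-3, initial learning rate 5e-3 under cosine annealing, batch size 512.
#'
#' @param d Embedding width.
#' @param n_layers,heads,head_dim,share_parameters,pool_ratios 2D trunk
#'   settings (see [topo2d_config()]).
#' @param dropout,epsilon 3D encoder settings (see [spatial3d_config()]).
#' @param scales,tau_bounds,gamma0,T Contrastive settings (see
#'   [contrastive_config()]).
#' @param use_3d,use_dfe,use_contrast Ablation switches: `use_3d = FALSE`
#'   replaces the 3D modality vector with zeros, `use_dfe = FALSE` pools the
#'   raw modality features without cross-attention, `use_contrast = FALSE`
#'   pins the contrastive weight at zero.
#' @param score_mode `"fused"` scores fused drug embeddings; `"cross_modal"`
#'   couples v2D of one drug with v3D of the other (both directions summed).
#' @param epochs,batch_size,lr,weight_decay Optimiser settings.
#' @param seed Master seed; all stochastic draws (initialisation, rotations,
#'   negative sampling, shuffling) derive from it.
#' @param eval_every Epoch stride for validation metrics in the history.
#' @param early_stop_auroc Optional early-stopping level: when a validation
#'   set is supplied and its AUROC reaches this value at an evaluation
#'   epoch, training stops there.
#' @param negative_ratio Corrupted negatives drawn per positive during
#'   training (evaluation always uses 1:1).
#' @return A `ddi_config` list.
#' @export
ddi_config <- function(d = 64L, n_layers = 4L, heads = 2L, head_dim = 32L,
                       share_parameters = TRUE, pool_ratios = c(0.5, 0.25),
                       dropout = 0.1, epsilon = 1e-8,
                       scales = c(1L, 2L, 4L), tau_bounds = c(0.1, 2.0),
                       gamma0 = 0.1, T = 500L,
                       use_3d = TRUE, use_dfe = TRUE, use_contrast = TRUE,
                       score_mode = c("fused", "cross_modal"),
                       epochs = 100L, batch_size = 512L, lr = 5e-3,
                       weight_decay = 1e-3, seed = 1L, eval_every = 1L,
                       early_stop_auroc = NULL, negative_ratio = 1L) {
  score_mode <- match.arg(score_mode)
  stopifnot(as.integer(d) == as.integer(heads) * as.integer(head_dim))
  structure(list(
    topo = topo2d_config(n_layers, heads, head_dim, share_parameters, pool_ratios),
    spat = spatial3d_config(d, dropout, epsilon),
    ctr = contrastive_config(scales, tau_bounds, gamma0, T),
    d = as.integer(d),
    use_3d = isTRUE(use_3d), use_dfe = isTRUE(use_dfe),
    use_contrast = isTRUE(use_contrast), score_mode = score_mode,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    lr = lr, weight_decay = weight_decay, seed = as.integer(seed),
    eval_every = as.integer(eval_every), early_stop_auroc = early_stop_auroc,
    negative_ratio = as.integer(negative_ratio)
  ), class = "ddi_config")
}

#' Read a run configuration from YAML
#'
#' Recognised keys mirror the configuration tree, e.g. `spatial3d: {d,
#' dropout, epsilon}`, `topo2d: {n_layers, heads, head_dim,
#' share_parameters, pool_ratios}`, `contrastive: {scales, gamma0, T}`,
#' `model: {use_3d, use_dfe, use_contrast, score_mode}` and `train:
#' {epochs, batch_size, lr, weight_decay, seed}`. Missing keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return A `ddi_config`.
#' @export
ddi_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  pick <- function(section, key, arg = key) {
    v <- y[[section]][[key]]
    if (!is.null(v)) args[[arg]] <<- v
  }
  pick("spatial3d", "d"); pick("spatial3d", "dropout"); pick("spatial3d", "epsilon")
  pick("topo2d", "n_layers"); pick("topo2d", "heads"); pick("topo2d", "head_dim")
  pick("topo2d", "share_parameters"); pick("topo2d", "pool_ratios")
  pick("contrastive", "scales"); pick("contrastive", "gamma0")
  pick("contrastive", "T"); pick("contrastive", "tau_bounds")
  pick("model", "use_3d"); pick("model", "use_dfe"); pick("model", "use_contrast")
  pick("model", "score_mode")
  pick("train", "epochs"); pick("train", "batch_size"); pick("train", "lr")
  pick("train", "weight_decay"); pick("train", "seed"); pick("train", "eval_every")
  pick("train", "early_stop_auroc"); pick("train", "negative_ratio")
  do.call(ddi_config, args)
}

#' Initialise all model parameters
#'
#' @param config A [ddi_config()].
#' @param n_types Number of interaction types in the vocabulary.
#' @param seed Seed for the initial draws (defaults to the config seed).
#' @return A named list of parameter matrices spanning every component.
#' @export
ddi_model_init <- function(config, n_types, seed = config$seed) {
  with_seed(seed, {
    c(topo2d_init(config$topo),
      spatial3d_init(config$spat),
      dfe_init(config$d),
      predictor_init(config$d, n_types),
      contrastive_init(config$ctr))
  })
}

# parameters excluded from weight decay: biases, layer-norm gains/offsets,
# the DFE scaling factor and the contrastive scalars
no_decay_names <- function(params) {
  nm <- names(params)
  nm[grepl("(_b[0-9]*$)|(_g[0-9]*$)|(_c[0-9]*$)|(ln_[gb]$)|(gamma$)|(tau_raw$)|(scale_logits$)", nm)]
}

# run R code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Precompute graphs and conformers for a registry
#'
#' Builds the 2D molecular graph and the 3D conformer of every drug once;
#' conformers are memoised per session, so repeated calls are cheap. The
#' result can be passed to [train_ddi()] and the evaluation helpers to
#' share one prepared set across runs.
#'
#' @param registry Tibble with `id` and `smiles`.
#' @param verbose Report progress every 50 drugs.
#' @return List with named lists `graphs` and `conformers`.
#' @export
prepare_drug_data <- function(registry, verbose = FALSE) {
  graphs <- list()
  conformers <- list()
  for (i in seq_len(nrow(registry))) {
    id <- registry$id[i]
    graphs[[id]] <- molecular_graph(registry$smiles[i], id)
    conformers[[id]] <- generate_conformer(registry$smiles[i], id)
    if (verbose && i %% 50 == 0) message("prepared ", i, "/", nrow(registry), " drugs")
  }
  list(graphs = graphs, conformers = conformers)
}

# ---- end-to-end forward -----------------------------------------------------

# Encode a set of drugs on one tape. Returns per-drug fused embeddings for
# view 1 (g) and, when requested, view 2 (g2), plus the modality vectors.
encode_drugs_tape <- function(tape, P, drug_ids, drug_data, config,
                              training = FALSE, two_views = FALSE) {
  graphs <- drug_data$graphs[drug_ids]
  b <- batch_graphs(graphs)
  topo <- topo2d_forward_tape(tape, b$node_feat, b$edges, b$edge_feat,
                              b$graph_index, b$n_graphs, P, config$topo)
  H2D <- topo$H2D
  M <- b$n_graphs
  d <- config$d

  spatial_view <- function() {
    coords <- lapply(drug_ids, function(id) {
      random_rotation(drug_data$conformers[[id]]$coordinates)
    })
    # batched spatial encoder: geometry is computed per molecule, the
    # row-wise encoders run once over the concatenated atoms
    geo <- lapply(coords, function(X) {
      g <- compute_center_and_distances(X)
      list(d = g$distances, v = compute_directions(X, g$center, config$spat$epsilon))
    })
    Xall <- do.call(rbind, coords)
    dall <- matrix(unlist(lapply(geo, `[[`, "d")), ncol = 1)
    vall <- do.call(rbind, lapply(geo, `[[`, "v"))
    f_pos <- mlp2_forward(tape, ad_const(tape, Xall), P, "spat.pos", training,
                          config$spat$dropout)
    f_dist <- mlp2_forward(tape, ad_const(tape, dall), P, "spat.dist", training)
    f_angle <- mlp2_forward(tape, ad_const(tape, vall), P, "spat.ang", training)
    f_comb <- ad_concat_cols(tape, list(f_pos, f_dist, f_angle))
    s <- ad_add_bias(tape, ad_matmul(tape, f_comb, P[["spat.fuse_W"]]),
                     P[["spat.fuse_b"]])
    s <- ad_relu(tape, s)
    ad_layernorm(tape, s, P[["spat.fuse_g"]], P[["spat.fuse_c"]])
  }

  modality_vectors <- function(H3D) {
    if (!config$use_3d) {
      v2 <- ad_mean_group(tape, H2D, b$graph_index, M)
      v3 <- ad_const(tape, matrix(0, M, d))
      return(list(v2D = v2, v3D = v3))
    }
    if (!config$use_dfe) {
      return(list(v2D = ad_mean_group(tape, H2D, b$graph_index, M),
                  v3D = ad_mean_group(tape, H3D, b$graph_index, M)))
    }
    res <- dfe_chunked_tape(tape, H2D, H3D, P, d, b$graph_index)
    list(v2D = ad_mean_group(tape, res$H2D_tilde, b$graph_index, M),
         v3D = ad_mean_group(tape, res$H3D_tilde, b$graph_index, M))
  }

  fuse <- function(mv) {
    g <- ad_add_bias(tape,
      ad_matmul(tape, ad_concat_cols(tape, list(mv$v2D, mv$v3D)),
                P[["pred.fuse_W"]]),
      P[["pred.fuse_b"]])
    g
  }

  mv1 <- modality_vectors(if (config$use_3d) spatial_view() else NULL)
  out <- list(ids = drug_ids, v2D = mv1$v2D, v3D = mv1$v3D, g = fuse(mv1),
              topo = topo)
  if (two_views) {
    mv2 <- modality_vectors(if (config$use_3d) spatial_view() else NULL)
    out$g2 <- fuse(mv2)
  }
  out
}

# RESCAL scores for triples given encoded drugs; ai/bi/type are parallel
# vectors of drug indices (into enc$ids) and relation indices
score_triples_tape <- function(tape, P, enc, ai, bi, type, config) {
  n <- length(ai)
  order_out <- integer(0)
  parts <- list()
  for (r in sort(unique(type))) {
    rows <- which(type == r)
    gx <- ad_gather(tape, enc$g, ai[rows])
    gy <- ad_gather(tape, enc$g, bi[rows])
    if (config$score_mode == "fused") {
      s <- ad_bilinear(tape, gx, P[[paste0("pred.rel_", r)]], gy)
    } else {
      v2x <- ad_gather(tape, enc$v2D, ai[rows])
      v3x <- ad_gather(tape, enc$v3D, ai[rows])
      v2y <- ad_gather(tape, enc$v2D, bi[rows])
      v3y <- ad_gather(tape, enc$v3D, bi[rows])
      W <- P[[paste0("pred.rel_", r)]]
      s <- ad_add(tape, ad_bilinear(tape, v2x, W, v3y),
                  ad_bilinear(tape, v3x, W, v2y))
    }
    parts[[length(parts) + 1L]] <- s
    order_out <- c(order_out, rows)
  }
  stacked <- ad_concat_rows(tape, parts)
  ad_gather(tape, stacked, order(order_out))
}

# one full differentiable pass over a batch of positive (and negative)
# triples; returns loss nodes and diagnostics
model_loss_tape <- function(tape, P, positives, negatives, drug_data, config,
                            epoch0) {
  ids <- sort(unique(c(positives$drug_a, positives$drug_b,
                       negatives$drug_a, negatives$drug_b)))
  use_contrast <- config$use_contrast
  enc <- encode_drugs_tape(tape, P, ids, drug_data, config,
                           training = TRUE, two_views = use_contrast)
  idx <- function(x) match(x, ids)
  pos_scores <- score_triples_tape(tape, P, enc, idx(positives$drug_a),
                                   idx(positives$drug_b), positives$type, config)
  neg_scores <- score_triples_tape(tape, P, enc, idx(negatives$drug_a),
                                   idx(negatives$drug_b), negatives$type, config)
  z <- ad_concat_rows(tape, list(pos_scores, neg_scores))
  y <- c(rep(1, nrow(positives)), rep(0, nrow(negatives)))
  l_main <- ad_bce_with_logits(tape, z, y)

  gamma_t <- contrastive_weight(epoch0, config$ctr$gamma0, config$ctr$T)
  if (use_contrast && gamma_t > 0) {
    f1 <- ad_concat_cols(tape, list(
      ad_gather(tape, enc$g, idx(positives$drug_a)),
      ad_gather(tape, enc$g, idx(positives$drug_b))))
    f2 <- ad_concat_cols(tape, list(
      ad_gather(tape, enc$g2, idx(positives$drug_a)),
      ad_gather(tape, enc$g2, idx(positives$drug_b))))
    tau <- tau_tape(tape, P[["ctr.tau_raw"]], config$ctr$tau_bounds)
    losses <- lapply(config$ctr$scales, function(s) {
      infonce_scale_loss_tape(tape, f1, f2, tau, s)
    })
    w <- ad_softmax_rows(tape, P[["ctr.scale_logits"]])
    l_ctr <- ad_sum(tape, ad_mul(tape, w, ad_concat_cols(tape, losses)))
    total <- ad_add(tape, l_main, ad_affine_const(tape, l_ctr, gamma_t))
    tau_val <- tau$value[1]
  } else {
    l_ctr <- NULL
    total <- l_main
    tau_val <- tau_from_raw(P[["ctr.tau_raw"]]$value, config$ctr$tau_bounds)
  }
  list(total = total, l_main = l_main$value[1],
       l_contrast = if (is.null(l_ctr)) 0 else l_ctr$value[1],
       gamma = gamma_t, tau = tau_val)
}

# evaluation-mode drug embeddings as plain matrices (no rotation: the raw
# conformer pose is used, so scoring is deterministic)
encode_drugs_eval <- function(params, drug_ids, drug_data, config) {
  tape <- ad_tape()
  P <- ad_wrap_params(tape, params)
  graphs <- drug_data$graphs[drug_ids]
  b <- batch_graphs(graphs)
  topo <- topo2d_forward_tape(tape, b$node_feat, b$edges, b$edge_feat,
                              b$graph_index, b$n_graphs, P, config$topo)
  H2D <- topo$H2D
  M <- b$n_graphs
  d <- config$d
  if (config$use_3d) {
    coords <- lapply(drug_ids, function(id) drug_data$conformers[[id]]$coordinates)
    geo <- lapply(coords, function(X) {
      g <- compute_center_and_distances(X)
      list(d = g$distances, v = compute_directions(X, g$center, config$spat$epsilon))
    })
    Xall <- do.call(rbind, coords)
    dall <- matrix(unlist(lapply(geo, `[[`, "d")), ncol = 1)
    vall <- do.call(rbind, lapply(geo, `[[`, "v"))
    f_pos <- mlp2_forward(tape, ad_const(tape, Xall), P, "spat.pos", FALSE)
    f_dist <- mlp2_forward(tape, ad_const(tape, dall), P, "spat.dist", FALSE)
    f_angle <- mlp2_forward(tape, ad_const(tape, vall), P, "spat.ang", FALSE)
    f_comb <- ad_concat_cols(tape, list(f_pos, f_dist, f_angle))
    s <- ad_add_bias(tape, ad_matmul(tape, f_comb, P[["spat.fuse_W"]]),
                     P[["spat.fuse_b"]])
    s <- ad_relu(tape, s)
    H3D <- ad_layernorm(tape, s, P[["spat.fuse_g"]], P[["spat.fuse_c"]])
  } else {
    H3D <- NULL
  }
  if (!config$use_3d) {
    v2D <- ad_mean_group(tape, H2D, b$graph_index, M)$value
    v3D <- matrix(0, M, d)
  } else if (!config$use_dfe) {
    v2D <- ad_mean_group(tape, H2D, b$graph_index, M)$value
    v3D <- ad_mean_group(tape, H3D, b$graph_index, M)$value
  } else {
    res <- dfe_chunked_tape(tape, H2D, H3D, P, d, b$graph_index)
    v2D <- ad_mean_group(tape, res$H2D_tilde, b$graph_index, M)$value
    v3D <- ad_mean_group(tape, res$H3D_tilde, b$graph_index, M)$value
  }
  g <- fuse_drug_embedding(v2D, v3D, params)
  list(ids = drug_ids, g = g, v2D = v2D, v3D = v3D)
}

# plain-math triple scores from evaluation embeddings
score_triples_eval <- function(params, enc, triples, config) {
  idx <- function(x) match(x, enc$ids)
  ai <- idx(triples$drug_a); bi <- idx(triples$drug_b)
  vapply(seq_len(nrow(triples)), function(i) {
    W <- params[[paste0("pred.rel_", triples$type[i])]]
    if (is.null(W)) stop("unknown relation index: ", triples$type[i], call. = FALSE)
    if (config$score_mode == "fused") {
      as.numeric(enc$g[ai[i], ] %*% W %*% enc$g[bi[i], ])
    } else {
      as.numeric(enc$v2D[ai[i], ] %*% W %*% enc$v3D[bi[i], ] +
                 enc$v3D[ai[i], ] %*% W %*% enc$v2D[bi[i], ])
    }
  }, numeric(1))
}
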