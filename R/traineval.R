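# Dataset splitting (warm triple-level and drug-level cold-start), the
# training loop (AdamW, cosine annealing, annealed contrastive weight,
# ablation switches), evaluation against 1:1 corrupted negatives, and the
# ablation suite.

#' Drug-level cold-start split
#'
#' Samples a fraction of drugs into the unseen set `G_new`; triples are
#' routed by membership: both drugs seen -> `train`, both unseen -> `s1`,
#' exactly one unseen -> `s2`. The three partitions are disjoint and cover
#' the input exactly.
#'
#' @param triples Tibble with `drug_a`, `drug_b`, `type`.
#' @param drugs Character vector of all drug ids (or a registry tibble with
#'   an `id` column); defaults to the drugs present in `triples`.
#' @param fraction Fraction of drugs assigned to `G_new` (default 1/5).
#' @param seed Split seed.
#' @return A `split_spec` with `g_new`, `g_old` and partitions `train`,
#'   `s1`, `s2`.
#' @export
cold_start_split <- function(triples, drugs = NULL, fraction = 0.2, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  if (is.data.frame(drugs)) drugs <- drugs$id
  if (is.null(drugs)) drugs <- sort(unique(c(triples$drug_a, triples$drug_b)))
  drugs <- as.character(drugs)
  stopifnot(length(drugs) >= 2)
  n_new <- max(1L, round(fraction * length(drugs)))
  g_new <- with_seed(seed, sample(drugs, n_new))
  g_old <- setdiff(drugs, g_new)
  a_new <- triples$drug_a %in% g_new
  b_new <- triples$drug_b %in% g_new
  parts <- list(
    train = triples[!a_new & !b_new, , drop = FALSE],
    s1 = triples[a_new & b_new, , drop = FALSE],
    s2 = triples[xor(a_new, b_new), , drop = FALSE]
  )
  if (nrow(parts$s1) == 0) {
    warning("cold-start routing left the S1 (new,new) partition empty",
            call. = FALSE)
  }
  structure(list(mode = "cold", fraction = fraction, seed = seed,
                 g_new = sort(g_new), g_old = sort(g_old),
                 partitions = parts),
            class = "split_spec")
}

#' Warm-start (transductive) split
#'
#' Random triple-level split; test drugs may also appear in training.
#'
#' @param triples Tibble with `drug_a`, `drug_b`, `type`.
#' @param props Proportions for train/valid/test (sum to 1).
#' @param seed Split seed.
#' @return A `split_spec` with partitions `train`, `valid`, `test`.
#' @export
warm_split <- function(triples, props = c(train = 0.7, valid = 0.1, test = 0.2),
                       seed = 1L) {
  stopifnot(abs(sum(props) - 1) < 1e-8, all(props >= 0))
  n <- nrow(triples)
  idx <- with_seed(seed, sample.int(n))
  n_train <- floor(props[1] * n)
  n_valid <- floor(props[2] * n)
  parts <- list(
    train = triples[idx[seq_len(n_train)], , drop = FALSE],
    valid = triples[idx[n_train + seq_len(n_valid)], , drop = FALSE],
    test = triples[idx[(n_train + n_valid + 1):n], , drop = FALSE]
  )
  structure(list(mode = "warm", seed = seed, partitions = parts),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  sizes <- vapply(x$partitions, nrow, integer(1))
  cat("<split_spec mode=", x$mode, "> ",
      paste(names(sizes), sizes, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Train the interaction model
#'
#' Runs AdamW with cosine-annealed learning rate on the combined objective
#' `L_main + gamma(t) * L_contrast`. All stochastic draws (initialisation,
#' conformer rotations, negative corruption, shuffling, dropout) come from
#' one seeded stream, so a fixed seed reproduces the run exactly within a
#' session (conformers are memoised per session; export them with
#' [write_conformer_sdf()] to pin geometries across sessions).
#'
#' @param registry Tibble with `id`, `smiles` covering every drug referenced.
#' @param triples Positive training triples (`drug_a`, `drug_b`, `type`).
#' @param config A [ddi_config()].
#' @param valid Optional validation triples; when given, validation metrics
#'   are appended to the history every `eval_every` epochs.
#' @param negatives Optional explicit negative triples (label 0). When
#'   absent, negatives are corrupted from the positives each epoch.
#' @param drug_data Optional precomputed [prepare_drug_data()] result.
#' @param verbose Print per-epoch progress.
#' @return A `ddi_fit`: parameters, config, type vocabulary, history tibble.
#' @export
train_ddi <- function(registry, triples, config = ddi_config(), valid = NULL,
                      negatives = NULL, drug_data = NULL, verbose = FALSE) {
  stopifnot(nrow(triples) >= 1)
  vocab <- sort(unique(c(triples$type, valid$type, negatives$type)))
  recode <- function(tt) {
    tt$type <- match(tt$type, vocab)
    tt
  }
  triples_r <- recode(triples)
  negatives_r <- if (!is.null(negatives)) recode(negatives)
  if (is.null(drug_data)) drug_data <- prepare_drug_data(registry, verbose)
  params <- ddi_model_init(config, length(vocab))
  state <- adamw_state(params)
  nd <- no_decay_names(params)
  drug_set <- registry$id
  history <- vector("list", config$epochs)

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- cosine_lr(epoch, config$epochs, config$lr)
      ord <- sample.int(nrow(triples_r))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_main <- 0; ep_ctr <- 0; ep_gamma <- NA_real_; ep_tau <- NA_real_
      for (bt in batches) {
        pos <- triples_r[bt, , drop = FALSE]
        neg <- if (is.null(negatives_r)) {
          dplyr::bind_rows(lapply(seq_len(config$negative_ratio), function(k) {
            sample_negatives(pos, drug_set, known = triples_r)
          }))
        } else if (nrow(negatives_r) == nrow(triples_r)) {
          # row-matched explicit negatives follow their positives
          negatives_r[bt, , drop = FALSE]
        } else {
          negatives_r
        }
        tape <- ad_tape()
        P <- ad_wrap_params(tape, params)
        out <- model_loss_tape(tape, P, pos, neg, drug_data, config, epoch - 1L)
        if (!is.finite(out$total$value[1])) {
          stop("training diverged at epoch ", epoch,
               " (loss = ", out$total$value[1], "); lower the learning rate",
               call. = FALSE)
        }
        ad_backward(tape, out$total)
        grads <- ad_collect_grads(P)
        upd <- adamw_step(params, grads, state, lr,
                          weight_decay = config$weight_decay, no_decay = nd)
        params <- upd$params
        state <- upd$state
        w <- nrow(pos) / nrow(triples_r)
        ep_main <- ep_main + w * out$l_main
        ep_ctr <- ep_ctr + w * out$l_contrast
        ep_gamma <- out$gamma
        ep_tau <- out$tau
      }
      row <- tibble::tibble(
        epoch = epoch, lr = lr, L_main = ep_main, L_contrast = ep_ctr,
        gamma = ep_gamma, tau = ep_tau,
        loss = ep_main + ep_gamma * ep_ctr
      )
      if (!is.null(valid) && (epoch %% config$eval_every == 0L ||
                              epoch == config$epochs)) {
        fit_tmp <- new_ddi_fit(params, config, vocab, registry, drug_data, NULL)
        vm <- evaluate_ddi(fit_tmp, valid, drug_set = drug_set,
                           seed = config$seed + 10000L, n_draws = 3L)
        row <- dplyr::bind_cols(row, dplyr::rename_with(vm, ~ paste0("valid_", .x)))
      }
      history[[epoch]] <- row
      if (!is.null(config$early_stop_auroc) && "valid_AUROC" %in% names(row) &&
          isTRUE(row$valid_AUROC >= config$early_stop_auroc)) {
        if (verbose) message("early stop at epoch ", epoch)
        break
      }
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  (main %.4f, contrast %.4f, gamma %.3f, tau %.3f)",
                        epoch, row$loss, ep_main, ep_ctr, ep_gamma, ep_tau))
      }
    }
  })
  new_ddi_fit(params, config, vocab, registry, drug_data,
              dplyr::bind_rows(history))
}

new_ddi_fit <- function(params, config, vocab, registry, drug_data, history) {
  structure(list(params = params, config = config, vocab = vocab,
                 registry = registry, drug_data = drug_data,
                 history = history),
            class = "ddi_fit")
}

#' @export
print.ddi_fit <- function(x, ...) {
  cat("<ddi_fit> ", length(x$vocab), " interaction types, ",
      nrow(x$registry), " drugs", sep = "")
  if (!is.null(x$history)) {
    cat(", ", max(x$history$epoch), " epochs, final loss ",
        sprintf("%.4f", x$history$loss[nrow(x$history)]), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Score interaction triples with a fitted model
#'
#' Evaluation is deterministic: the unrotated conformer pose is used and
#' dropout is off.
#'
#' @param object A `ddi_fit`.
#' @param pairs Tibble with `drug_a`, `drug_b`, `type` (types in the fit's
#'   vocabulary).
#' @param ... Unused.
#' @return `pairs` with `score` and `probability` columns appended.
#' @export
predict.ddi_fit <- function(object, pairs, ...) {
  fit <- object
  tt <- pairs
  unknown_t <- setdiff(unique(tt$type), fit$vocab)
  if (length(unknown_t)) {
    stop("unknown interaction type(s): ", paste(unknown_t, collapse = ", "),
         call. = FALSE)
  }
  tt$type <- match(tt$type, fit$vocab)
  ids <- sort(unique(c(tt$drug_a, tt$drug_b)))
  missing_ids <- setdiff(ids, names(fit$drug_data$graphs))
  if (length(missing_ids)) {
    stop("drugs not in the fitted registry: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  enc <- encode_drugs_eval(fit$params, ids, fit$drug_data, fit$config)
  sc <- score_triples_eval(fit$params, enc, tt, fit$config)
  dplyr::mutate(pairs, score = sc, probability = stats::plogis(sc))
}

#' Score one drug pair given as SMILES
#'
#' Builds temporary graph/conformer entries for the two molecules and scores
#' the requested interaction type.
#'
#' @param fit A `ddi_fit`.
#' @param smiles_a,smiles_b SMILES strings.
#' @param type Interaction type (must be in the fit's vocabulary).
#' @return A one-row tibble with `score` and `probability`.
#' @export
predict_smiles <- function(fit, smiles_a, smiles_b, type) {
  reg <- tibble::tibble(id = c(".a", ".b"), smiles = c(smiles_a, smiles_b))
  dd <- prepare_drug_data(reg)
  fit2 <- fit
  fit2$drug_data <- list(graphs = c(fit$drug_data$graphs, dd$graphs),
                         conformers = c(fit$drug_data$conformers, dd$conformers))
  fit2$registry <- dplyr::bind_rows(fit$registry, reg)
  out <- predict.ddi_fit(fit2, tibble::tibble(drug_a = ".a", drug_b = ".b",
                                              type = type))
  dplyr::select(out, "score", "probability")
}

#' Evaluate a fitted model on positive triples
#'
#' Scores the positives plus an equal number of corrupted negatives (drawn
#' with a fixed evaluation seed), then computes ACC and F1 at probability
#' 0.5 and AUROC/AP over the scores. Pass explicit `negatives` to override
#' the corruption protocol (e.g. matched stereo counterfactuals).
#'
#' @param fit A `ddi_fit`.
#' @param triples Positive triples.
#' @param drug_set Candidate drugs for corruption (defaults to the fit's
#'   registry).
#' @param negatives Optional explicit negative triples.
#' @param seed Evaluation seed for the corruption draw.
#' @return A one-row tibble with `ACC`, `AUROC`, `AP`, `F1`.
#' @export
evaluate_ddi <- function(fit, triples, drug_set = NULL, negatives = NULL,
                         seed = 7L, n_draws = 1L) {
  stopifnot(nrow(triples) >= 1)
  if (is.null(drug_set)) drug_set <- fit$registry$id
  ppos <- predict.ddi_fit(fit, triples)
  if (!is.null(negatives)) {
    pneg <- predict.ddi_fit(fit, negatives[, c("drug_a", "drug_b", "type")])
    return(classification_metrics(
      c(rep(1L, nrow(ppos)), rep(0L, nrow(pneg))),
      c(ppos$probability, pneg$probability)))
  }
  draws <- lapply(seq_len(n_draws), function(k) {
    neg <- with_seed(seed + k - 1L, sample_negatives(triples, drug_set))
    pneg <- predict.ddi_fit(fit, neg[, c("drug_a", "drug_b", "type")])
    classification_metrics(
      c(rep(1L, nrow(ppos)), rep(0L, nrow(pneg))),
      c(ppos$probability, pneg$probability))
  })
  # metrics averaged over corruption draws
  dplyr::summarise(dplyr::bind_rows(draws), dplyr::across(dplyr::everything(), mean))
}

#' Run the ablation suite
#'
#' Trains and evaluates the requested variants on identical splits and
#' seeds. Variants: `full`, `wo_3d`, `wo_DFE`, `wo_contrast`,
#' `wo_3d_contrast`, plus `scale_<s...>` entries restricting the contrastive
#' scales (e.g. `scale_4`, `scale_1_2`).
#'
#' @param registry Drug registry.
#' @param split A `split_spec` (warm: evaluated on `test`; cold: on `s1`
#'   and `s2`).
#' @param config Base [ddi_config()].
#' @param variants Character vector of variant names.
#' @param verbose Print progress.
#' @return A tibble with one row per variant (and per cold partition).
#' @export
run_ablation_suite <- function(registry, split, config = ddi_config(),
                               variants = c("full", "wo_3d", "wo_DFE",
                                            "wo_contrast", "wo_3d_contrast"),
                               verbose = FALSE) {
  apply_variant <- function(cfg, v) {
    if (v == "full") return(cfg)
    if (v == "wo_3d") { cfg$use_3d <- FALSE; return(cfg) }
    if (v == "wo_DFE") { cfg$use_dfe <- FALSE; return(cfg) }
    if (v == "wo_contrast") { cfg$use_contrast <- FALSE; return(cfg) }
    if (v == "wo_3d_contrast") { cfg$use_3d <- FALSE; cfg$use_contrast <- FALSE; return(cfg) }
    if (grepl("^scale_", v)) {
      sc <- as.integer(strsplit(sub("^scale_", "", v), "_")[[1]])
      cfg$ctr$scales <- sc
      return(cfg)
    }
    stop("unknown ablation variant: ", v, call. = FALSE)
  }
  train_part <- split$partitions$train
  eval_parts <- if (split$mode == "cold") {
    split$partitions[intersect(c("s1", "s2"), names(split$partitions))]
  } else {
    split$partitions["test"]
  }
  valid <- split$partitions$valid
  drug_data <- prepare_drug_data(registry)
  purrr::map_dfr(variants, function(v) {
    cfg <- apply_variant(config, v)
    fit <- train_ddi(registry, train_part, cfg, valid = NULL,
                     drug_data = drug_data, verbose = verbose)
    purrr::map_dfr(names(eval_parts), function(pn) {
      part <- eval_parts[[pn]]
      if (nrow(part) == 0) return(tibble::tibble())
      dplyr::bind_cols(tibble::tibble(variant = v, partition = pn),
                       evaluate_ddi(fit, part, drug_set = registry$id,
                                    seed = config$seed + 10000L))
    })
  })
}

# ---- broom-style accessors and plots ----------------------------------------

#' Tidy the training history of a fit
#'
#' @param x A `ddi_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @method tidy ddi_fit
#' @export
tidy.ddi_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x A `ddi_fit`.
#' @param ... Unused.
#' @return Tibble with the final losses and schedule state.
#' @method glance ddi_fit
#' @export
glance.ddi_fit <- function(x, ...) {
  h <- x$history
  last <- h[nrow(h), ]
  tibble::tibble(epochs = nrow(h), loss = last$loss, L_main = last$L_main,
                 L_contrast = last$L_contrast, gamma = last$gamma,
                 tau = last$tau, n_types = length(x$vocab),
                 n_drugs = nrow(x$registry))
}

#' Plot the training history
#'
#' Loss components and the annealing/temperature schedules per epoch.
#'
#' @param object A `ddi_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddi_fit
#' @export
autoplot.ddi_fit <- function(object, ...) {
  h <- object$history
  long <- tidyr::pivot_longer(
    dplyr::select(h, "epoch", "loss", "L_main", "L_contrast", "gamma", "tau"),
    -"epoch", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' Plot an ablation-suite result table
#'
#' @param metrics Output of [run_ablation_suite()].
#' @param metric Which metric column to show.
#' @return A ggplot object.
#' @export
plot_ablation <- function(metrics, metric = "AUROC") {
  ggplot2::ggplot(metrics,
                  ggplot2::aes(x = .data$variant, y = .data[[metric]],
                               fill = .data$partition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
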