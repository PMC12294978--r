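# Triple scoring: each drug's two modality vectors are fused to a single
# 64-dim embedding by a learned linear map of their concatenation, and a
# (drug_a, drug_b, relation) triple is scored with the RESCAL bilinear form
# g_a' W_r g_b. The main task is binary cross-entropy against 1:1 corrupted
# negatives. An alternative `cross_modal` scoring mode couples v2D of one
# drug with v3D of the other under the same relation matrix.

#' Initialise predictor parameters
#'
#' @param d Modality vector width (64).
#' @param n_types Number of interaction types (one 64 x 64 relation matrix
#'   each).
#' @return Named list with `pred.fuse_W` (2d x d), `pred.fuse_b`, and
#'   `pred.rel_<r>` for r in `1..n_types`.
#' @export
predictor_init <- function(d = 64L, n_types) {
  stopifnot(n_types >= 1)
  p <- list(fuse_W = init_matrix(2L * d, d), fuse_b = matrix(0, 1, d))
  for (r in seq_len(n_types)) {
    p[[paste0("rel_", r)]] <- init_matrix(d, d)
  }
  names(p) <- paste0("pred.", names(p))
  p
}

#' Fuse a drug's modality vectors into one embedding
#'
#' `g = [v2D ; v3D] W + b`, a deterministic linear map from `2d` to `d`.
#'
#' @param v2D,v3D Modality vectors (length d each), or matrices with one row
#'   per drug.
#' @param params Parameters from [predictor_init()].
#' @return A length-d vector (or n x d matrix for matrix input).
#' @export
fuse_drug_embedding <- function(v2D, v3D, params) {
  single <- is.null(dim(v2D))
  v2D <- if (single) matrix(v2D, 1) else as.matrix(v2D)
  v3D <- if (is.null(dim(v3D))) matrix(v3D, 1) else as.matrix(v3D)
  stopifnot(ncol(v2D) == ncol(v3D), nrow(v2D) == nrow(v3D),
            2L * ncol(v2D) == nrow(params[["pred.fuse_W"]]))
  g <- cbind(v2D, v3D) %*% params[["pred.fuse_W"]]
  g <- sweep(g, 2L, as.numeric(params[["pred.fuse_b"]]), "+")
  if (single) as.numeric(g) else g
}

#' RESCAL bilinear score of a drug pair under one relation
#'
#' `score = g_x' W_r g_y`; the interaction probability is `plogis(score)`.
#'
#' @param g_x,g_y Drug embeddings (length-d vectors).
#' @param r Relation index (1-based position in the type vocabulary).
#' @param relation_tensor Either a list of d x d matrices or a parameter list
#'   containing `pred.rel_<r>` entries.
#' @return The scalar score.
#' @export
rescal_score <- function(g_x, g_y, r, relation_tensor) {
  W <- if (!is.null(relation_tensor[[paste0("pred.rel_", r)]])) {
    relation_tensor[[paste0("pred.rel_", r)]]
  } else if (r >= 1 && r <= length(relation_tensor)) {
    relation_tensor[[r]]
  } else {
    stop("unknown relation index: ", r, call. = FALSE)
  }
  if (is.null(W)) stop("unknown relation index: ", r, call. = FALSE)
  as.numeric(matrix(g_x, 1) %*% W %*% matrix(g_y, ncol = 1))
}

#' Corrupt positive triples into negatives
#'
#' For each positive, one corrupted triple is drawn: with probability 0.5 the
#' first drug is replaced, otherwise the second, uniformly over `drug_set`.
#' Corruptions that recreate a known positive (same pair and type, in either
#' orientation) are rejected and redrawn up to `max_tries` times, after which
#' the collision is accepted and flagged.
#'
#' @param triples Tibble with `drug_a`, `drug_b`, `type`.
#' @param drug_set Character vector of candidate replacement drug ids.
#' @param known Optional tibble of all known positives used for rejection
#'   (defaults to `triples`).
#' @param max_tries Rejection cap per negative.
#' @return A tibble like `triples` with an added logical column `collision`.
#' @export
sample_negatives <- function(triples, drug_set, known = triples, max_tries = 20L) {
  stopifnot(length(drug_set) >= 1)
  key <- function(a, b, r) {
    paste(pmin(a, b), pmax(a, b), r, sep = "\r")
  }
  known_keys <- key(known$drug_a, known$drug_b, known$type)
  n <- nrow(triples)
  out_a <- triples$drug_a
  out_b <- triples$drug_b
  collision <- logical(n)
  side <- stats::runif(n) < 0.5
  for (i in seq_len(n)) {
    ok <- FALSE
    for (k in seq_len(max_tries)) {
      cand <- drug_set[sample.int(length(drug_set), 1L)]
      a <- if (side[i]) cand else triples$drug_a[i]
      b <- if (side[i]) triples$drug_b[i] else cand
      if (a == b) next
      if (!(key(a, b, triples$type[i]) %in% known_keys)) {
        out_a[i] <- a; out_b[i] <- b; ok <- TRUE
        break
      }
      # remember the last candidate in case every draw collides
      out_a[i] <- a; out_b[i] <- b
    }
    collision[i] <- !ok
  }
  tibble::tibble(drug_a = out_a, drug_b = out_b, type = triples$type,
                 collision = collision)
}

#' Main-task loss: mean binary cross-entropy over positives and negatives
#'
#' Scores are logits; positives carry label 1, negatives label 0.
#'
#' @param positive_scores,negative_scores Numeric score vectors (equal
#'   length).
#' @return The scalar loss.
#' @export
main_loss <- function(positive_scores, negative_scores) {
  stopifnot(length(positive_scores) == length(negative_scores),
            length(positive_scores) > 0)
  z <- c(positive_scores, negative_scores)
  y <- c(rep(1, length(positive_scores)), rep(0, length(negative_scores)))
  sp <- pmax(z, 0) + log1p(exp(-abs(z)))
  mean(sp - y * z)
}
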