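# Multiscale InfoNCE contrastive learning over drug-pair representations.
# A pair representation is the concatenation of the two fused drug embeddings
# (width 128); its second view recomputes the 3D pathway from an
# independently rotated conformer. Each scale s in {1, 2, 4} mean-pools the
# representation along the feature axis with window = stride = s, L2
# normalises, and takes an in-batch InfoNCE loss with temperature tau
# (learnable, hard-bounded in [0.1, 2.0] by a logistic reparameterisation).
# Per-scale losses are combined with softmax weights over three learnable
# logits, and the combined loss enters the total objective with a linearly
# annealed coefficient gamma(t) = gamma0 * (1 - t/T).

#' Contrastive-learning configuration
#'
#' @param scales Feature-axis pooling scales; each must divide the pair
#'   representation width.
#' @param tau_bounds Hard lower/upper bounds for the learnable temperature.
#' @param gamma0 Initial contrastive weight (0.1).
#' @param T Annealing horizon in epochs (500); `gamma` reaches 0 at `t = T`
#'   and is clamped at 0 beyond it, regardless of the training budget.
#' @return A `contrastive_config` list.
#' @export
contrastive_config <- function(scales = c(1L, 2L, 4L), tau_bounds = c(0.1, 2.0),
                               gamma0 = 0.1, T = 500L) {
  stopifnot(length(tau_bounds) == 2, tau_bounds[1] > 0,
            tau_bounds[1] < tau_bounds[2], gamma0 >= 0, T >= 1)
  structure(list(scales = as.integer(scales), tau_bounds = tau_bounds,
                 gamma0 = gamma0, T = as.integer(T)),
            class = "contrastive_config")
}

#' Initialise contrastive parameters
#'
#' @param config A [contrastive_config()]; the raw temperature starts at the
#'   midpoint of its bounds, the scale logits at zero (uniform weights).
#' @return Named list with `ctr.tau_raw` and `ctr.scale_logits`.
#' @export
contrastive_init <- function(config = contrastive_config()) {
  list(ctr.tau_raw = matrix(0, 1, 1),
       ctr.scale_logits = matrix(0, 1, length(config$scales)))
}

#' Map the raw temperature parameter into its bounds
#'
#' `tau = lo + (hi - lo) * plogis(tau_raw)`: the bounds are a hard
#' constraint, so the temperature can never escape them during optimisation.
#'
#' @param tau_raw Unconstrained scalar.
#' @param bounds Length-2 vector `(lo, hi)`.
#' @return The temperature.
#' @export
tau_from_raw <- function(tau_raw, bounds = c(0.1, 2.0)) {
  bounds[1] + (bounds[2] - bounds[1]) * stats::plogis(as.numeric(tau_raw))
}

tau_tape <- function(tape, tau_raw_node, bounds) {
  ad_affine_const(tape, ad_sigmoid(tape, tau_raw_node),
                  mult = bounds[2] - bounds[1], add = bounds[1])
}

#' Mean-pool a representation along the feature axis
#'
#' Non-overlapping window means with window = stride = `s`; `s = 1` is the
#' identity.
#'
#' @param f Numeric vector (length D) or matrix (N x D).
#' @param s Scale; must divide D.
#' @return Vector of length `D/s` (or N x D/s matrix).
#' @export
scale_pool <- function(f, s) {
  vec <- is.null(dim(f))
  m <- if (vec) matrix(f, 1) else as.matrix(f)
  D <- ncol(m)
  s <- as.integer(s)
  if (D %% s != 0L) stop("scale ", s, " does not divide width ", D, call. = FALSE)
  if (s == 1L) return(if (vec) as.numeric(m) else m)
  out <- matrix(0, nrow(m), D %/% s)
  for (k in seq_len(s)) out <- out + m[, seq(k, D, by = s), drop = FALSE]
  out <- out / s
  if (vec) as.numeric(out) else out
}

# tape version (constant reindexing, differentiable through the averaging)
scale_pool_tape <- function(tape, f, s) {
  D <- ncol(f$value)
  s <- as.integer(s)
  stopifnot(D %% s == 0L)
  if (s == 1L) return(f)
  parts <- lapply(seq_len(s), function(k) {
    sel <- seq(k, D, by = s)
    ad_new(tape, f$value[, sel, drop = FALSE], list(f), local({
      sel_k <- sel
      function(g) {
        full <- matrix(0, nrow(f$value), D)
        full[, sel_k] <- g
        ad_accum(f, full)
      }
    }))
  })
  acc <- parts[[1]]
  for (k in 2:s) acc <- ad_add(tape, acc, parts[[k]])
  ad_affine_const(tape, acc, 1 / s)
}

#' L2-normalise a vector or the rows of a matrix
#'
#' Zero vectors are returned unchanged with a warning.
#'
#' @param f Numeric vector or matrix.
#' @return Same shape, unit Euclidean norm per row.
#' @export
l2_normalize <- function(f) {
  vec <- is.null(dim(f))
  m <- if (vec) matrix(f, 1) else as.matrix(f)
  nr <- sqrt(rowSums(m^2))
  if (any(nr == 0)) {
    warning("zero vector passed to l2_normalize; returned unchanged", call. = FALSE)
  }
  out <- m / ifelse(nr == 0, 1, nr)
  if (vec) as.numeric(out) else out
}

#' Temperature-scaled cosine similarity matrix
#'
#' `S = F1 F2' / tau` for row-normalised inputs.
#'
#' @param F1,F2 N x D matrices with unit-norm rows.
#' @param tau Temperature.
#' @return N x N matrix.
#' @export
similarity_matrix <- function(F1, F2, tau) {
  stopifnot(ncol(F1) == ncol(F2))
  (as.matrix(F1) %*% t(as.matrix(F2))) / tau
}

#' InfoNCE loss at one scale
#'
#' Both views are pooled to scale `s` and L2-normalised; sample i's positive
#' is its second view, and the denominator adds the `2(N-1)` in-batch
#' negatives (other samples' first and second views). A batch of one has no
#' negatives and the loss is exactly 0.
#'
#' @param F1,F2 N x D matrices: view 1 and view 2 of the batch.
#' @param tau Temperature.
#' @param s Pooling scale.
#' @return Scalar loss (nonnegative).
#' @export
infonce_scale_loss <- function(F1, F2, tau, s = 1L) {
  F1 <- as.matrix(F1); F2 <- as.matrix(F2)
  stopifnot(nrow(F1) == nrow(F2), ncol(F1) == ncol(F2), tau > 0)
  n <- nrow(F1)
  if (n == 1L) return(0)
  f1 <- suppressWarnings(l2_normalize(scale_pool(F1, s)))
  f2 <- suppressWarnings(l2_normalize(scale_pool(F2, s)))
  s_cross <- similarity_matrix(f1, f2, tau)
  s_self <- similarity_matrix(f1, f1, tau)
  diag(s_self) <- -Inf
  m <- pmax(apply(s_cross, 1, max), apply(s_self, 1, max))
  den <- rowSums(exp(s_cross - m)) + rowSums(exp(s_self - m))
  mean(log(den) + m - diag(s_cross))
}

infonce_scale_loss_tape <- function(tape, F1, F2, tau_node, s) {
  f1 <- ad_l2norm_rows(tape, scale_pool_tape(tape, F1, s))
  f2 <- ad_l2norm_rows(tape, scale_pool_tape(tape, F2, s))
  s_cross <- ad_div_scalar(tape, ad_matmul(tape, f1, ad_transpose(tape, f2)), tau_node)
  s_self <- ad_div_scalar(tape, ad_matmul(tape, f1, ad_transpose(tape, f1)), tau_node)
  ad_infonce(tape, s_cross, s_self)
}

#' Softmax weights over the scale logits
#'
#' @param scale_logits Numeric vector (one logit per scale).
#' @return Nonnegative weights summing to 1.
#' @export
scale_weights <- function(scale_logits) {
  z <- as.numeric(scale_logits)
  e <- exp(z - max(z))
  e / sum(e)
}

#' Weighted multiscale contrastive loss
#'
#' @param scale_losses Per-scale InfoNCE losses.
#' @param weights Weights from [scale_weights()] (sum to 1).
#' @return Scalar combined loss.
#' @export
multiscale_loss <- function(scale_losses, weights) {
  stopifnot(length(scale_losses) == length(weights))
  sum(as.numeric(scale_losses) * as.numeric(weights))
}

#' Annealed contrastive weight
#'
#' `gamma(t) = gamma0 * (1 - t/T)`, clamped at 0 for `t > T`.
#'
#' @param t Current epoch (0-based, as in the schedule definition).
#' @param gamma0 Initial weight.
#' @param T Annealing horizon in epochs.
#' @return The contrastive weight at epoch `t`.
#' @export
contrastive_weight <- function(t, gamma0 = 0.1, T = 500L) {
  stopifnot(all(t >= 0))
  pmax(gamma0 * (1 - t / T), 0)
}

#' Combined training objective
#'
#' `L = L_main + gamma(t) * L_total`.
#'
#' @param L_main Main-task loss.
#' @param L_total Multiscale contrastive loss.
#' @param t Current epoch.
#' @param gamma0,T Annealing parameters.
#' @return Scalar total loss.
#' @export
total_loss <- function(L_main, L_total, t, gamma0 = 0.1, T = 500L) {
  L_main + contrastive_weight(t, gamma0, T) * L_total
}
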