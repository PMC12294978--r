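# Reverse-mode automatic differentiation on dense matrices.
#
# Every value on the tape is a numeric matrix (scalars are 1x1). Nodes are
# environments holding `value`, a lazily allocated `grad`, the parent nodes and
# a `backward` closure that pushes the node's gradient into its parents.
# `ad_backward()` walks the tape in reverse creation order, so any expression
# built through the `ad_*` ops is differentiable end to end. The op set is the
# minimum the model needs: affine maps, pointwise nonlinearities, gather /
# grouped reductions for batched molecular graphs, row softmax (attention),
# layer normalisation, and fused losses (binary cross-entropy with logits,
# InfoNCE) whose gradients are hand-derived for stability.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

as_ad_matrix <- function(x) {
  if (is.matrix(x) && is.double(x)) return(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  x
}

ad_new <- function(tape, value, parents = list(), backward = NULL, track = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- as_ad_matrix(value)
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  if (is.null(track)) {
    track <- any(vapply(parents, function(p) isTRUE(p$track), logical(1)))
  }
  n$track <- track
  if (track) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$n]] <- n
    n$id <- tape$n
  }
  n
}

#' @noRd
ad_leaf <- function(tape, value) ad_new(tape, value, track = TRUE)
ad_const <- function(tape, value) ad_new(tape, value, track = FALSE)

ad_accum <- function(node, g) {
  if (!isTRUE(node$track)) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar loss node through the whole tape.
ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  if (tape$n == 0L) return(invisible(NULL))
  for (i in seq(tape$n, 1L)) {
    n <- tape$nodes[[i]]
    if (!is.null(n$grad) && !is.null(n$backward)) n$backward(n$grad)
  }
  invisible(NULL)
}

# ---- arithmetic -------------------------------------------------------------

ad_matmul <- function(tape, a, b) {
  ad_new(tape, a$value %*% b$value, list(a, b), function(g) {
    ad_accum(a, tcrossprod(g, b$value))
    ad_accum(b, crossprod(a$value, g))
  })
}

ad_add <- function(tape, a, b) {
  stopifnot(all(dim(a$value) == dim(b$value)))
  ad_new(tape, a$value + b$value, list(a, b), function(g) {
    ad_accum(a, g); ad_accum(b, g)
  })
}

ad_sub <- function(tape, a, b) {
  ad_new(tape, a$value - b$value, list(a, b), function(g) {
    ad_accum(a, g); ad_accum(b, -g)
  })
}

ad_mul <- function(tape, a, b) {
  stopifnot(all(dim(a$value) == dim(b$value)))
  ad_new(tape, a$value * b$value, list(a, b), function(g) {
    ad_accum(a, g * b$value); ad_accum(b, g * a$value)
  })
}

# bias is 1 x D, broadcast over the rows of a
ad_add_bias <- function(tape, a, bias) {
  n <- nrow(a$value)
  v <- a$value + matrix(bias$value, n, ncol(a$value), byrow = TRUE)
  ad_new(tape, v, list(a, bias), function(g) {
    ad_accum(a, g)
    ad_accum(bias, matrix(colSums(g), 1L))
  })
}

ad_affine_const <- function(tape, a, mult = 1, add = 0) {
  ad_new(tape, a$value * mult + add, list(a), function(g) ad_accum(a, g * mult))
}

# s is a 1x1 node
ad_mul_scalar <- function(tape, a, s) {
  sv <- s$value[1L]
  ad_new(tape, a$value * sv, list(a, s), function(g) {
    ad_accum(a, g * sv)
    ad_accum(s, matrix(sum(g * a$value), 1L, 1L))
  })
}

ad_div_scalar <- function(tape, a, s) {
  sv <- s$value[1L]
  ad_new(tape, a$value / sv, list(a, s), function(g) {
    ad_accum(a, g / sv)
    ad_accum(s, matrix(-sum(g * a$value) / sv^2, 1L, 1L))
  })
}

# multiply each row of a by the matching entry of a column-vector node v (n x 1)
ad_mul_colvec <- function(tape, a, v) {
  vv <- as.numeric(v$value)
  ad_new(tape, a$value * vv, list(a, v), function(g) {
    ad_accum(a, g * vv)
    ad_accum(v, matrix(rowSums(g * a$value), ncol = 1L))
  })
}

# scale row i of a by w[i] (constant weights), used for per-graph mean pooling
ad_scale_rows <- function(tape, a, w) {
  ad_new(tape, a$value * w, list(a), function(g) ad_accum(a, g * w))
}

ad_transpose <- function(tape, a) {
  ad_new(tape, t(a$value), list(a), function(g) ad_accum(a, t(g)))
}

ad_concat_cols <- function(tape, nodes) {
  v <- do.call(cbind, lapply(nodes, function(n) n$value))
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_new(tape, v, nodes, function(g) {
    for (k in seq_along(nodes)) {
      ad_accum(nodes[[k]], g[, starts[k]:ends[k], drop = FALSE])
    }
  })
}

ad_concat_rows <- function(tape, nodes) {
  v <- do.call(rbind, lapply(nodes, function(n) n$value))
  heights <- vapply(nodes, function(n) nrow(n$value), integer(1))
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  ad_new(tape, v, nodes, function(g) {
    for (k in seq_along(nodes)) {
      ad_accum(nodes[[k]], g[starts[k]:ends[k], , drop = FALSE])
    }
  })
}

# ---- nonlinearities ---------------------------------------------------------

ad_relu <- function(tape, a) {
  m <- a$value > 0
  ad_new(tape, a$value * m, list(a), function(g) ad_accum(a, g * m))
}

ad_leaky_relu <- function(tape, a, slope = 0.2) {
  neg <- a$value < 0
  m <- array(1, dim(a$value))
  m[neg] <- slope
  ad_new(tape, a$value * m, list(a), function(g) ad_accum(a, g * m))
}

ad_elu <- function(tape, a, alpha = 1) {
  v <- a$value
  d <- array(1, dim(v))
  neg <- v < 0
  ev <- alpha * (exp(v[neg]) - 1)
  v[neg] <- ev
  d[neg] <- ev + alpha
  ad_new(tape, v, list(a), function(g) ad_accum(a, g * d))
}

ad_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$value))
  ad_new(tape, v, list(a), function(g) ad_accum(a, g * v * (1 - v)))
}

ad_tanh_ <- function(tape, a) {
  v <- tanh(a$value)
  ad_new(tape, v, list(a), function(g) ad_accum(a, g * (1 - v^2)))
}

# ---- indexing and grouped reductions ---------------------------------------

# rows of a selected by integer index (with repetition)
ad_gather <- function(tape, a, idx) {
  idx <- as.integer(idx)
  contiguous <- !anyDuplicated(idx) && !is.unsorted(idx)
  ad_new(tape, a$value[idx, , drop = FALSE], list(a), function(g) {
    full <- matrix(0, nrow(a$value), ncol(a$value))
    if (contiguous) {
      full[idx, ] <- g
    } else {
      acc <- rowsum(g, group = idx)
      full[as.integer(rownames(acc)), ] <- acc
    }
    ad_accum(a, full)
  })
}

# sum rows of a within groups 1..ngroups -> ngroups x D
ad_rowsum_group <- function(tape, a, group, ngroups) {
  group <- as.integer(group)
  v <- matrix(0, ngroups, ncol(a$value))
  acc <- rowsum(a$value, group = group)
  v[as.integer(rownames(acc)), ] <- acc
  ad_new(tape, v, list(a), function(g) ad_accum(a, g[group, , drop = FALSE]))
}

# mean rows within groups -> ngroups x D
ad_mean_group <- function(tape, a, group, ngroups) {
  cnt <- tabulate(as.integer(group), nbins = ngroups)
  s <- ad_rowsum_group(tape, a, group, ngroups)
  ad_scale_rows(tape, s, 1 / pmax(cnt, 1L))
}

ad_mean_rows <- function(tape, a) {
  n <- nrow(a$value)
  ad_new(tape, matrix(colMeans(a$value), 1L), list(a), function(g) {
    ad_accum(a, matrix(rep(g / n, each = n), n, ncol(a$value)))
  })
}

ad_sum <- function(tape, a) {
  ad_new(tape, matrix(sum(a$value), 1L, 1L), list(a), function(g) {
    ad_accum(a, matrix(g[1L], nrow(a$value), ncol(a$value)))
  })
}

ad_mean <- function(tape, a) ad_affine_const(tape, ad_sum(tape, a), 1 / length(a$value))

# ---- normalisation and attention -------------------------------------------

# row-wise layer normalisation with learnable gain/bias (1 x D each)
ad_layernorm <- function(tape, a, gain, bias, eps = 1e-5) {
  x <- a$value
  D <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  sd_ <- sqrt(va + eps)
  xhat <- xc / sd_
  gv <- as.numeric(gain$value)
  n <- nrow(x)
  v <- xhat * matrix(gv, n, D, byrow = TRUE) +
    matrix(bias$value, n, D, byrow = TRUE)
  ad_new(tape, v, list(a, gain, bias), function(g) {
    ad_accum(gain, matrix(colSums(g * xhat), 1L))
    ad_accum(bias, matrix(colSums(g), 1L))
    gh <- g * matrix(gv, nrow(g), D, byrow = TRUE)
    dx <- (gh - rowMeans(gh) - xhat * rowMeans(gh * xhat)) / sd_
    ad_accum(a, dx)
  })
}

ad_softmax_rows <- function(tape, a) {
  z <- a$value - apply(a$value, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  ad_new(tape, p, list(a), function(g) {
    ad_accum(a, p * (g - rowSums(g * p)))
  })
}

# softmax over entries of a column vector within groups (attention per
# destination node); logits E x 1, group in 1..ngroups
ad_softmax_group <- function(tape, a, group, ngroups) {
  group <- as.integer(group)
  z <- as.numeric(a$value)
  gmax <- vapply(split(z, group), max, numeric(1))
  e <- exp(z - gmax[as.character(group)])
  den <- rowsum(e, group = group)
  denv <- den[as.character(group), 1L]
  p <- e / denv
  ad_new(tape, matrix(p, ncol = 1L), list(a), function(g) {
    gp <- as.numeric(g) * p
    s <- rowsum(gp, group = group)
    ad_accum(a, matrix(gp - p * s[as.character(group), 1L], ncol = 1L))
  })
}

# row-wise L2 normalisation; rows with norm < eps pass through unchanged
ad_l2norm_rows <- function(tape, a, eps = 1e-12) {
  nr <- sqrt(rowSums(a$value^2))
  keep <- nr < eps
  nr_safe <- ifelse(keep, 1, nr)
  y <- a$value / nr_safe
  ad_new(tape, y, list(a), function(g) {
    d <- (g - y * rowSums(g * y)) / nr_safe
    d[keep, ] <- g[keep, , drop = FALSE]
    ad_accum(a, d)
  })
}

# ---- fused losses -----------------------------------------------------------

# row-wise bilinear form: out_i = x_i' W y_i (x, y: n x d; W: d x d)
ad_bilinear <- function(tape, x, w, y) {
  xw <- x$value %*% w$value
  v <- matrix(rowSums(xw * y$value), ncol = 1L)
  ad_new(tape, v, list(x, w, y), function(g) {
    gd <- as.numeric(g)
    ad_accum(x, (y$value * gd) %*% t(w$value))
    ad_accum(y, gd * xw)
    ad_accum(w, t(x$value) %*% (gd * y$value))
  })
}

# mean binary cross-entropy of logistic(z) against labels y in {0,1}
ad_bce_with_logits <- function(tape, z, y) {
  zv <- as.numeric(z$value)
  n <- length(zv)
  # log(1 + exp(z)) computed stably
  sp <- pmax(zv, 0) + log1p(exp(-abs(zv)))
  loss <- mean(sp - y * zv)
  ad_new(tape, matrix(loss, 1L, 1L), list(z), function(g) {
    p <- 1 / (1 + exp(-zv))
    ad_accum(z, matrix(g[1L] * (p - y) / n, nrow(z$value), ncol(z$value)))
  })
}

# InfoNCE over two similarity matrices (already divided by tau):
#  s_cross[i, j] = sim(view1_i, view2_j); diagonal = positives
#  s_self [i, j] = sim(view1_i, view1_j); diagonal excluded
# loss = -1/N sum_i log( exp(s_cross[i,i]) /
#          ( exp(s_cross[i,i]) + sum_{j!=i} exp(s_self[i,j]) + exp(s_cross[i,j]) ) )
ad_infonce <- function(tape, s_cross, s_self) {
  N <- nrow(s_cross$value)
  if (N == 1L) {
    # no negatives: the softmax is degenerate and the loss is identically 0
    return(ad_new(tape, matrix(0, 1L, 1L), list(s_cross, s_self), function(g) NULL))
  }
  mask <- diag(N) == 1
  a <- s_cross$value
  b <- s_self$value
  b[mask] <- -Inf                      # self-pairs are not negatives
  m <- pmax(apply(a, 1L, max), apply(b, 1L, max))
  ea <- exp(a - m)
  eb <- exp(b - m)
  den <- rowSums(ea) + rowSums(eb)
  # per-row loss: log(denominator) - positive logit
  li <- log(den) + m - diag(a)
  ad_new(tape, matrix(mean(li), 1L, 1L), list(s_cross, s_self), function(g) {
    pa <- ea / den
    pb <- eb / den
    ga <- pa
    diag(ga) <- diag(ga) - 1
    ad_accum(s_cross, g[1L] * ga / N)
    ad_accum(s_self, g[1L] * pb / N)
  })
}

# dropout: active only when training; the mask is drawn from R's RNG
ad_dropout <- function(tape, a, rate, training) {
  if (!training || rate <= 0) return(a)
  keep <- (matrix(stats::runif(length(a$value)), nrow(a$value)) >= rate) / (1 - rate)
  ad_new(tape, a$value * keep, list(a), function(g) ad_accum(a, g * keep))
}

# ---- parameter store and optimiser ------------------------------------------

# A parameter store is a plain named list of matrices. Each forward pass wraps
# it once into leaf nodes with ad_wrap_params(); after ad_backward() the
# gradients are collected by name and fed to the AdamW update.

ad_wrap_params <- function(tape, params) {
  lapply(params, function(p) ad_leaf(tape, p))
}

ad_collect_grads <- function(nodes) {
  lapply(nodes, function(n) {
    if (is.null(n$grad)) matrix(0, nrow(n$value), ncol(n$value)) else n$grad
  })
}

adamw_state <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim(as_ad_matrix(p)))),
    v = lapply(params, function(p) array(0, dim(as_ad_matrix(p)))),
    t = 0L
  )
}

# Decoupled weight decay (applied to the weights, not the gradient moments).
# `no_decay` names parameters excluded from decay (biases, gains, scalars).
adamw_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 1e-3, no_decay = character()) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / b1t
    vhat <- state$v[[nm]] / b2t
    upd <- mhat / (sqrt(vhat) + eps)
    if (!(nm %in% no_decay)) upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

# cosine annealing from lr0 to lr_min over `total` epochs (no restarts)
cosine_lr <- function(epoch, total, lr0, lr_min = 1e-5) {
  if (total <= 1) return(lr0)
  frac <- (epoch - 1) / (total - 1)
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * frac))
}

# fan-in scaled uniform initialisation (Glorot-style for ReLU-family stacks)
init_matrix <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}
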