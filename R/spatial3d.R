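# Spatial3DLayer: per-atom 3D featurisation. Three parallel encoders consume
# the rotated coordinates (3 -> d), the centroid distances (1 -> d/2) and the
# unit direction vectors (3 -> d/2); their concatenation (width 2d) is fused
# back to d. The distance pathway is rotation- and translation-invariant by
# construction; the coordinate and angle pathways are deliberately not, which
# is what the rotation augmentation regularises.

#' Configuration for the 3D spatial encoder
#'
#' @param d Embedding width (even; the distance and angle pathways each
#'   occupy `d/2`). Default 64.
#' @param dropout Dropout rate applied inside the coordinate encoder during
#'   training (the other pathways are dropout-free).
#' @param epsilon Threshold below which an atom is considered to sit on the
#'   centroid, in which case its direction vector is the zero vector.
#' @return A `spatial3d_config` list.
#' @export
spatial3d_config <- function(d = 64L, dropout = 0.1, epsilon = 1e-8) {
  d <- as.integer(d)
  stopifnot(d > 0, d %% 2L == 0L, dropout >= 0, dropout < 1, epsilon > 0)
  structure(list(d = d, dropout = dropout, epsilon = epsilon),
            class = "spatial3d_config")
}

#' Initialise spatial-encoder parameters
#'
#' Each pathway is a two-layer perceptron (linear, ReLU, layer normalisation,
#' and - for the coordinate pathway only - dropout); the fusion stage is a
#' single linear, ReLU, layer-normalisation block mapping `2d -> d`.
#'
#' @param config A [spatial3d_config()].
#' @return Named list of parameter matrices (prefix `spat.`).
#' @export
spatial3d_init <- function(config = spatial3d_config()) {
  d <- config$d
  h <- d %/% 2L
  p <- list(
    pos_W1 = init_matrix(3L, d), pos_b1 = matrix(0, 1, d),
    pos_g1 = matrix(1, 1, d), pos_c1 = matrix(0, 1, d),
    pos_W2 = init_matrix(d, d), pos_b2 = matrix(0, 1, d),
    pos_g2 = matrix(1, 1, d), pos_c2 = matrix(0, 1, d),
    dist_W1 = init_matrix(1L, h), dist_b1 = matrix(0, 1, h),
    dist_g1 = matrix(1, 1, h), dist_c1 = matrix(0, 1, h),
    dist_W2 = init_matrix(h, h), dist_b2 = matrix(0, 1, h),
    dist_g2 = matrix(1, 1, h), dist_c2 = matrix(0, 1, h),
    ang_W1 = init_matrix(3L, h), ang_b1 = matrix(0, 1, h),
    ang_g1 = matrix(1, 1, h), ang_c1 = matrix(0, 1, h),
    ang_W2 = init_matrix(h, h), ang_b2 = matrix(0, 1, h),
    ang_g2 = matrix(1, 1, h), ang_c2 = matrix(0, 1, h),
    fuse_W = init_matrix(2L * d, d), fuse_b = matrix(0, 1, d),
    fuse_g = matrix(1, 1, d), fuse_c = matrix(0, 1, d)
  )
  names(p) <- paste0("spat.", names(p))
  p
}

#' Geometric centre and per-atom centroid distances
#'
#' @param X N x 3 coordinate matrix.
#' @return List with `center` (length-3 vector) and `distances`
#'   (nonnegative length-N vector).
#' @export
compute_center_and_distances <- function(X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == 3, nrow(X) >= 1, all(is.finite(X)))
  ctr <- colMeans(X)
  diffs <- sweep(X, 2L, ctr)
  list(center = ctr, distances = sqrt(rowSums(diffs^2)))
}

#' Normalised atom-to-centroid direction vectors
#'
#' Rows are unit vectors pointing from the centroid to each atom; atoms closer
#' to the centroid than `epsilon` emit the zero vector (e.g. any single-atom
#' molecule).
#'
#' @param X N x 3 coordinate matrix.
#' @param center Centroid (defaults to the column means of `X`).
#' @param epsilon Degeneracy threshold on the centroid distance.
#' @return N x 3 matrix of direction cosines.
#' @export
compute_directions <- function(X, center = colMeans(X), epsilon = 1e-8) {
  X <- as.matrix(X)
  diffs <- sweep(X, 2L, center)
  nrm <- sqrt(rowSums(diffs^2))
  out <- diffs / ifelse(nrm < epsilon, 1, nrm)
  out[nrm < epsilon, ] <- 0
  out
}

# two-layer perceptron block used by each pathway
mlp2_forward <- function(tape, x, P, prefix, training, dropout = 0) {
  h <- ad_add_bias(tape, ad_matmul(tape, x, P[[paste0(prefix, "_W1")]]),
                   P[[paste0(prefix, "_b1")]])
  h <- ad_relu(tape, h)
  h <- ad_layernorm(tape, h, P[[paste0(prefix, "_g1")]], P[[paste0(prefix, "_c1")]])
  h <- ad_dropout(tape, h, dropout, training)
  h <- ad_add_bias(tape, ad_matmul(tape, h, P[[paste0(prefix, "_W2")]]),
                   P[[paste0(prefix, "_b2")]])
  h <- ad_relu(tape, h)
  h <- ad_layernorm(tape, h, P[[paste0(prefix, "_g2")]], P[[paste0(prefix, "_c2")]])
  ad_dropout(tape, h, dropout, training)
}

# tape-level forward used by the full model; X_aug is a plain matrix
spatial3d_forward_tape <- function(tape, X_aug, P, config, training = FALSE) {
  geo <- compute_center_and_distances(X_aug)
  vnorm <- compute_directions(X_aug, geo$center, config$epsilon)
  xin <- ad_const(tape, X_aug)
  din <- ad_const(tape, matrix(geo$distances, ncol = 1))
  ain <- ad_const(tape, vnorm)
  f_pos <- mlp2_forward(tape, xin, P, "spat.pos", training, config$dropout)
  f_dist <- mlp2_forward(tape, din, P, "spat.dist", training)
  f_angle <- mlp2_forward(tape, ain, P, "spat.ang", training)
  f_comb <- ad_concat_cols(tape, list(f_pos, f_dist, f_angle))
  s <- ad_add_bias(tape, ad_matmul(tape, f_comb, P[["spat.fuse_W"]]),
                   P[["spat.fuse_b"]])
  s <- ad_relu(tape, s)
  s <- ad_layernorm(tape, s, P[["spat.fuse_g"]], P[["spat.fuse_c"]])
  list(f_pos = f_pos, f_dist = f_dist, f_angle = f_angle,
       f_combined = f_comb, s = s, center = geo$center,
       distances = geo$distances, v_norm = vnorm)
}

#' Run the 3D spatial encoder on a coordinate matrix
#'
#' Evaluation mode is deterministic (dropout off); set `training = TRUE` to
#' apply dropout in the coordinate pathway.
#'
#' @param X_aug N x 3 (possibly rotation-augmented) coordinates.
#' @param params Parameters from [spatial3d_init()].
#' @param config A [spatial3d_config()].
#' @param training Apply dropout?
#' @return A list with matrices `f_pos` (N x d), `f_dist` (N x d/2),
#'   `f_angle` (N x d/2), `f_combined` (N x 2d), `s` (N x d), and the
#'   geometric intermediates `center`, `distances`, `v_norm`.
#' @export
spatial3d_forward <- function(X_aug, params, config = spatial3d_config(),
                              training = FALSE) {
  if (inherits(X_aug, "conformer")) X_aug <- X_aug$coordinates
  tape <- ad_tape()
  P <- ad_wrap_params(tape, params)
  out <- spatial3d_forward_tape(tape, X_aug, P, config, training)
  list(f_pos = out$f_pos$value, f_dist = out$f_dist$value,
       f_angle = out$f_angle$value, f_combined = out$f_combined$value,
       s = out$s$value, center = out$center, distances = out$distances,
       v_norm = out$v_norm)
}

#' Two independently rotated views of one conformer
#'
#' Draws two sets of Euler angles from R's RNG and returns the rotated
#' coordinate matrices; these are the positive pair consumed by the
#' contrastive objective.
#'
#' @param conformer A `conformer` (or N x 3 matrix).
#' @return List with `view1` and `view2` coordinate matrices.
#' @export
make_two_views <- function(conformer) {
  X <- if (inherits(conformer, "conformer")) conformer$coordinates else conformer
  list(view1 = random_rotation(X), view2 = random_rotation(X))
}
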