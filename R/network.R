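# Two-branch fusion network.
#
# Both branches share a 2x2x2 average-pooling stem (a memory-efficient
# subsampling layer: the encoder scales run at half the input resolution).
#
# Segmentation branch: 3-level 3D U-Net encoder (3x3x3 convs, 2x2x2 average
# pooling) with a lightweight decoder (nearest-neighbour upsampling, 1x1x1
# refinement convs, additive encoder skips), upsampled back to the input
# grid and ending in a voxelwise sigmoid lesion-probability map.
#
# Classification branch: a convolutional stack mirroring the encoder scales;
# at each scale its activations are modulated by (1 + prior attention), the
# attention map being the squashed channel-mean of the matching segmentation
# encoder activation. Global average pooling then a dense layer gives the
# 64-d semantic vector.
#
# Heads: CNN-only (dense on the semantic vector), radiomics-only (dense on
# the attention-weighted radiomics vector), combined (MLP on the
# concatenation). All heads are 2-class softmax; their final layers are
# zero-initialized so an untrained model outputs (0.5, 0.5).

relu <- function(x) {
  x[x < 0] <- 0
  x
}
sigmoid <- function(x) 1 / (1 + exp(-x))
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}
# internal feature maps are channel-last (z, y, x, C) so a channel is a
# contiguous block; matrix view is voxels x channels
as_mat <- function(a) {
  d <- dim(a)
  dim(a) <- c(prod(d[1:3]), d[4])
  a
}
as_arr <- function(m, sp) {
  dim(m) <- c(sp, ncol(m))
  m
}
# add a per-channel bias to a voxels x channels matrix
add_bias <- function(m, b) m + rep(b, each = nrow(m))

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * true) + eps) / (sum(pred) + sum(true) + eps)` with
#' `eps = 1e-6`; lies in [0, 1].
#'
#' @param pred voxelwise probabilities in [0, 1].
#' @param true binary mask of the same shape.
#' @param eps smoothing constant.
#' @return scalar loss.
#' @export
dice_loss <- function(pred, true, eps = 1e-6) {
  if (!identical(dim(pred), dim(true)) &&
      length(pred) != length(true)) stop("shape mismatch")
  1 - (2 * sum(pred * true) + eps) / (sum(pred) + sum(true) + eps)
}

#' Two-class cross-entropy
#'
#' `-log(probs[label])` with the probability clamped at a floor of 1e-12.
#'
#' @param probs probability 2-vector (sums to 1).
#' @param label class in {0, 1}.
#' @param floor clamp value.
#' @return scalar loss.
#' @export
class_cross_entropy <- function(probs, label, floor = 1e-12) {
  -log(max(probs[label + 1], floor))
}

#' Compose the two stage losses
#'
#' Stage 1 (feature extraction): Dice loss + CNN-head cross-entropy.
#' Stage 2 (classification): radiomics-head + combined-head cross-entropies.
#' The segmentation term enters as the Dice LOSS (one minus Dice
#' coefficient): minimizing one-minus-Dice-loss would reward bad
#' segmentation.
#'
#' @param l_seg Dice loss value.
#' @param l_cnn,l_rad,l_com head cross-entropies.
#' @return named numeric `c(stage1 =, stage2 =)`.
#' @export
stage_losses <- function(l_seg, l_cnn, l_rad, l_com) {
  c(stage1 = l_seg + l_cnn, stage2 = l_rad + l_com)
}

#' Exponential learning-rate schedule
#'
#' `lr(t) = lr0 * decay^t`, decay applied per epoch; defaults lr0 = 1e-4,
#' decay = 0.98.
#'
#' @param t epoch (integer >= 0).
#' @param lr0 base learning rate.
#' @param decay per-epoch decay factor.
#' @return learning rate at epoch `t`.
#' @export
lr_schedule <- function(t, lr0 = 1e-4, decay = 0.98) {
  if (any(t < 0)) stop("epoch must be >= 0")
  lr0 * decay^t
}

#' Prior attention map from an encoder activation
#'
#' The channel mean of the activation passed through a sigmoid squashing
#' onto [0, 1]. A zero activation therefore gives a flat 0.5 map.
#'
#' @param activation 4-D (C, z, y, x) activation.
#' @return 3-D attention map in [0, 1].
#' @export
prior_attention <- function(activation) {
  sp <- dim(activation)[1:3]
  m <- rowMeans(as_mat(activation))
  array(sigmoid(m), sp)
}

#' Residual attention modulation
#'
#' Elementwise `features * (1 + attention)` with the attention map broadcast
#' over channels, so attention can emphasize but never zero out a location.
#'
#' @param features 4-D (C, z, y, x) activation.
#' @param attention 3-D map in [0, 1].
#' @return modulated 4-D activation.
#' @export
modulate_attention <- function(features, attention) {
  out <- as_mat(features) * (1 + as.vector(attention))  # recycles over channels
  as_arr(out, dim(features)[1:3])
}

#' Self-attention over the radiomics vector
#'
#' Per-feature scores `a + g * z` (both parameter vectors learnable, zero at
#' initialization so the weights start uniform) are softmax-normalized into
#' simplex weights; the weighted vector is `d * weights * z` (scaled by the
#' feature count d so magnitudes stay training-friendly). The weights are
#' what the FSR machinery averages.
#'
#' @param z standardized radiomics vector.
#' @param a additive score parameters (default 0).
#' @param g multiplicative gate parameters (default 0).
#' @return list with `weights` (simplex) and `weighted`.
#' @export
radiomics_attention <- function(z, a = rep(0, length(z)),
                                g = rep(0, length(z))) {
  stopifnot(all(is.finite(z)))
  w <- softmax(a + g * z)
  list(weights = w, weighted = length(z) * w * z)
}

# He-scaled Gaussian init; `fan_in` is the incoming dimension
he_init <- function(nrow, ncol, fan_in = ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

#' Initialize the fusion model parameters
#'
#' @param d_rad radiomics feature count.
#' @param n_channels input channels.
#' @param base_channels first-level channel width k; levels use (k, 2k, 4k).
#' @param sem_dim semantic vector width.
#' @param seed RNG seed for the initialization.
#' @return object of class `lf_model`: parameter list plus architecture
#'   metadata.
#' @export
init_fusion_model <- function(d_rad, n_channels = 1L, base_channels = 8L,
                              sem_dim = 64L, seed = 1L) {
  k <- base_channels * c(1L, 2L, 4L)
  with_seed(seed, {
    par <- list(
      e1_W = he_init(27 * n_channels, k[1], 27 * n_channels), e1_b = rep(0, k[1]),
      e2_W = he_init(27 * k[1], k[2], 27 * k[1]), e2_b = rep(0, k[2]),
      e3_W = he_init(27 * k[2], k[3], 27 * k[2]), e3_b = rep(0, k[3]),
      d2_W = he_init(k[3], k[2], k[3]),      d2_b = rep(0, k[2]),
      d1_W = he_init(k[2], k[1], k[2]),      d1_b = rep(0, k[1]),
      # seg head: 1x1 conv on the upsampled decoder output plus a small
      # full-resolution refinement path on the raw input (the finest skip),
      # so boundaries resolve at voxel level; bias starts negative because
      # lesion voxels are sparse
      # head combination weights start at zero (clean prior p = sigmoid(-2))
      seg_W = matrix(0, k[1], 1),            seg_b = -2,
      segr_W = he_init(27 * n_channels, 4, 27 * n_channels),
      segr_b = rep(0, 4),
      segf_W = matrix(0, 4, 1),
      segx_W = matrix(0, n_channels, 1),
      c1_W = he_init(27 * n_channels, k[1], 27 * n_channels), c1_b = rep(0, k[1]),
      c2_W = he_init(27 * k[1], k[2], 27 * k[1]), c2_b = rep(0, k[2]),
      c3_W = he_init(27 * k[2], k[3], 27 * k[2]), c3_b = rep(0, k[3]),
      sem_W = he_init(sem_dim, k[3]),        sem_b = rep(0, sem_dim),
      cnn_W = matrix(0, 2, sem_dim),         cnn_b = rep(0, 2),
      attn_a = rep(0, d_rad),                attn_g = rep(0, d_rad),
      rad_W = matrix(0, 2, d_rad),           rad_b = rep(0, 2),
      f1_W = he_init(sem_dim, sem_dim + d_rad), f1_b = rep(0, sem_dim),
      f2_W = matrix(0, 2, sem_dim),          f2_b = rep(0, 2)
    )
    structure(list(par = par,
                   arch = list(k = k, sem_dim = sem_dim, d_rad = d_rad,
                               n_channels = n_channels)),
              class = "lf_model")
  })
}

stage1_param_names <- function() {
  c("e1_W", "e1_b", "e2_W", "e2_b", "e3_W", "e3_b", "d2_W", "d2_b",
    "d1_W", "d1_b", "seg_W", "seg_b", "segx_W", "segr_W", "segr_b",
    "segf_W", "c1_W", "c1_b", "c2_W", "c2_b",
    "c3_W", "c3_b", "sem_W", "sem_b", "cnn_W", "cnn_b")
}
stage2_param_names <- function() {
  c("attn_a", "attn_g", "rad_W", "rad_b", "f1_W", "f1_b", "f2_W", "f2_b")
}

#' Full forward pass of the fusion model
#'
#' Deterministic in inference mode: same parameters and inputs give
#' identical outputs.
#'
#' @param model an `lf_model`.
#' @param input an `lf_model_input` (or 4-D (C, z, y, x) array). Spatial
#'   dims must be divisible by 8 (stem + two pooling stages).
#' @param z standardized radiomics vector of length `arch$d_rad`.
#' @param keep if `TRUE`, return all intermediate activations (training /
#'   Grad-CAM use).
#' @return list with `seg_map` (3-D, in [0,1]), `p_rad`, `p_cnn`, `p_com`
#'   (2-class probability vectors), `attention_weights`, and (with
#'   `keep = TRUE`) the activation cache.
#' @export
forward_fusion <- function(model, input, z, keep = FALSE) {
  x <- if (inherits(input, "lf_model_input")) input$data else input
  if (length(dim(x)) != 4L || dim(x)[1] != model$arch$n_channels)
    stop("input must be channel-first 4-D with matching channel count")
  if (length(z) != model$arch$d_rad) stop("radiomics vector length mismatch")
  x <- aperm(x, c(2, 3, 4, 1))  # to internal channel-last layout
  p <- model$par
  sp1 <- dim(x)[1:3]
  # --- shared average-pooling stem (encoder scales run at half resolution;
  # the segmentation head upsamples back to the input grid)
  xs <- avgpool2_fwd(x)
  # --- segmentation encoder
  z1 <- conv3d_fwd(xs, p$e1_W, p$e1_b); a1 <- relu(z1)
  p1 <- avgpool2_fwd(a1)
  z2 <- conv3d_fwd(p1, p$e2_W, p$e2_b); a2 <- relu(z2)
  p2 <- avgpool2_fwd(a2)
  z3 <- conv3d_fwd(p2, p$e3_W, p$e3_b); a3 <- relu(z3)
  # --- decoder (1x1 refinement + additive skips)
  u2 <- upsample2_fwd(a3)
  t2 <- as_arr(add_bias(as_mat(u2) %*% p$d2_W, p$d2_b), dim(a2)[1:3]) + a2
  r2 <- relu(t2)
  u1 <- upsample2_fwd(r2)
  t1 <- as_arr(add_bias(as_mat(u1) %*% p$d1_W, p$d1_b), dim(a1)[1:3]) + a1
  r1 <- relu(t1)
  u0 <- upsample2_fwd(r1)
  fr_z <- conv3d_fwd(x, p$segr_W, p$segr_b)
  fr <- relu(fr_z)
  slog <- as.vector(as_mat(u0) %*% p$seg_W) +
    as.vector(as_mat(fr) %*% p$segf_W) +
    as.vector(as_mat(x) %*% p$segx_W) + p$seg_b
  seg_map <- array(sigmoid(slog), sp1)
  # --- prior attention from the encoder activations
  att1 <- prior_attention(a1)
  att2 <- prior_attention(a2)
  att3 <- prior_attention(a3)
  # --- classification branch (shares the stem resolution)
  w1 <- conv3d_fwd(xs, p$c1_W, p$c1_b); b1 <- relu(w1)
  m1 <- modulate_attention(b1, att1)
  q1 <- avgpool2_fwd(m1)
  w2 <- conv3d_fwd(q1, p$c2_W, p$c2_b); b2 <- relu(w2)
  m2 <- modulate_attention(b2, att2)
  q2 <- avgpool2_fwd(m2)
  w3 <- conv3d_fwd(q2, p$c3_W, p$c3_b); b3 <- relu(w3)
  m3 <- modulate_attention(b3, att3)
  gap <- colMeans(as_mat(m3))
  sem_z <- as.vector(p$sem_W %*% gap + p$sem_b)
  sem <- relu(sem_z)
  p_cnn <- softmax(as.vector(p$cnn_W %*% sem + p$cnn_b))
  # --- radiomics attention + heads
  ra <- radiomics_attention(z, p$attn_a, p$attn_g)
  p_rad <- softmax(as.vector(p$rad_W %*% ra$weighted + p$rad_b))
  v <- c(sem, ra$weighted)
  f1z <- as.vector(p$f1_W %*% v + p$f1_b)
  f1 <- relu(f1z)
  p_com <- softmax(as.vector(p$f2_W %*% f1 + p$f2_b))
  out <- list(seg_map = seg_map, p_rad = p_rad, p_cnn = p_cnn, p_com = p_com,
              attention_weights = ra$weights)
  if (keep)
    out$cache <- list(x = x, xs = xs, z1 = z1, a1 = a1, p1 = p1, z2 = z2,
                      a2 = a2,
                      p2 = p2, z3 = z3, a3 = a3, u2 = u2, t2 = t2, r2 = r2,
                      u1 = u1, t1 = t1, r1 = r1, u0 = u0, fr_z = fr_z,
                      fr = fr, slog = slog,
                      att1 = att1, att2 = att2, att3 = att3,
                      w1 = w1, b1 = b1, m1 = m1, q1 = q1, w2 = w2, b2 = b2,
                      m2 = m2, q2 = q2, w3 = w3, b3 = b3, m3 = m3,
                      gap = gap, sem_z = sem_z, sem = sem, z = z, ra = ra,
                      v = v, f1z = f1z, f1 = f1)
  out
}

# gradient of the soft Dice loss w.r.t. the probability map
dice_grad <- function(pred, true, eps = 1e-6) {
  den <- sum(pred) + sum(true) + eps
  num <- 2 * sum(pred * true) + eps
  -(2 * true * den - num) / den^2
}

# Stage-1 backward pass: d(dice + ce_cnn)/d(stage-1 params).
# Returns a named list of gradients matching stage1_param_names().
backward_stage1 <- function(model, fwd, mask, label) {
  p <- model$par
  cc <- fwd$cache
  k <- model$arch$k
  sp1 <- dim(cc$a1)[1:3]
  # CNN head
  g_cl <- fwd$p_cnn - c(label == 0, label == 1) * 1
  gW_cnn <- outer(g_cl, cc$sem)
  gb_cnn <- g_cl
  g_sem <- as.vector(t(p$cnn_W) %*% g_cl) * (cc$sem_z > 0)
  gW_sem <- outer(g_sem, cc$gap)
  gb_sem <- g_sem
  g_gap <- as.vector(t(p$sem_W) %*% g_sem)
  V3 <- prod(dim(cc$m3)[1:3])
  g_m3 <- as_arr(matrix(g_gap / V3, V3, k[3], byrow = TRUE),
                 dim(cc$m3)[1:3])
  # modulation backward at scale 3
  g_b3 <- modulate_attention(g_m3, cc$att3)
  g_att3 <- rowSums(as_mat(g_m3) * as_mat(cc$b3))
  g_w3 <- g_b3 * (cc$w3 > 0)
  bw3 <- conv3d_bwd(cc$q2, p$c3_W, g_w3)
  g_m2 <- avgpool2_bwd(bw3$gx)
  g_b2 <- modulate_attention(g_m2, cc$att2)
  g_att2 <- rowSums(as_mat(g_m2) * as_mat(cc$b2))
  g_w2 <- g_b2 * (cc$w2 > 0)
  bw2 <- conv3d_bwd(cc$q1, p$c2_W, g_w2)
  g_m1 <- avgpool2_bwd(bw2$gx)
  g_b1 <- modulate_attention(g_m1, cc$att1)
  g_att1 <- rowSums(as_mat(g_m1) * as_mat(cc$b1))
  g_w1 <- g_b1 * (cc$w1 > 0)
  bw1 <- conv3d_bwd(cc$xs, p$c1_W, g_w1, need_gx = FALSE)
  # segmentation head + decoder backward
  s <- as.vector(fwd$seg_map)
  g_s <- dice_grad(s, as.vector(mask))
  g_slog <- g_s * s * (1 - s)
  gW_seg <- crossprod(as_mat(cc$u0), g_slog)
  gW_segx <- crossprod(as_mat(cc$x), g_slog)
  gb_seg <- sum(g_slog)
  gW_segf <- crossprod(as_mat(cc$fr), g_slog)
  g_frz <- as_arr(tcrossprod(g_slog, p$segf_W[, 1]), dim(cc$fr)[1:3]) *
    (cc$fr_z > 0)
  bsegr <- conv3d_bwd(cc$x, p$segr_W, g_frz, need_gx = FALSE)
  g_u0 <- as_arr(tcrossprod(g_slog, p$seg_W[, 1]), dim(cc$u0)[1:3])
  g_r1 <- upsample2_bwd(g_u0)
  g_t1 <- g_r1 * (cc$t1 > 0)
  g_a1 <- g_t1  # additive skip
  g_u1m <- as_mat(g_t1) %*% t(p$d1_W)
  gW_d1 <- crossprod(as_mat(cc$u1), as_mat(g_t1))
  gb_d1 <- colSums(as_mat(g_t1))
  g_r2 <- upsample2_bwd(as_arr(g_u1m, sp1))
  g_t2 <- g_r2 * (cc$t2 > 0)
  g_a2 <- g_t2
  g_u2m <- as_mat(g_t2) %*% t(p$d2_W)
  gW_d2 <- crossprod(as_mat(cc$u2), as_mat(g_t2))
  gb_d2 <- colSums(as_mat(g_t2))
  g_a3 <- upsample2_bwd(as_arr(g_u2m, dim(cc$r2)[1:3]))
  # attention backward into the encoder activations:
  # att = sigmoid(mean_c a); d att/d a[v, c] = att(1-att)[v] / C
  att_back <- function(g_att, att, C, sp) {
    gv <- g_att * as.vector(att) * (1 - as.vector(att)) / C
    as_arr(matrix(gv, length(gv), C), sp)
  }
  g_a1 <- g_a1 + att_back(g_att1, cc$att1, k[1], sp1)
  g_a2 <- g_a2 + att_back(g_att2, cc$att2, k[2], dim(cc$a2)[1:3])
  g_a3 <- g_a3 + att_back(g_att3, cc$att3, k[3], dim(cc$a3)[1:3])
  # encoder backward, top-down, accumulating all contributions first
  g_z3 <- g_a3 * (cc$z3 > 0)
  be3 <- conv3d_bwd(cc$p2, p$e3_W, g_z3)
  g_a2 <- g_a2 + avgpool2_bwd(be3$gx)
  g_z2 <- g_a2 * (cc$z2 > 0)
  be2 <- conv3d_bwd(cc$p1, p$e2_W, g_z2)
  g_a1 <- g_a1 + avgpool2_bwd(be2$gx)
  g_z1 <- g_a1 * (cc$z1 > 0)
  be1 <- conv3d_bwd(cc$xs, p$e1_W, g_z1, need_gx = FALSE)
  list(e1_W = be1$gW, e1_b = be1$gb, e2_W = be2$gW, e2_b = be2$gb,
       e3_W = be3$gW, e3_b = be3$gb,
       d2_W = gW_d2, d2_b = gb_d2, d1_W = gW_d1, d1_b = gb_d1,
       seg_W = gW_seg, seg_b = gb_seg, segx_W = gW_segx,
       segr_W = bsegr$gW, segr_b = bsegr$gb, segf_W = gW_segf,
       c1_W = bw1$gW, c1_b = bw1$gb, c2_W = bw2$gW, c2_b = bw2$gb,
       c3_W = bw3$gW, c3_b = bw3$gb,
       sem_W = gW_sem, sem_b = gb_sem, cnn_W = gW_cnn, cnn_b = gb_cnn)
}

# Stage-2 forward from a precomputed semantic vector (extractors frozen)
forward_stage2 <- function(model, sem, z) {
  p <- model$par
  ra <- radiomics_attention(z, p$attn_a, p$attn_g)
  p_rad <- softmax(as.vector(p$rad_W %*% ra$weighted + p$rad_b))
  v <- c(sem, ra$weighted)
  f1z <- as.vector(p$f1_W %*% v + p$f1_b)
  f1 <- relu(f1z)
  p_com <- softmax(as.vector(p$f2_W %*% f1 + p$f2_b))
  list(p_rad = p_rad, p_com = p_com, ra = ra, v = v, f1z = f1z, f1 = f1)
}

# Stage-2 backward: d(ce_rad + ce_com)/d(stage-2 params)
backward_stage2 <- function(model, fwd2, z, label) {
  p <- model$par
  d <- length(z)
  onehot <- c(label == 0, label == 1) * 1
  g_rl <- fwd2$p_rad - onehot
  gW_rad <- outer(g_rl, fwd2$ra$weighted)
  gb_rad <- g_rl
  g_weighted <- as.vector(t(p$rad_W) %*% g_rl)
  g_cl <- fwd2$p_com - onehot
  gW_f2 <- outer(g_cl, fwd2$f1)
  gb_f2 <- g_cl
  g_f1 <- as.vector(t(p$f2_W) %*% g_cl) * (fwd2$f1z > 0)
  gW_f1 <- outer(g_f1, fwd2$v)
  gb_f1 <- g_f1
  g_v <- as.vector(t(p$f1_W) %*% g_f1)
  sem_dim <- length(fwd2$v) - d
  g_weighted <- g_weighted + g_v[(sem_dim + 1):(sem_dim + d)]
  # weighted = d * w * z; softmax backward for w = softmax(a + g*z)
  g_w <- d * z * g_weighted
  w <- fwd2$ra$weights
  g_scores <- w * (g_w - sum(g_w * w))
  list(attn_a = g_scores, attn_g = g_scores * z,
       rad_W = gW_rad, rad_b = gb_rad,
       f1_W = gW_f1, f1_b = gb_f1, f2_W = gW_f2, f2_b = gb_f2)
}

# Adam optimizer over a named subset of parameters
adam_init <- function(par, names) {
  list(m = lapply(par[names], function(x) x * 0),
       v = lapply(par[names], function(x) x * 0), t = 0)
}
adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}
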