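#' Training / run configuration
#'
#' Validated bundle of every tunable knob. Defaults follow the training
#' protocol: 50 epochs split 25/25 over the two stages, batch size 8, Adam
#' with exponentially decaying learning rate `1e-4 * 0.98^t`, fivefold
#' patient-level cross-validation, 32 gray levels for radiomics, 2000
#' bootstrap resamples for confidence intervals. `base_channels` sets the
#' network width (levels use k, 2k, 4k channels).
#'
#' @param epochs_stage1,epochs_stage2 epochs per training stage.
#' @param batch_size studies per optimizer step.
#' @param lr0 base learning rate.
#' @param lr_decay per-epoch exponential decay factor.
#' @param n_levels radiomics discretization levels.
#' @param base_channels first-level channel width.
#' @param sem_dim semantic vector width.
#' @param k_folds cross-validation folds.
#' @param n_boot bootstrap resamples for AUC confidence intervals.
#' @param seed master seed; all other seeds derive from it.
#' @param augment apply random flips / in-plane 90-degree rotations during
#'   stage-1 training.
#' @param model_shape spatial shape of the network input tensor; each
#'   dimension must be divisible by 8.
#' @return object of class `lf_config` with a content hash attached.
#' @export
lf_config <- function(epochs_stage1 = 25L, epochs_stage2 = 25L,
                      batch_size = 8L, lr0 = 1e-4, lr_decay = 0.98,
                      n_levels = 32L, base_channels = 8L, sem_dim = 64L,
                      k_folds = 5L, n_boot = 2000L, seed = 1L,
                      augment = TRUE, model_shape = c(32L, 64L, 64L)) {
  cfg <- list(epochs_stage1 = as.integer(epochs_stage1),
              epochs_stage2 = as.integer(epochs_stage2),
              batch_size = as.integer(batch_size),
              lr0 = lr0, lr_decay = lr_decay,
              n_levels = as.integer(n_levels),
              base_channels = as.integer(base_channels),
              sem_dim = as.integer(sem_dim),
              k_folds = as.integer(k_folds),
              n_boot = as.integer(n_boot), seed = as.integer(seed),
              augment = isTRUE(augment),
              model_shape = as.integer(model_shape))
  stopifnot(cfg$epochs_stage1 >= 1, cfg$epochs_stage2 >= 1,
            cfg$batch_size >= 1, cfg$lr0 > 0,
            cfg$lr_decay > 0, cfg$lr_decay <= 1,
            cfg$n_levels >= 2, cfg$base_channels >= 1, cfg$sem_dim >= 2,
            cfg$k_folds >= 2, cfg$n_boot >= 1,
            length(cfg$model_shape) == 3, all(cfg$model_shape %% 8L == 0L))
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "lf_config")
}

# FNV-1a hash of the canonical (name-sorted) serialization, so the hash is
# stable under key reordering and fully determines the architecture
config_hash <- function(cfg) {
  cfg$hash <- NULL
  keys <- sort(names(cfg))
  txt <- paste(vapply(keys, function(k) {
    paste0(k, "=", paste(format(cfg[[k]], digits = 15), collapse = ","))
  }, character(1)), collapse = ";")
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Sample or apply a training augmentation
#'
#' The augmentation group is the product of axis flips and in-plane
#' 90-degree rotations (volume and mask transformed identically, label
#' untouched); every transform is a voxel permutation, and the identity has
#' positive probability (each flip is drawn with p = 0.5, the rotation
#' count uniformly from 0..3).
#'
#' @param input an `lf_model_input`.
#' @param transform a list `(flip = logical(3), rot = 0..3)`; if `NULL`, one
#'   is drawn from the current RNG stream via [sample_augment()].
#' @return the transformed `lf_model_input`.
#' @export
augment <- function(input, transform = NULL) {
  if (is.null(transform)) transform <- sample_augment()
  x <- input$data
  m <- input$mask_lowres
  d <- dim(x)
  for (ax in 1:3) if (transform$flip[ax]) {
    idx <- rev(seq_len(d[ax + 1]))
    if (ax == 1) { x <- x[, idx, , , drop = FALSE]; m <- m[idx, , , drop = FALSE] }
    if (ax == 2) { x <- x[, , idx, , drop = FALSE]; m <- m[, idx, , drop = FALSE] }
    if (ax == 3) { x <- x[, , , idx, drop = FALSE]; m <- m[, , idx, drop = FALSE] }
  }
  if (transform$rot %% 4 != 0) {
    if (d[3] != d[4]) stop("in-plane rotation requires square slices")
    for (k in seq_len(transform$rot %% 4)) {
      # 90-degree counter-clockwise rotation of the (y, x) plane
      x <- aperm(x, c(1, 2, 4, 3))[, , rev(seq_len(d[4])), , drop = FALSE]
      m <- aperm(m, c(1, 3, 2))[, rev(seq_len(d[4])), , drop = FALSE]
    }
  }
  structure(list(data = x, mask_lowres = m), class = "lf_model_input")
}

#' @rdname augment
#' @export
sample_augment <- function() {
  list(flip = stats::runif(3) < 0.5, rot = sample(0:3, 1))
}

#' Assign studies to cross-validation folds
#'
#' Uniform random partition into `k` folds whose sizes differ by at most 1;
#' reproducible from the seed.
#'
#' @param study_ids character vector of unique ids.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return object of class `lf_fold_plan`: named integer vector `assignment`
#'   (values 0..k-1), `k`, `seed`.
#' @export
assign_folds <- function(study_ids, k = 5L, seed = 1L) {
  stopifnot(!anyDuplicated(study_ids))
  n <- length(study_ids)
  if (n < k) stop("fewer studies than folds")
  assignment <- with_seed(seed, {
    perm <- sample(n)
    folds <- rep(seq_len(k) - 1L, length.out = n)
    out <- integer(n)
    out[perm] <- folds
    out
  })
  names(assignment) <- study_ids
  structure(list(assignment = assignment, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "lf_fold_plan")
}

# mean stage-1 validation loss (dice + cnn cross-entropy), no augmentation
stage1_val_loss <- function(model, inputs, zmat, labels) {
  mean(vapply(seq_along(inputs), function(i) {
    fw <- forward_fusion(model, inputs[[i]], zmat[i, ])
    dice_loss(fw$seg_map, inputs[[i]]$mask_lowres) +
      class_cross_entropy(fw$p_cnn, labels[i])
  }, numeric(1)))
}

#' Train one cross-validation fold
#'
#' Runs the two-stage protocol on the studies outside `fold`, validating on
#' the studies inside it. Stage 1 trains both branch extractors and the CNN
#' head with loss Dice + cross-entropy under random flip/rotation
#' augmentation; the best (minimum validation loss) stage-1 parameters are
#' restored, the CNN semantic vectors are then frozen and precomputed, and
#' stage 2 trains the radiomics attention, radiomics head and fusion MLP
#' with loss `ce_rad + ce_com`. The learning-rate schedule continues across
#' the stage boundary. Feature standardization is fitted on the training
#' split only. Fully seeded: two runs with the same inputs are identical.
#'
#' @param cohort list of `lf_study`.
#' @param plan an `lf_fold_plan` covering the cohort's ids.
#' @param fold validation fold index in `0..k-1`.
#' @param config an [lf_config()].
#' @param features optional precomputed feature matrix (rows = study ids)
#'   to avoid re-extracting radiomics per fold.
#' @param inputs optional list of precomputed `lf_model_input`s aligned
#'   with `cohort` (they are fold-independent, so callers training several
#'   folds can preprocess once).
#' @return object of class `lf_train_state`: best model, scaler, per-epoch
#'   validation-loss traces and running minima, seeds, fold indices and the
#'   config hash.
#' @export
train_fold <- function(cohort, plan, fold, config, features = NULL,
                       inputs = NULL) {
  stopifnot(inherits(plan, "lf_fold_plan"), fold %in% (seq_len(plan$k) - 1L))
  ids <- vapply(cohort, function(s) s$study_id, character(1))
  labels <- vapply(cohort, function(s) s$label, integer(1))
  in_val <- plan$assignment[ids] == fold
  if (all(in_val)) stop("empty training split")
  if (is.null(features)) features <- extract_cohort_features(
    cohort, n_levels = config$n_levels)
  features <- features[ids, , drop = FALSE]
  scaler <- fit_feature_scaler(features[!in_val, , drop = FALSE])
  zmat <- apply_feature_scaler(scaler, features)
  if (is.null(inputs))
    inputs <- lapply(cohort, preprocess_study,
                     model_shape = config$model_shape)
  seeds <- list(init = derive_seed(config$seed, 1000L + fold),
                train = derive_seed(config$seed, 2000L + fold))
  model <- init_fusion_model(d_rad = ncol(zmat),
                             n_channels = dim(inputs[[1]]$data)[1],
                             base_channels = config$base_channels,
                             sem_dim = config$sem_dim, seed = seeds$init)
  tr_idx <- which(!in_val)
  va_idx <- which(in_val)
  trace1 <- numeric(0); trace2 <- numeric(0)
  best1 <- Inf; best2 <- Inf
  best1_par <- model$par
  with_seed(seeds$train, {
    opt1 <- adam_init(model$par, stage1_param_names())
    for (epoch in seq_len(config$epochs_stage1) - 1L) {
      lr <- lr_schedule(epoch, config$lr0, config$lr_decay)
      order <- sample(tr_idx)
      for (b0 in seq(1, length(order), by = config$batch_size)) {
        batch <- order[b0:min(b0 + config$batch_size - 1, length(order))]
        gsum <- NULL
        for (i in batch) {
          inp <- if (config$augment) augment(inputs[[i]]) else inputs[[i]]
          fw <- forward_fusion(model, inp, zmat[i, ], keep = TRUE)
          g <- backward_stage1(model, fw, inp$mask_lowres, labels[i])
          gsum <- if (is.null(gsum)) g else
            Map(`+`, gsum, g)
        }
        gsum <- lapply(gsum, function(x) x / length(batch))
        st <- adam_step(model$par, gsum, opt1, lr)
        model$par <- st$par
        opt1 <- st$state
      }
      vl <- stage1_val_loss(model, inputs[va_idx], zmat[va_idx, , drop = FALSE],
                            labels[va_idx])
      trace1 <- c(trace1, vl)
      if (vl < best1) { best1 <- vl; best1_par <- model$par }
    }
    model$par <- best1_par
    # freeze extractors; precompute semantic vectors (no augmentation)
    sems <- lapply(inputs, function(inp)
      forward_fusion(model, inp, zmat[1, ], keep = TRUE)$cache$sem)
    best2_par <- model$par
    opt2 <- adam_init(model$par, stage2_param_names())
    for (epoch in seq_len(config$epochs_stage2) - 1L) {
      lr <- lr_schedule(config$epochs_stage1 + epoch, config$lr0,
                        config$lr_decay)
      order <- sample(tr_idx)
      for (b0 in seq(1, length(order), by = config$batch_size)) {
        batch <- order[b0:min(b0 + config$batch_size - 1, length(order))]
        gsum <- NULL
        for (i in batch) {
          fw2 <- forward_stage2(model, sems[[i]], zmat[i, ])
          g <- backward_stage2(model, fw2, zmat[i, ], labels[i])
          gsum <- if (is.null(gsum)) g else Map(`+`, gsum, g)
        }
        gsum <- lapply(gsum, function(x) x / length(batch))
        st <- adam_step(model$par, gsum, opt2, lr)
        model$par <- st$par
        opt2 <- st$state
      }
      vl <- mean(vapply(va_idx, function(i) {
        fw2 <- forward_stage2(model, sems[[i]], zmat[i, ])
        class_cross_entropy(fw2$p_rad, labels[i]) +
          class_cross_entropy(fw2$p_com, labels[i])
      }, numeric(1)))
      trace2 <- c(trace2, vl)
      if (vl < best2) { best2 <- vl; best2_par <- model$par }
    }
    model$par <- best2_par
  })
  structure(list(model = model, scaler = scaler, fold = fold,
                 config_hash = config$hash, seeds = seeds,
                 val_trace = list(stage1 = trace1, stage2 = trace2),
                 best_val_loss = list(stage1 = cummin(trace1),
                                      stage2 = cummin(trace2)),
                 train_ids = ids[tr_idx], val_ids = ids[va_idx],
                 n_levels = config$n_levels,
                 model_shape = config$model_shape),
            class = "lf_train_state")
}

#' Predict head probabilities for studies with one trained fold model
#'
#' Inference applies no augmentation and is deterministic.
#'
#' @param state an `lf_train_state`.
#' @param studies list of `lf_study`.
#' @param features optional precomputed (unstandardized) feature matrix.
#' @param inputs optional list of precomputed `lf_model_input`s aligned
#'   with `studies`.
#' @return data.frame with `study_id`, `label` and class-1 probabilities
#'   `p_rad`, `p_cnn`, `p_com`.
#' @export
predict_fold <- function(state, studies, features = NULL, inputs = NULL) {
  if (is.null(features)) features <- extract_cohort_features(
    studies, n_levels = state$n_levels)
  ids <- vapply(studies, function(s) s$study_id, character(1))
  zmat <- apply_feature_scaler(state$scaler, features[ids, , drop = FALSE])
  rows <- lapply(seq_along(studies), function(i) {
    inp <- if (is.null(inputs)) preprocess_study(
      studies[[i]], model_shape = state$model_shape) else inputs[[i]]
    fw <- forward_fusion(state$model, inp, zmat[i, ])
    data.frame(study_id = ids[i], label = studies[[i]]$label,
               p_rad = fw$p_rad[2], p_cnn = fw$p_cnn[2], p_com = fw$p_com[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-fold ensemble prediction
#'
#' Averages the per-head class-1 probabilities of the five (in general k)
#' fold models; all checkpoints must share a config hash.
#'
#' @param states list of `lf_train_state` (the k fold checkpoints).
#' @param studies list of `lf_study` to score.
#' @param features optional precomputed feature matrix.
#' @param inputs optional list of precomputed `lf_model_input`s.
#' @return data.frame as in [predict_fold()] with averaged probabilities.
#' @export
ensemble_predict <- function(states, studies, features = NULL,
                             inputs = NULL) {
  hashes <- vapply(states, function(s) s$config_hash, character(1))
  if (length(unique(hashes)) != 1L)
    stop("ensemble integrity: fold checkpoints have differing config hashes")
  if (is.null(features)) features <- extract_cohort_features(
    studies, n_levels = states[[1]]$n_levels)
  preds <- lapply(states, predict_fold, studies = studies,
                  features = features, inputs = inputs)
  out <- preds[[1]]
  for (k in seq_along(preds)[-1]) {
    out$p_rad <- out$p_rad + preds[[k]]$p_rad
    out$p_cnn <- out$p_cnn + preds[[k]]$p_cnn
    out$p_com <- out$p_com + preds[[k]]$p_com
  }
  out$p_rad <- out$p_rad / length(preds)
  out$p_cnn <- out$p_cnn / length(preds)
  out$p_com <- out$p_com / length(preds)
  out
}
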