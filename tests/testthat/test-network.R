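test_that("loss closed forms match hand values", {
  m <- array(0, c(4, 4, 4)); m[1:2, 1, 1] <- 1
  expect_equal(dice_loss(m, m), 0, tolerance = 1e-5)
  disj <- array(0, c(4, 4, 4)); disj[3:4, 4, 4] <- 1
  expect_equal(dice_loss(m, disj), 1, tolerance = 1e-5)
  pred <- array(0, c(2, 2, 2)); pred[1:4] <- 1
  true <- array(0, c(2, 2, 2)); true[3:6] <- 1
  expect_equal(dice_loss(pred, true), 0.5, tolerance = 1e-5)

  expect_equal(class_cross_entropy(c(0.5, 0.5), 0), log(2))
  expect_equal(class_cross_entropy(c(0.5, 0.5), 1), log(2))
  expect_equal(class_cross_entropy(c(1, 0), 0), 0)
  expect_equal(class_cross_entropy(c(0.8, 0.2), 1), -log(0.2))

  expect_equal(unname(stage_losses(0, log(2), 0, 0)["stage1"]), log(2))
  expect_equal(unname(stage_losses(0, 0, 0.3, 0.4)["stage2"]), 0.7)
  expect_equal(unname(stage_losses(0.5, -log(0.8), 0, 0)["stage1"]),
               0.5 - log(0.8))
})

test_that("learning-rate schedule is the documented exponential decay", {
  expect_identical(lr_schedule(0), 1e-4)
  expect_equal(lr_schedule(1), 9.8e-5)
  t <- 0:60
  expect_true(all(diff(lr_schedule(t)) < 0))
  expect_error(lr_schedule(-1))
})

test_that("Dice loss equals the soft-overlap oracle on random binary pairs", {
  set.seed(70)
  for (i in 1:100) {
    p <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
    t0 <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
    o <- 1 - (2 * sum(p * t0) + 1e-6) / (sum(p) + sum(t0) + 1e-6)
    expect_equal(dice_loss(p, t0), o, tolerance = 1e-12)
  }
})

test_that("prior attention squashes the channel mean and modulates residually", {
  act <- array(0, c(4, 4, 4, 3))
  att <- prior_attention(act)
  expect_true(all(att == 0.5))
  mod <- modulate_attention(act + 1, att)
  expect_true(all(mod == 1.5))
  # hot region attracts the attention maximum
  act2 <- array(0, c(4, 4, 4, 3))
  act2[2, 3, 1, ] <- 5
  att2 <- prior_attention(act2)
  expect_equal(which.max(att2), which(array(seq_len(64), c(4, 4, 4)) ==
                                        (2 + 4 * (3 - 1) + 16 * (1 - 1))))
  # recomposition oracle
  set.seed(71)
  f <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  a <- array(runif(64), c(4, 4, 4))
  mo <- modulate_attention(f, a)
  for (ch in 1:2) expect_equal(mo[, , , ch], f[, , , ch] * (1 + a))
})

test_that("radiomics self-attention lives on the simplex and saturates", {
  z <- rnorm(10)
  ra <- radiomics_attention(z)
  expect_equal(ra$weights, rep(0.1, 10))
  expect_equal(ra$weighted, 10 * 0.1 * z)
  set.seed(72)
  for (i in 1:10) {
    a <- rnorm(7); g <- rnorm(7); zz <- rnorm(7)
    w <- radiomics_attention(zz, a, g)$weights
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
  a_sat <- c(50, rep(0, 6))
  expect_equal(radiomics_attention(rnorm(7), a_sat)$weights[1], 1,
               tolerance = 1e-12)
})

test_that("an untrained model outputs (0.5, 0.5) from every head and is
          deterministic at inference", {
  s <- generate_study(small_params(), 1, seed = 80)
  inp <- preprocess_study(s, model_shape = c(16, 16, 16))
  m <- init_fusion_model(d_rad = 5, base_channels = 2, sem_dim = 8, seed = 1)
  z <- rnorm(5)
  fw <- forward_fusion(m, inp, z)
  expect_equal(fw$p_cnn, c(0.5, 0.5))
  expect_equal(fw$p_rad, c(0.5, 0.5))
  expect_equal(fw$p_com, c(0.5, 0.5))
  expect_true(all(fw$seg_map >= 0 & fw$seg_map <= 1))
  fw2 <- forward_fusion(m, inp, z)
  expect_identical(fw[c("seg_map", "p_rad", "p_cnn", "p_com")],
                   fw2[c("seg_map", "p_rad", "p_cnn", "p_com")])
})

test_that("the radiomics head is consistent under feature reordering", {
  s <- generate_study(small_params(), 0, seed = 81)
  inp <- preprocess_study(s, model_shape = c(16, 16, 16))
  d <- 9
  m <- init_fusion_model(d_rad = d, base_channels = 2, sem_dim = 8, seed = 2)
  set.seed(82)
  m$par$attn_a <- rnorm(d); m$par$attn_g <- rnorm(d)
  m$par$rad_W <- matrix(rnorm(2 * d), 2, d)
  z <- rnorm(d)
  p1 <- forward_fusion(m, inp, z)$p_rad
  perm <- sample(d)
  m2 <- m
  m2$par$attn_a <- m$par$attn_a[perm]
  m2$par$attn_g <- m$par$attn_g[perm]
  m2$par$rad_W <- m$par$rad_W[, perm]
  m2$par$f1_W <- m$par$f1_W[, c(seq_len(m$arch$sem_dim),
                                m$arch$sem_dim + perm)]
  p2 <- forward_fusion(m2, inp, z[perm])$p_rad
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("backpropagation matches finite differences on a tiny model", {
  pp <- phantom_params(grid_shape = c(8, 8, 8), lesion_radius_range = c(2, 2),
                       n_lesions_range = c(1, 1))
  s <- generate_study(pp, 1, seed = 90)
  inp <- preprocess_study(s, model_shape = c(8, 8, 8))
  m <- init_fusion_model(d_rad = 6, base_channels = 2, sem_dim = 6, seed = 3)
  set.seed(91)
  # randomize zero-initialized heads so gradients flow everywhere
  for (nm in c("cnn_W", "rad_W", "f2_W", "seg_W", "segf_W", "segx_W"))
    m$par[[nm]][] <- rnorm(length(m$par[[nm]]), sd = 0.3)
  m$par$attn_a <- rnorm(6, sd = 0.2); m$par$attn_g <- rnorm(6, sd = 0.2)
  z <- rnorm(6)
  fw <- forward_fusion(m, inp, z, keep = TRUE)
  g1 <- lesionfuse:::backward_stage1(m, fw, inp$mask_lowres, s$label)
  loss1 <- function(model) {
    f <- forward_fusion(model, inp, z)
    dice_loss(f$seg_map, inp$mask_lowres) + class_cross_entropy(f$p_cnn,
                                                                s$label)
  }
  for (nm in lesionfuse:::stage1_param_names()) {
    i <- sample(length(m$par[[nm]]), 1)
    eps <- 1e-5
    mp <- m; mp$par[[nm]][i] <- mp$par[[nm]][i] + eps
    mm <- m; mm$par[[nm]][i] <- mm$par[[nm]][i] - eps
    num <- (loss1(mp) - loss1(mm)) / (2 * eps)
    expect_equal(g1[[nm]][i], num, tolerance = 1e-4,
                 label = paste("stage-1 grad", nm))
  }
  sem <- fw$cache$sem
  fw2 <- lesionfuse:::forward_stage2(m, sem, z)
  g2 <- lesionfuse:::backward_stage2(m, fw2, z, s$label)
  loss2 <- function(model) {
    f2 <- lesionfuse:::forward_stage2(model, sem, z)
    class_cross_entropy(f2$p_rad, s$label) +
      class_cross_entropy(f2$p_com, s$label)
  }
  for (nm in lesionfuse:::stage2_param_names()) {
    i <- sample(length(m$par[[nm]]), 1)
    eps <- 1e-6
    mp <- m; mp$par[[nm]][i] <- mp$par[[nm]][i] + eps
    mm <- m; mm$par[[nm]][i] <- mm$par[[nm]][i] - eps
    num <- (loss2(mp) - loss2(mm)) / (2 * eps)
    expect_equal(g2[[nm]][i], num, tolerance = 1e-4,
                 label = paste("stage-2 grad", nm))
  }
})

test_that("gradients are finite and nonzero on random batches", {
  s <- generate_study(small_params(), 1, seed = 95)
  inp <- preprocess_study(s, model_shape = c(16, 16, 16))
  m <- init_fusion_model(d_rad = 4, base_channels = 2, sem_dim = 8, seed = 5)
  set.seed(96)
  m$par$cnn_W[] <- rnorm(length(m$par$cnn_W), sd = 0.1)
  z <- rnorm(4)
  fw <- forward_fusion(m, inp, z, keep = TRUE)
  g1 <- lesionfuse:::backward_stage1(m, fw, inp$mask_lowres, 1L)
  expect_true(all(vapply(g1, function(x) all(is.finite(x)), logical(1))))
  expect_true(any(vapply(g1, function(x) any(x != 0), logical(1))))
  fw2 <- lesionfuse:::forward_stage2(m, fw$cache$sem, z)
  g2 <- lesionfuse:::backward_stage2(m, fw2, z, 1L)
  expect_true(all(vapply(g2, function(x) all(is.finite(x)), logical(1))))
})

test_that("200 optimizer steps overfit a single batch of four phantoms", {
  pp <- small_params()
  cohort <- lapply(1:4, function(i)
    generate_study(pp, i %% 2, seed = 100 + i, sprintf("S%d", i)))
  feats <- extract_cohort_features(cohort)
  labels <- vapply(cohort, function(s) s$label, integer(1))
  z <- apply_feature_scaler(fit_feature_scaler(feats), feats)
  inputs <- lapply(cohort, preprocess_study, model_shape = c(16, 16, 16))
  m <- init_fusion_model(d_rad = ncol(z), base_channels = 8, seed = 3)
  opt <- lesionfuse:::adam_init(m$par, lesionfuse:::stage1_param_names())
  for (step in 1:200) {
    gs <- NULL
    for (i in 1:4) {
      fw <- forward_fusion(m, inputs[[i]], z[i, ], keep = TRUE)
      g <- lesionfuse:::backward_stage1(m, fw, inputs[[i]]$mask_lowres,
                                        labels[i])
      gs <- if (is.null(gs)) g else Map(`+`, gs, g)
    }
    st <- lesionfuse:::adam_step(m$par, lapply(gs, function(x) x / 4), opt,
                                 1e-2)
    m$par <- st$par; opt <- st$state
  }
  sems <- lapply(1:4, function(i)
    forward_fusion(m, inputs[[i]], z[i, ], keep = TRUE)$cache$sem)
  opt2 <- lesionfuse:::adam_init(m$par, lesionfuse:::stage2_param_names())
  for (step in 1:200) {
    gs <- NULL
    for (i in 1:4) {
      fw2 <- lesionfuse:::forward_stage2(m, sems[[i]], z[i, ])
      g <- lesionfuse:::backward_stage2(m, fw2, z[i, ], labels[i])
      gs <- if (is.null(gs)) g else Map(`+`, gs, g)
    }
    st <- lesionfuse:::adam_step(m$par, lapply(gs, function(x) x / 4), opt2,
                                 1e-2)
    m$par <- st$par; opt2 <- st$state
  }
  total <- mean(vapply(1:4, function(i) {
    fw <- forward_fusion(m, inputs[[i]], z[i, ])
    fw2 <- lesionfuse:::forward_stage2(m, sems[[i]], z[i, ])
    dice_loss(fw$seg_map, inputs[[i]]$mask_lowres) +
      class_cross_entropy(fw$p_cnn, labels[i]) +
      class_cross_entropy(fw2$p_rad, labels[i]) +
      class_cross_entropy(fw2$p_com, labels[i])
  }, numeric(1)))
  expect_lt(total, 0.05)
})
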