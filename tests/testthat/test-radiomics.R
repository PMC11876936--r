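test_that("discretization follows the fixed-bin-count contract", {
  v <- array(c(0, 0.5, 1), c(3, 1, 1))
  m <- array(1L, c(3, 1, 1))
  d <- discretize_roi(v, m, n_levels = 2)
  # width 0.5: [0, 0.5) -> 1, [0.5, 1] -> 2 (right-closed top bin)
  expect_identical(as.vector(d$levels), c(1L, 2L, 2L))
  expect_warning(dc <- discretize_roi(array(3, c(2, 2, 2)),
                                      array(1L, c(2, 2, 2)), 4), "constant")
  expect_true(all(dc$levels == 1L))
  # histogram equals a direct binning enumeration
  set.seed(9)
  v2 <- array(runif(100), c(100, 1, 1))
  m2 <- array(1L, c(100, 1, 1))
  d2 <- discretize_roi(v2, m2, n_levels = 4)
  w <- (max(v2) - min(v2)) / 4
  direct <- pmin(floor((v2 - min(v2)) / w) + 1, 4)
  expect_identical(as.vector(d2$levels), as.integer(direct))
})

test_that("first-order features match examples and the closed-form oracle", {
  f <- firstorder_features(c(1, 2, 3, 4))
  expect_equal(f[["firstorder_range"]], 3)
  expect_equal(f[["firstorder_mean"]], 2.5)
  fc <- firstorder_features(rep(2, 10))
  expect_equal(fc[["firstorder_range"]], 0)
  expect_equal(fc[["firstorder_entropy"]], 0)
  set.seed(10)
  x <- rnorm(50)
  f2 <- firstorder_features(x)
  o <- oracle_firstorder(x)
  for (nm in c("mean", "range", "energy", "entropy", "sd", "skewness",
               "kurtosis", "p10", "p90"))
    expect_equal(f2[[paste0("firstorder_", nm)]], o[[nm]], tolerance = 1e-12)
})

test_that("shape features: cube volume, anisotropy ordering, diameter oracle", {
  cube <- array(0L, c(8, 8, 8)); cube[3:6, 3:6, 3:6] <- 1L
  sc <- shape_features(cube)
  expect_equal(sc[["shape_volume"]], 64)
  expect_equal(sc[["shape_surface_area"]], 6 * 16)
  rod <- array(0L, c(10, 3, 3)); rod[2:9, 2, 2] <- 1L
  cube2 <- array(0L, c(4, 4, 4)); cube2[2:3, 2:3, 2:3] <- 1L
  expect_gt(shape_features(rod)[["shape_elongation"]],
            shape_features(cube2)[["shape_elongation"]])
  single <- array(0L, c(3, 3, 3)); single[2, 2, 2] <- 1L
  ss <- shape_features(single)
  expect_equal(ss[["shape_elongation"]], 1)
  expect_equal(ss[["shape_flatness"]], 1)
  set.seed(11)
  for (rep in 1:5) {
    blob <- array(rbinom(6^3, 1, 0.4), c(6, 6, 6))
    if (sum(blob) < 2) next
    expect_equal(shape_features(blob)[["shape_max_diameter"]],
                 oracle_max_diameter(blob), tolerance = 1e-12)
  }
})

test_that("GLCM: alternating strip, constant ROI, and oracle equivalence", {
  # 1-D strip 1,2,1,2: only one direction has pairs; all co-occurrences
  # are at level distance 1 -> contrast exactly 1
  v <- array(c(0, 1, 0, 1), c(4, 1, 1))
  d <- discretize_roi(v, array(1L, c(4, 1, 1)), n_levels = 2)
  g <- glcm_features(d)
  expect_equal(g[["glcm_contrast"]], 1)
  dc <- suppressWarnings(discretize_roi(array(1, c(3, 3, 3)),
                                        array(1L, c(3, 3, 3)), 2))
  gc <- glcm_features(dc)
  expect_equal(gc[["glcm_contrast"]], 0)
  expect_equal(gc[["glcm_idm"]], 1)
  for (seed in 1:8) {
    dr <- random_droi(seed, max_dim = 5, n_levels = 3)
    if (sum(!is.na(dr$levels)) < 2) next
    g1 <- glcm_features(dr)
    o <- oracle_glcm(dr$levels, 3)
    expect_equal(unname(attr(g1, "matrix")), unname(o$matrix),
                 tolerance = 1e-9)
    expect_equal(g1[["glcm_contrast"]], o$contrast, tolerance = 1e-9)
    expect_equal(g1[["glcm_correlation"]], o$correlation, tolerance = 1e-9)
    expect_equal(g1[["glcm_joint_entropy"]], o$joint_entropy,
                 tolerance = 1e-9)
    expect_equal(g1[["glcm_idm"]], o$idm, tolerance = 1e-9)
    expect_equal(g1[["glcm_cluster_shade"]], o$cluster_shade,
                 tolerance = 1e-9)
  }
})

test_that("GLDM: constant-ROI enumeration, single voxel, oracle equivalence", {
  dc <- suppressWarnings(discretize_roi(array(1, c(3, 3, 3)),
                                        array(1L, c(3, 3, 3)), 2))
  g <- gldm_features(dc, alpha = 0)
  # in a constant 3^3 ROI every neighbour is dependent: 1 voxel with 26,
  # 6 face voxels with 17, 12 edge voxels with 11, 8 corner voxels with 7
  counts <- c(`26` = 1, `17` = 6, `11` = 12, `7` = 8)
  sde <- sum(counts / (as.numeric(names(counts)) + 1)^2) / 27
  expect_equal(g[["gldm_small_dependence_emphasis"]], sde, tolerance = 1e-12)
  single <- suppressWarnings(discretize_roi(array(1, c(1, 1, 1)),
                                            array(1L, c(1, 1, 1)), 2))
  gs <- gldm_features(single)
  expect_equal(unname(attr(gs, "matrix")[1, 1]), 1)  # one entry, dependence 0
  for (seed in 11:16) {
    dr <- random_droi(seed, max_dim = 4, n_levels = 3)
    g1 <- gldm_features(dr, alpha = 0)
    o <- oracle_gldm(dr$levels, 3, alpha = 0)
    expect_equal(unname(attr(g1, "matrix")), unname(o$matrix))
    expect_equal(g1[["gldm_small_dependence_emphasis"]], o$sde,
                 tolerance = 1e-9)
    expect_equal(g1[["gldm_large_dependence_emphasis"]], o$lde,
                 tolerance = 1e-9)
    expect_equal(g1[["gldm_gray_level_nonuniformity"]], o$gln,
                 tolerance = 1e-9)
    expect_equal(g1[["gldm_dependence_entropy"]], o$dep_entropy,
                 tolerance = 1e-9)
  }
})

test_that("GLSZM: single zone, disjoint zones, flood-fill oracle", {
  dc <- suppressWarnings(discretize_roi(array(5, c(2, 2, 2)),
                                        array(1L, c(2, 2, 2)), 2))
  g <- glszm_features(dc)
  P <- attr(g, "matrix")
  expect_equal(sum(P), 1)
  expect_equal(unname(P[1, 8]), 1)  # one zone of size 8
  # two single-voxel zones of different levels, separated by background
  v <- array(c(0, 0.5, 1), c(3, 1, 1))
  m <- array(c(1L, 0L, 1L), c(3, 1, 1))
  g2 <- glszm_features(discretize_roi(v, m, n_levels = 2))
  expect_equal(sum(attr(g2, "matrix")), 2)
  expect_true(all(attr(g2, "matrix")[, 1][attr(g2, "matrix")[, 1] > 0] == 1))
  for (seed in 21:26) {
    dr <- random_droi(seed, max_dim = 5, n_levels = 3)
    g1 <- glszm_features(dr)
    o <- oracle_glszm(dr$levels, 3)
    expect_equal(unname(attr(g1, "matrix")), unname(o$matrix))
    expect_equal(g1[["glszm_small_area_emphasis"]], o$sae, tolerance = 1e-9)
    expect_equal(g1[["glszm_large_area_emphasis"]], o$lae, tolerance = 1e-9)
    expect_equal(g1[["glszm_zone_size_nonuniformity"]], o$zsn,
                 tolerance = 1e-9)
    expect_equal(g1[["glszm_zone_entropy"]], o$zone_entropy,
                 tolerance = 1e-9)
  }
})

test_that("NGTDM: degenerate convention, hand enumeration, oracle", {
  dc <- suppressWarnings(discretize_roi(array(1, c(3, 3, 3)),
                                        array(1L, c(3, 3, 3)), 2))
  g <- ngtdm_features(dc)
  expect_equal(unname(attr(g, "table")$s), c(0, 0))
  expect_equal(g[["ngtdm_contrast"]], 0)
  expect_equal(g[["ngtdm_coarseness"]], 1e6)
  # 3x3x1 plane, centre level 2 surrounded by level 1
  v <- array(0, c(3, 3, 1)); v[2, 2, 1] <- 1
  d2 <- discretize_roi(v, array(1L, c(3, 3, 1)), n_levels = 2)
  tb <- attr(ngtdm_features(d2), "table")
  # centre: |2 - 1| = 1. corners: 3 neighbours, one is the centre ->
  # |1 - 4/3|; edges: 5 neighbours, one is the centre -> |1 - 6/5|
  expect_equal(tb$s[2], 1)
  expect_equal(tb$s[1], 4 * abs(1 - 4 / 3) + 4 * abs(1 - 6 / 5))
  for (seed in 31:36) {
    dr <- random_droi(seed, max_dim = 5, n_levels = 3)
    g1 <- ngtdm_features(dr)
    o <- oracle_ngtdm(dr$levels, 3)
    for (nm in c("coarseness", "contrast", "busyness", "complexity",
                 "strength"))
      expect_equal(g1[[paste0("ngtdm_", nm)]], o[[nm]], tolerance = 1e-9)
  }
})

test_that("texture matrices conserve their totals against enumeration", {
  for (seed in 41:46) {
    dr <- random_droi(seed, max_dim = 6, n_levels = 3)
    n_roi <- sum(!is.na(dr$levels))
    expect_equal(sum(sapply(oracle_glcm_mats(dr$levels, 3), sum)),
                 sum(sapply(lesionfuse:::glcm_matrices(dr), sum)))
    expect_equal(sum(attr(gldm_features(dr), "matrix")), n_roi)
    expect_equal(sum(attr(glszm_features(dr), "matrix") *
                       col(attr(glszm_features(dr), "matrix"))), n_roi)
    tb <- attr(ngtdm_features(dr), "table")
    expect_equal(sum(tb$n / tb$N), 1, tolerance = 1e-9)
  }
})

test_that("texture features are invariant to intensity shift and 90-degree
          rotation", {
  s <- generate_study(small_params(), 1, seed = 55)
  droi <- discretize_roi(s$volume, s$mask, n_levels = 8)
  droi_shift <- discretize_roi(s$volume + 100, s$mask, n_levels = 8)
  expect_equal(glcm_features(droi), glcm_features(droi_shift))
  expect_equal(ngtdm_features(droi), ngtdm_features(droi_shift))
  rot <- function(a) {
    # 90-degree rotation about the slice axis
    aperm(a, c(1, 3, 2))[, rev(seq_len(dim(a)[3])), , drop = FALSE]
  }
  droi_rot <- discretize_roi(rot(s$volume), rot(s$mask), n_levels = 8)
  g1 <- glcm_features(droi)
  g2 <- glcm_features(droi_rot)
  expect_equal(unname(g1), unname(g2), tolerance = 1e-9)
})

test_that("the full feature vector has the fixed schema and is invariant to
          lesion translation", {
  s <- generate_study(small_params(), 1, seed = 60)
  fv <- extract_feature_vector(s)
  expect_identical(names(fv), radiomics_feature_names())
  expect_length(fv, 36)
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_feature_vector(s))
  # translate lesion and intensities by 3 voxels along x
  s2 <- s
  d <- dim(s$volume)
  s2$volume <- array(0.1, d)
  s2$mask <- array(0L, d)
  src <- 1:(d[3] - 3)
  s2$volume[, , src + 3] <- s$volume[, , src]
  s2$mask[, , src + 3] <- s$mask[, , src]
  if (sum(s2$mask) == sum(s$mask)) {  # lesion fully inside after shift
    fv2 <- extract_feature_vector(s2)
    texture_and_shape <- setdiff(names(fv), c())
    keep <- grepl("^(glcm|gldm|glszm|ngtdm|shape)_", names(fv))
    expect_equal(fv[keep], fv2[keep], tolerance = 1e-8)
  }
})

test_that("feature standardization is fold-aware and invertible", {
  set.seed(61)
  X <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, letters[1:10]))
  sc <- fit_feature_scaler(X[1:10, ])
  Z <- apply_feature_scaler(sc, X[1:10, ])
  expect_equal(colMeans(Z), setNames(rep(0, 10), letters[1:10]),
               tolerance = 1e-12)
  expect_equal(apply(Z, 2, sd), setNames(rep(1, 10), letters[1:10]),
               tolerance = 1e-12)
  # applying to held-out rows uses the training statistics
  Zh <- apply_feature_scaler(sc, X[11:20, ])
  expect_equal(Zh[1, "a"], (X[11, "a"] - mean(X[1:10, "a"])) / sd(X[1:10, "a"]))
})
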