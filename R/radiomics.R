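#' Discretize ROI intensities into gray levels
#'
#' Equal-width binning of the intensities under `mask` into `n_levels`
#' levels: the ROI minimum maps to level 1 and the maximum to level
#' `n_levels` (the top bin is right-closed). Texture matrices are computed
#' only over these levels; voxels outside the ROI are excluded everywhere.
#'
#' @param volume 3-D intensity array (use one channel).
#' @param mask 3-D 0/1 array of the same shape.
#' @param n_levels number of gray levels (>= 2), default 32.
#' @param spacing voxel size triple, recorded for shape features.
#' @return object of class `lf_droi`: list with `levels` (3-D integer array
#'   cropped to the mask bounding box, `NA` outside the ROI), `mask`
#'   (cropped), `n_levels`, `roi_voxel_count`, `spacing` and the raw
#'   `intensities` vector.
#' @export
discretize_roi <- function(volume, mask, n_levels = 32L, spacing = c(1, 1, 1)) {
  stopifnot(identical(dim(volume), dim(mask)), n_levels >= 2L)
  if (sum(mask) < 1) stop("mask must contain at least one foreground voxel")
  idx <- which(mask == 1, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  crop <- function(a) a[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                        rng[1, 3]:rng[2, 3], drop = FALSE]
  vol_c <- crop(volume)
  mask_c <- crop(mask)
  vals <- vol_c[mask_c == 1]
  lo <- min(vals); hi <- max(vals)
  if (hi == lo) {
    warning("constant ROI: all voxels assigned level 1")
    lev <- rep(1L, length(vals))
  } else {
    w <- (hi - lo) / n_levels
    lev <- pmin(as.integer(floor((vals - lo) / w)) + 1L, as.integer(n_levels))
  }
  levels <- array(NA_integer_, dim(vol_c))
  levels[mask_c == 1] <- lev
  structure(list(levels = levels, mask = array(as.integer(mask_c),
                                               dim(mask_c)),
                 n_levels = as.integer(n_levels),
                 roi_voxel_count = length(vals),
                 spacing = spacing, intensities = vals),
            class = "lf_droi")
}

# the 26 unit offsets, and the 13 unique ones up to sign (for GLCM)
lf_offsets26 <- function() {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}
lf_offsets13 <- function() {
  g <- lf_offsets26()
  keep <- apply(g, 1, function(o) {
    o[3] > 0 || (o[3] == 0 && o[2] > 0) || (o[3] == 0 && o[2] == 0 && o[1] > 0)
  })
  g[keep, , drop = FALSE]
}

# shift a 3-D array by (dz, dy, dx), NA-filling the vacated border
shift_arr <- function(a, o) {
  d <- dim(a)
  out <- array(NA_integer_, d)
  lo <- pmax(1, 1 + o)
  hi <- pmin(d, d + o)
  if (any(hi < lo)) return(out)  # shift exceeds the extent: all NA
  src <- lapply(1:3, function(k) lo[k]:hi[k])
  dst <- lapply(1:3, function(k) src[[k]] - o[k])
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' First-order intensity statistics of the ROI
#'
#' Entropy is computed on a 32-bin equal-width histogram of the ROI
#' intensities (log2; 0 for a constant ROI). Skewness and kurtosis use
#' population moments (`m3/m2^1.5`, `m4/m2^2`), both defined as 0 when the
#' variance is 0. Percentiles use the default (type 7) quantile rule.
#'
#' @param x numeric vector of ROI intensities (>= 1 voxel).
#' @return named numeric vector, names prefixed `firstorder_`.
#' @export
firstorder_features <- function(x) {
  stopifnot(length(x) >= 1)
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  ent <- if (max(x) == min(x)) 0 else {
    h <- tabulate(pmin(as.integer(floor((x - min(x)) /
                                          ((max(x) - min(x)) / 32))) + 1L, 32L),
                  nbins = 32L)
    p <- h[h > 0] / n
    -sum(p * log2(p))
  }
  c(firstorder_mean = m,
    firstorder_median = stats::median(x),
    firstorder_min = min(x),
    firstorder_max = max(x),
    firstorder_range = max(x) - min(x),
    firstorder_energy = sum(x^2),
    firstorder_entropy = ent,
    firstorder_sd = sqrt(m2),
    firstorder_skewness = if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0,
    firstorder_kurtosis = if (m2 > 0) mean((x - m)^4) / m2^2 else 0,
    firstorder_p10 = unname(stats::quantile(x, 0.10)),
    firstorder_p90 = unname(stats::quantile(x, 0.90)))
}

#' Shape features of a binary mask
#'
#' Volume is voxel count times voxel volume. Surface area uses the
#' face-count method (exposed voxel faces times face area). Sphericity is
#' `pi^(1/3) * (6V)^(2/3) / A`. Elongation and flatness are anisotropy
#' ratios `sqrt(l1/l2)` and `sqrt(l1/l3)` of the ordered eigenvalues
#' `l1 >= l2 >= l3` of the mask's second central moments (voxel centres,
#' spacing applied), each axis augmented by the voxel's own extent variance
#' `s^2/12` so a single voxel yields elongation = flatness = 1 and
#' degenerate (collinear) masks stay finite. Both are >= 1; larger means
#' more anisotropic. Maximum 3-D diameter is the largest pairwise distance
#' between surface-voxel centres.
#'
#' @param mask 3-D 0/1 array.
#' @param spacing voxel size triple (z, y, x).
#' @return named numeric vector, names prefixed `shape_`.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  idx <- which(mask == 1, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 1) stop("mask must be non-empty")
  vox_vol <- prod(spacing)
  volume <- n * vox_vol
  # exposed faces: voxel faces whose 6-neighbour is background/outside
  face_areas <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                  spacing[1] * spacing[2])
  area <- 0
  d <- dim(mask)
  surf <- rep(FALSE, n)
  for (axk in 1:3) for (s in c(-1L, 1L)) {
    nb <- idx
    nb[, axk] <- nb[, axk] + s
    inb <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    occ <- rep(FALSE, n)
    occ[inb] <- mask[nb[inb, , drop = FALSE]] == 1
    area <- area + sum(!occ) * face_areas[axk]
    surf <- surf | !occ
  }
  sphericity <- pi^(1 / 3) * (6 * volume)^(2 / 3) / area
  pts <- sweep(idx, 2, spacing, "*")
  cm <- if (n > 1) stats::cov(pts) * (n - 1) / n else matrix(0, 3, 3)
  cm <- cm + diag(spacing^2 / 12)
  ev <- sort(eigen(cm, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  spts <- pts[surf, , drop = FALSE]
  if (nrow(spts) == 0) spts <- pts
  dd <- as.matrix(stats::dist(spts))
  c(shape_volume = volume,
    shape_surface_area = area,
    shape_sphericity = sphericity,
    shape_elongation = sqrt(ev[1] / ev[2]),
    shape_flatness = sqrt(ev[1] / ev[3]),
    shape_max_diameter = max(dd))
}

# co-occurrence matrices per direction (symmetric, ROI-restricted),
# returned unnormalized; directions with no pair are dropped
glcm_matrices <- function(droi) {
  ng <- droi$n_levels
  offs <- lf_offsets13()
  out <- list()
  for (k in seq_len(nrow(offs))) {
    sh <- shift_arr(droi$levels, offs[k, ])
    ok <- !is.na(droi$levels) & !is.na(sh)
    if (!any(ok)) next
    i <- droi$levels[ok]; j <- sh[ok]
    P <- matrix(0, ng, ng)
    tab <- table(factor(i, levels = 1:ng), factor(j, levels = 1:ng))
    P <- unclass(tab) + t(unclass(tab))  # symmetric: count both orientations
    out[[length(out) + 1]] <- P
  }
  out
}

#' Gray-level co-occurrence (GLCM) features
#'
#' Symmetric co-occurrence matrices over the 13 unique distance-1
#' 3-D directions, restricted to in-ROI voxel pairs; each direction's matrix
#' is normalized and the normalized matrices are averaged (directions with
#' no valid pair are dropped). Correlation of a zero-variance (degenerate)
#' matrix is defined as 1.
#'
#' @param droi an `lf_droi`.
#' @return named numeric vector prefixed `glcm_`, with the averaged
#'   probability matrix attached as attribute `"matrix"`.
#' @export
glcm_features <- function(droi) {
  mats <- glcm_matrices(droi)
  if (length(mats) == 0) stop("feature undefined: no valid in-ROI voxel pair")
  Ps <- lapply(mats, function(P) P / sum(P))
  P <- Reduce(`+`, Ps) / length(Ps)
  ng <- droi$n_levels
  i <- matrix(1:ng, ng, ng)
  j <- t(i)
  pi_m <- rowSums(P)
  mu_i <- sum((1:ng) * pi_m)
  sd_i <- sqrt(sum((1:ng)^2 * pi_m) - mu_i^2)
  contrast <- sum(P * (i - j)^2)
  correlation <- if (sd_i > 0)
    (sum(P * i * j) - mu_i^2) / sd_i^2 else 1
  nz <- P > 0
  out <- c(glcm_contrast = contrast,
           glcm_correlation = correlation,
           glcm_joint_entropy = -sum(P[nz] * log2(P[nz])),
           glcm_idm = sum(P / (1 + (i - j)^2)),
           glcm_cluster_shade = sum(P * (i + j - 2 * mu_i)^3))
  attr(out, "matrix") <- P
  out
}

# dependence matrix: rows = gray level, cols = dependence count d = 0..26
gldm_matrix <- function(droi, alpha = 0) {
  ng <- droi$n_levels
  dep <- array(0L, dim(droi$levels))
  for (k in seq_len(nrow(lf_offsets26()))) {
    sh <- shift_arr(droi$levels, lf_offsets26()[k, ])
    dep <- dep + ifelse(!is.na(droi$levels) & !is.na(sh) &
                          abs(droi$levels - sh) <= alpha, 1L, 0L)
  }
  ok <- !is.na(droi$levels)
  P <- matrix(0, ng, 27)
  tab <- table(factor(droi$levels[ok], levels = 1:ng),
               factor(dep[ok], levels = 0:26))
  P[] <- unclass(tab)
  P
}

#' Gray-level dependence (GLDM) features
#'
#' For each ROI voxel the dependence count d is the number of its 26
#' distance-1 in-ROI neighbours with gray-level difference <= `alpha`
#' (a single isolated voxel has d = 0). Emphasis weights use the
#' dependence-group size d + 1 (the centre voxel counts itself), so the
#' weights are well defined at d = 0.
#'
#' @param droi an `lf_droi`.
#' @param alpha dependence tolerance on the level difference (default 0).
#' @return named numeric vector prefixed `gldm_`, with the dependence
#'   matrix (levels x dependence 0..26) as attribute `"matrix"`.
#' @export
gldm_features <- function(droi, alpha = 0) {
  P <- gldm_matrix(droi, alpha)
  N <- sum(P)
  dsize <- matrix(0:26 + 1, nrow(P), 27, byrow = TRUE)  # d + 1
  p <- P / N
  nz <- P > 0
  out <- c(gldm_small_dependence_emphasis = sum(P / dsize^2) / N,
           gldm_large_dependence_emphasis = sum(P * dsize^2) / N,
           gldm_gray_level_nonuniformity = sum(rowSums(P)^2) / N,
           gldm_dependence_entropy = -sum(p[nz] * log2(p[nz])))
  attr(out, "matrix") <- P
  out
}

# 26-connected components of equal-level ROI voxels -> zone (level, size)
glszm_zones <- function(droi) {
  d <- dim(droi$levels)
  lab <- array(0L, d)
  offs <- lf_offsets26()
  zones <- list()
  nxt <- 0L
  idx_all <- which(!is.na(droi$levels))
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    level <- droi$levels[start]
    queue <- start
    lab[start] <- nxt
    size <- 0L
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1L
      ai <- arrayInd(v, d)
      for (k in seq_len(nrow(offs))) {
        nb <- ai + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        w <- nb[1] + d[1] * (nb[2] - 1 + d[2] * (nb[3] - 1))
        if (lab[w] == 0L && !is.na(droi$levels[w]) &&
            droi$levels[w] == level) {
          lab[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
    zones[[nxt]] <- c(level = level, size = size)
  }
  do.call(rbind, zones)
}

#' Gray-level size-zone (GLSZM) features
#'
#' Zones are 26-connected components of equal-level ROI voxels; the matrix
#' counts zones by (level, size).
#'
#' @param droi an `lf_droi`.
#' @return named numeric vector prefixed `glszm_`, with the zone matrix
#'   (levels x sizes 1..max) as attribute `"matrix"`.
#' @export
glszm_features <- function(droi) {
  z <- glszm_zones(droi)
  ng <- droi$n_levels
  smax <- max(z[, "size"])
  P <- matrix(0, ng, smax)
  for (r in seq_len(nrow(z))) {
    P[z[r, "level"], z[r, "size"]] <- P[z[r, "level"], z[r, "size"]] + 1
  }
  nz_total <- sum(P)
  s <- matrix(seq_len(smax), ng, smax, byrow = TRUE)
  p <- P / nz_total
  nzp <- P > 0
  out <- c(glszm_small_area_emphasis = sum(P / s^2) / nz_total,
           glszm_large_area_emphasis = sum(P * s^2) / nz_total,
           glszm_zone_size_nonuniformity = sum(colSums(P)^2) / nz_total,
           glszm_zone_entropy = -sum(p[nzp] * log2(p[nzp])))
  attr(out, "matrix") <- P
  out
}

# NGTDM table: per level i, n_i (voxels with >= 1 in-ROI neighbour),
# s_i = sum over those voxels of |i - mean level of in-ROI 26-neighbours|
ngtdm_table <- function(droi) {
  ng <- droi$n_levels
  nb_sum <- array(0, dim(droi$levels))
  nb_cnt <- array(0L, dim(droi$levels))
  offs <- lf_offsets26()
  for (k in seq_len(nrow(offs))) {
    sh <- shift_arr(droi$levels, offs[k, ])
    has <- !is.na(sh)
    nb_sum[has] <- nb_sum[has] + sh[has]
    nb_cnt <- nb_cnt + ifelse(has, 1L, 0L)
  }
  ok <- !is.na(droi$levels) & nb_cnt > 0
  lev <- droi$levels[ok]
  diffs <- abs(lev - nb_sum[ok] / nb_cnt[ok])
  n_i <- tabulate(lev, nbins = ng)
  s_i <- vapply(1:ng, function(i) sum(diffs[lev == i]), numeric(1))
  list(n = n_i, s = s_i, N = sum(n_i))
}

#' Neighbouring gray-tone difference (NGTDM) features
#'
#' For each gray level i, `s_i` sums |i - mean level of the voxel's in-ROI
#' 26-neighbours| over ROI voxels of level i (voxels without any in-ROI
#' neighbour are excluded), with level probabilities `p_i = n_i / N`.
#' Standard formulas:
#' * coarseness = 1 / sum(p_i s_i) (1e6 when the denominator is 0);
#' * contrast = (sum_{i,j} p_i p_j (i-j)^2 / (Ngp (Ngp - 1))) * (sum s_i / N),
#'   0 when only one level is present;
#' * busyness = sum(p_i s_i) / sum_{i,j} |i p_i - j p_j| (0 if denominator 0);
#' * complexity = (1/N) sum_{i,j} |i-j| (p_i s_i + p_j s_j) / (p_i + p_j);
#' * strength = sum_{i,j} (p_i + p_j)(i-j)^2 / sum s_i (0 if sum s_i = 0);
#' with the double sums over levels with p > 0.
#'
#' @param droi an `lf_droi`.
#' @return named numeric vector prefixed `ngtdm_`, with the (n_i, s_i)
#'   table as attribute `"table"`.
#' @export
ngtdm_features <- function(droi) {
  tb <- ngtdm_table(droi)
  if (tb$N == 0) stop("feature undefined: no ROI voxel has an in-ROI neighbour")
  act <- which(tb$n > 0)
  p <- tb$n / tb$N
  s <- tb$s
  ngp <- length(act)
  ps <- sum(p * s)
  coarseness <- if (ps > 0) 1 / ps else 1e6
  contrast <- if (ngp > 1) {
    acc <- 0
    for (i in act) for (j in act) acc <- acc + p[i] * p[j] * (i - j)^2
    acc / (ngp * (ngp - 1)) * sum(s) / tb$N
  } else 0
  den_busy <- 0
  complexity <- 0
  strength_num <- 0
  for (i in act) for (j in act) {
    den_busy <- den_busy + abs(i * p[i] - j * p[j])
    complexity <- complexity + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) /
      (p[i] + p[j])
    strength_num <- strength_num + (p[i] + p[j]) * (i - j)^2
  }
  out <- c(ngtdm_coarseness = coarseness,
           ngtdm_contrast = contrast,
           ngtdm_busyness = if (den_busy > 0) ps / den_busy else 0,
           ngtdm_complexity = complexity / tb$N,
           ngtdm_strength = if (sum(s) > 0) strength_num / sum(s) else 0)
  attr(out, "table") <- tb
  out
}

#' Fixed radiomics feature schema
#'
#' @return character vector of the 36 feature names in their fixed order
#'   (firstorder, shape, glcm, gldm, glszm, ngtdm).
#' @export
radiomics_feature_names <- function() {
  c(names(firstorder_features(c(0, 1))),
    "shape_volume", "shape_surface_area", "shape_sphericity",
    "shape_elongation", "shape_flatness", "shape_max_diameter",
    "glcm_contrast", "glcm_correlation", "glcm_joint_entropy", "glcm_idm",
    "glcm_cluster_shade",
    "gldm_small_dependence_emphasis", "gldm_large_dependence_emphasis",
    "gldm_gray_level_nonuniformity", "gldm_dependence_entropy",
    "glszm_small_area_emphasis", "glszm_large_area_emphasis",
    "glszm_zone_size_nonuniformity", "glszm_zone_entropy",
    "ngtdm_coarseness", "ngtdm_contrast", "ngtdm_busyness",
    "ngtdm_complexity", "ngtdm_strength")
}

#' Extract the full radiomics vector of a study
#'
#' Concatenates the six families in the fixed order of
#' [radiomics_feature_names()], computed inside the lesion ROI of the
#' intensity-rescaled first channel. Standardization is NOT applied here:
#' z-scaling statistics must be fitted on training folds only (see
#' [fit_feature_scaler()]) and applied to validation/test data.
#'
#' @param study an `lf_study`.
#' @param n_levels gray levels for discretization (default 32).
#' @param spacing voxel spacing (default unit).
#' @return named numeric vector of length `length(radiomics_feature_names())`.
#' @export
extract_feature_vector <- function(study, n_levels = 32L, spacing = c(1, 1, 1)) {
  vol <- study$volume
  if (length(dim(vol)) == 4L) vol <- vol[1, , , ]
  vol <- rescale_intensity(vol)
  droi <- discretize_roi(vol, study$mask, n_levels = n_levels,
                         spacing = spacing)
  out <- tryCatch(
    c(firstorder_features(droi$intensities),
      shape_features(study$mask, spacing),
      glcm_features(droi),
      gldm_features(droi),
      glszm_features(droi),
      ngtdm_features(droi)),
    error = function(e) stop(sprintf("study %s: %s", study$study_id,
                                     conditionMessage(e)), call. = FALSE))
  out <- out[radiomics_feature_names()]
  if (any(!is.finite(out)))
    stop(sprintf("study %s: non-finite features: %s", study$study_id,
                 paste(names(out)[!is.finite(out)], collapse = ", ")))
  out
}

#' Extract the feature matrix of a cohort
#'
#' @param cohort list of `lf_study`.
#' @param n_levels gray levels for discretization.
#' @return numeric matrix, one row per study (rownames = study ids).
#' @export
extract_cohort_features <- function(cohort, n_levels = 32L) {
  X <- t(vapply(cohort, extract_feature_vector,
                numeric(length(radiomics_feature_names())),
                n_levels = n_levels))
  rownames(X) <- vapply(cohort, function(s) s$study_id, character(1))
  X
}

#' Fit / apply fold-aware feature standardization
#'
#' Column means and SDs are fitted on training rows only and applied to
#' validation/test rows, preventing information leakage across folds.
#' Zero-SD columns are passed through centred only.
#'
#' @param X training feature matrix.
#' @return an `lf_scaler` (means, sds).
#' @export
fit_feature_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  structure(list(mean = mu, sd = sd), class = "lf_scaler")
}

#' @rdname fit_feature_scaler
#' @param scaler an `lf_scaler`.
#' @param newX matrix (or vector) to standardize.
#' @export
apply_feature_scaler <- function(scaler, newX) {
  if (is.null(dim(newX))) newX <- matrix(newX, nrow = 1,
                                         dimnames = list(NULL, names(newX)))
  sweep(sweep(newX, 2, scaler$mean), 2, scaler$sd, "/")
}
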