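#' Phantom generator parameters
#'
#' Bundles and validates the knobs of the synthetic lesion-phantom
#' generator. Phantoms are brain-scale 3-D intensity volumes containing one
#' or more ellipsoidal "lesions" whose internal texture and shape depend on
#' the class label, over a noisy background, with per-study multiplicative
#' intensity jitter emulating scanner scale variation.
#'
#' The two classes are built to differ in exactly the properties the
#' downstream model is meant to pick up:
#' * class 1 ("AF-like"): voxel-wise alternating high/low intensity inside
#'   the lesion (a 3-D checkerboard of amplitude `texture_amp`), which
#'   drives neighbourhood gray-tone contrast (NGTDM/GLCM families), plus an
#'   elongated lesion shape;
#' * class 0 ("non-AF-like"): low-pass-filtered Gaussian texture of small
#'   amplitude (smooth), near-spherical lesion.
#'
#' @param grid_shape integer triple (slices, rows, cols), each >= 8.
#' @param n_lesions_range integer pair, inclusive range of lesion count.
#' @param lesion_radius_range numeric pair, voxel-unit nominal radii.
#' @param class_effect named list with elements `"0"` and `"1"`, each a list
#'   with `texture` (`"smooth"` or `"checkerboard"`), `texture_amp`
#'   (intensity units; the per-voxel texture SD for smooth, the half-swing
#'   for checkerboard), `texture_period` (cell edge in voxels for the
#'   checkerboard; a coarse period gives the same marginal distribution as
#'   a fine one but low neighbourhood contrast), `base_intensity` and
#'   `elongation` (>= 1; ratio of the long to the short lesion semi-axis
#'   scale).
#' @param noise_sd additive Gaussian noise SD (intensity units, >= 0).
#' @param intensity_scale_jitter multiplicative range (lo, hi) applied to the
#'   whole study volume.
#' @param n_channels number of image channels (default 1).
#' @param correlate_metadata logical; if `TRUE`, simulated clinical metadata
#'   (age, CHA2DS2-VASc) are shifted upward for class-1 studies so subgroup
#'   machinery can be exercised under an enriched regime; default samples
#'   metadata independently of the label (a null regime).
#' @return an object of class `lf_phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(32L, 64L, 64L),
                           n_lesions_range = c(1L, 2L),
                           lesion_radius_range = c(4, 8),
                           class_effect = list(
                             "0" = list(texture = "smooth", texture_amp = 0.1,
                                        base_intensity = 0.7, elongation = 1),
                             "1" = list(texture = "checkerboard",
                                        texture_amp = 0.4, texture_period = 1,
                                        base_intensity = 0.7, elongation = 2)
                           ),
                           noise_sd = 0.05,
                           intensity_scale_jitter = c(0.8, 1.25),
                           n_channels = 1L,
                           correlate_metadata = FALSE) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            length(n_lesions_range) == 2L, n_lesions_range[1] >= 1L,
            n_lesions_range[1] <= n_lesions_range[2],
            length(lesion_radius_range) == 2L,
            lesion_radius_range[1] > 0,
            lesion_radius_range[1] <= lesion_radius_range[2],
            noise_sd >= 0,
            length(intensity_scale_jitter) == 2L,
            intensity_scale_jitter[1] > 0,
            intensity_scale_jitter[1] <= intensity_scale_jitter[2],
            n_channels >= 1L)
  if (!all(c("0", "1") %in% names(class_effect)))
    stop("class_effect must define recipes for both classes \"0\" and \"1\"")
  for (cl in c("0", "1")) {
    ce <- class_effect[[cl]]
    stopifnot(is.list(ce), ce$texture_amp >= 0, ce$elongation >= 1,
              (ce$texture %||% "smooth") %in% c("smooth", "checkerboard"))
  }
  # the largest semi-axis must fit inside the grid
  emax <- max(vapply(class_effect, function(ce) ce$elongation, numeric(1)))
  if (lesion_radius_range[2] * sqrt(emax) * 2 >= min(grid_shape))
    stop("lesion radii do not fit inside the grid (placement impossible)")
  structure(list(grid_shape = grid_shape,
                 n_lesions_range = as.integer(n_lesions_range),
                 lesion_radius_range = lesion_radius_range,
                 class_effect = class_effect,
                 noise_sd = noise_sd,
                 intensity_scale_jitter = intensity_scale_jitter,
                 n_channels = as.integer(n_channels),
                 correlate_metadata = isTRUE(correlate_metadata)),
            class = "lf_phantom_params")
}

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so generators are pure functions of their seeds
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a per-study child seed < 2^31 from a master seed
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 104729 + 12345) %%
               2147483647)
}

# 3-D box smoothing (3^3 mean filter) used for the smooth class-0 texture
box_smooth3 <- function(a) {
  d <- dim(a)
  out <- array(0, d)
  cnt <- array(0, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
    zt <- zs - dz; yt <- ys - dy; xt <- xs - dx
    out[zt, yt, xt] <- out[zt, yt, xt] + a[zs, ys, xs]
    cnt[zt, yt, xt] <- cnt[zt, yt, xt] + 1
  }
  out / cnt
}

#' Generate a single labelled phantom study
#'
#' Draws lesion geometry, paints the class-specific internal texture, adds
#' background noise and intensity jitter. Deterministic for a fixed
#' `(params, label, seed)` triple.
#'
#' @param params an [phantom_params()] object.
#' @param label class label, 0 or 1.
#' @param seed integer seed controlling every random draw in this study.
#' @param study_id identifier string.
#' @return an object of class `lf_study`: list with `volume` (3-D array, or
#'   4-D channel-first when `n_channels > 1`), `mask` (3-D 0/1 array),
#'   `label`, `study_id`, `metadata` and a `lesions` table of the drawn
#'   geometry (centres, semi-axes, nominal radius).
#' @export
generate_study <- function(params, label, seed, study_id = "S1") {
  stopifnot(inherits(params, "lf_phantom_params"), label %in% c(0, 1))
  with_seed(seed, {
    d <- params$grid_shape
    ce <- params$class_effect[[as.character(label)]]
    n_lesions <- sample(params$n_lesions_range[1]:params$n_lesions_range[2], 1)
    mask <- array(0L, d)
    tex <- array(0, d)
    lesions <- vector("list", n_lesions)
    for (li in seq_len(n_lesions)) {
      r <- stats::runif(1, params$lesion_radius_range[1],
                        params$lesion_radius_range[2])
      e <- ce$elongation
      # volume-preserving anisotropy: long semi-axis r*sqrt(e), short r/e^(1/4)
      ax <- rep(r / e^0.25, 3)
      long_axis <- sample(2:3, 1)  # elongate in-plane (rows or cols)
      ax[long_axis] <- r * sqrt(e)
      lo <- ceiling(ax) + 1
      hi <- d - ceiling(ax)
      if (any(hi < lo)) stop("lesion cannot be placed inside the grid")
      ctr <- vapply(1:3, function(k) {
        if (lo[k] == hi[k]) as.numeric(lo[k])
        else as.numeric(sample(lo[k]:hi[k], 1))
      }, numeric(1))
      zz <- ((seq_len(d[1]) - ctr[1]) / ax[1])^2
      yy <- ((seq_len(d[2]) - ctr[2]) / ax[2])^2
      xx <- ((seq_len(d[3]) - ctr[3]) / ax[3])^2
      inside <- outer(outer(zz, yy, "+"), xx, "+") <= 1
      mask[inside] <- 1L
      lesions[[li]] <- data.frame(z = ctr[1], y = ctr[2], x = ctr[3],
                                  az = ax[1], ay = ax[2], axx = ax[3],
                                  radius = r)
    }
    # class texture inside the lesion
    if ((ce$texture %||% "smooth") == "checkerboard") {
      p <- ce$texture_period %||% 1
      idx <- which(mask == 1L, arr.ind = TRUE)
      parity <- (((idx[, 1] - 1) %/% p) + ((idx[, 2] - 1) %/% p) +
                   ((idx[, 3] - 1) %/% p)) %% 2
      tex[mask == 1L] <- ce$texture_amp * (2 * parity - 1)
    } else {
      # low-pass-filtered noise, rescaled so texture_amp is the per-voxel
      # SD for both class recipes (the classes then differ in spatial
      # arrangement, not marginal amplitude)
      sm <- box_smooth3(box_smooth3(array(stats::rnorm(prod(d)), d)))
      s <- stats::sd(sm)
      if (s > 0) sm <- sm / s
      tex[mask == 1L] <- ce$texture_amp * sm[mask == 1L]
    }
    background <- 0.1
    vol <- array(background, d) + tex
    vol[mask == 1L] <- vol[mask == 1L] + (ce$base_intensity - background)
    if (params$noise_sd > 0)
      vol <- vol + array(stats::rnorm(prod(d), sd = params$noise_sd), d)
    vol <- vol * stats::runif(1, params$intensity_scale_jitter[1],
                              params$intensity_scale_jitter[2])
    if (params$n_channels > 1L) {
      vol <- array(rep(as.vector(vol), params$n_channels),
                   c(d, params$n_channels))
      vol <- aperm(vol, c(4, 1, 2, 3))
    }
    metadata <- sample_metadata(label, params$correlate_metadata)
    structure(list(volume = vol, mask = mask, label = as.integer(label),
                   study_id = study_id, metadata = metadata,
                   lesions = do.call(rbind, lesions)),
              class = "lf_study")
  })
}

# metadata sampling rules (documented defaults): sex ~ Bernoulli(0.65 male),
# age ~ N(71.6, 12) rounded, NIHSS ~ |N(6, 7)| rounded, CHA2DS2-VASc ~ 0..8
# weighted toward mid scores. Under the enriched regime class-1 studies get
# +6 years of age and +1.5 CHA2DS2-VASc points before rounding/clamping.
sample_metadata <- function(label, correlate) {
  age <- stats::rnorm(1, 71.6, 12)
  chads <- sample(0:8, 1, prob = c(1, 2, 4, 6, 8, 9, 8, 4, 2))
  if (correlate && label == 1) {
    age <- age + 6
    chads <- min(8, chads + round(stats::runif(1, 1, 2)))
  }
  list(sex = sample(c("male", "female"), 1, prob = c(0.65, 0.35)),
       age = max(18, round(age)),
       nihss = round(abs(stats::rnorm(1, 6, 7))),
       chads_vasc = chads)
}

#' Generate a balanced labelled phantom cohort
#'
#' Produces `2 * n_per_class` studies with unique ids, balanced labels and
#' per-study seeds derived reproducibly from `seed`. A pure function of
#' `(params, n_per_class, seed)`.
#'
#' @inheritParams generate_study
#' @param n_per_class studies per class (>= 1).
#' @param seed master seed.
#' @return list of `lf_study`, classes interleaved (0, 1, 0, 1, ...).
#' @export
generate_cohort <- function(params, n_per_class, seed) {
  stopifnot(n_per_class >= 1)
  n <- 2L * as.integer(n_per_class)
  labels <- rep(c(0L, 1L), n_per_class)
  lapply(seq_len(n), function(i) {
    generate_study(params, labels[i], derive_seed(seed, i),
                   study_id = sprintf("S%03d", i))
  })
}

#' @export
print.lf_study <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("<lf_study %s> label=%d volume=[%s] lesion voxels=%d\n",
              x$study_id, x$label, paste(d, collapse = "x"), sum(x$mask)))
  invisible(x)
}

#' Write a cohort to disk as NIfTI pairs plus a manifest
#'
#' Each study becomes `<id>_vol.nii.gz` and `<id>_mask.nii.gz` under `dir`,
#' and `manifest.csv` lists (study_id, volume_path, mask_path, label,
#' metadata columns).
#'
#' @param cohort list of `lf_study`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    vp <- file.path(dir, paste0(s$study_id, "_vol.nii.gz"))
    mp <- file.path(dir, paste0(s$study_id, "_mask.nii.gz"))
    RNifti::writeNifti(s$volume, vp)
    RNifti::writeNifti(s$mask, mp)
    data.frame(study_id = s$study_id, volume_path = vp, mask_path = mp,
               label = s$label, sex = s$metadata$sex, age = s$metadata$age,
               nihss = s$metadata$nihss, chads_vasc = s$metadata$chads_vasc,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
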