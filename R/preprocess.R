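#' Zero-pad a volume to the canonical tensor shape
#'
#' Centres the input in a zero grid of the canonical spatial shape
#' (default 32 x 256 x 256), preserving the intensity sum exactly and
#' recording the applied offsets so the padding is reversible with
#' [unpad_canonical()]. Inputs may be 3-D or channel-first 4-D; the output
#' is always channel-first 4-D.
#'
#' No cropping is defined: any spatial dimension exceeding the canonical
#' size is an error, since the canonical grid is chosen larger than all
#' expected data.
#'
#' @param volume 3-D array (z, y, x) or 4-D array (C, z, y, x).
#' @param canonical integer triple, canonical spatial shape.
#' @return object of class `lf_canonical`: list with `data` (C, 32, 256,
#'   256 by default) and `provenance` (original dims, channel flag, offsets).
#' @export
pad_to_canonical <- function(volume, canonical = c(32L, 256L, 256L)) {
  had_channels <- length(dim(volume)) == 4L
  if (!had_channels) {
    if (is.null(dim(volume)) || length(dim(volume)) != 3L)
      stop("volume must be a 3-D or channel-first 4-D array")
    dim(volume) <- c(1L, dim(volume))
  }
  d <- dim(volume)
  sp <- d[2:4]
  if (any(sp > canonical))
    stop(sprintf("spatial dims (%s) exceed canonical size (%s); no cropping is defined",
                 paste(sp, collapse = ","), paste(canonical, collapse = ",")))
  off <- (canonical - sp) %/% 2L
  out <- array(0, c(d[1], canonical))
  out[, off[1] + seq_len(sp[1]), off[2] + seq_len(sp[2]),
      off[3] + seq_len(sp[3])] <- volume
  structure(list(data = out,
                 provenance = list(original_spatial = sp,
                                   had_channels = had_channels,
                                   offsets = off, canonical = canonical)),
            class = "lf_canonical")
}

#' Undo canonical padding using recorded provenance
#'
#' @param cv an `lf_canonical` object.
#' @return the original array (3-D if the input to [pad_to_canonical()] was
#'   3-D), bit-identical to it.
#' @export
unpad_canonical <- function(cv) {
  stopifnot(inherits(cv, "lf_canonical"))
  p <- cv$provenance
  out <- cv$data[, p$offsets[1] + seq_len(p$original_spatial[1]),
                 p$offsets[2] + seq_len(p$original_spatial[2]),
                 p$offsets[3] + seq_len(p$original_spatial[3]), drop = FALSE]
  dim(out) <- c(dim(cv$data)[1], p$original_spatial)
  if (!p$had_channels) dim(out) <- p$original_spatial
  out
}

#' Min-max rescale intensities onto [0, 1]
#'
#' Per-study monotone mapping `(x - min) / (max - min)`. A constant volume
#' is degenerate (no contrast to preserve): it maps to all zeros with a
#' warning.
#'
#' @param volume numeric array with finite values.
#' @return array of the same shape with min 0 and max 1 (non-constant input).
#' @export
rescale_intensity <- function(volume) {
  if (!all(is.finite(volume))) stop("volume must be finite")
  lo <- min(volume); hi <- max(volume)
  if (hi == lo) {
    warning("degenerate input: constant volume rescaled to all zeros")
    return(array(0, dim(volume)))
  }
  (volume - lo) / (hi - lo)
}

#' Downsample a canonical volume to the model-input tensor
#'
#' 4x in-plane downsampling from (C, 32, 256, 256) to (C, 32, 64, 64): block
#' mean for intensities, majority vote for the mask (ties counted as
#' foreground). The slice axis is untouched, so spatial alignment is exact:
#' a low-resolution voxel covers precisely its 4 x 4 in-plane block.
#'
#' @param cv an `lf_canonical` object (or a 4-D array of canonical shape).
#' @param mask 3-D binary array aligned with the canonical grid, or `NULL`.
#' @return object of class `lf_model_input`: list with `data` (C, 32, 64,
#'   64) and `mask_lowres` (32, 64, 64 in 0/1, or `NULL`).
#' @export
resample_to_model_input <- function(cv, mask = NULL) {
  data <- if (inherits(cv, "lf_canonical")) cv$data else cv
  d <- dim(data)
  stopifnot(length(d) == 4L, d[3] %% 4L == 0L, d[4] %% 4L == 0L)
  out <- block_mean_inplane(data, 4L)
  mask_lr <- NULL
  if (!is.null(mask)) {
    m4 <- array(as.double(mask), c(1L, dim(mask)))
    frac <- block_mean_inplane(m4, 4L)[1, , , ]
    mask_lr <- array(ifelse(frac >= 0.5, 1L, 0L), dim(frac))
  }
  structure(list(data = out, mask_lowres = mask_lr),
            class = "lf_model_input")
}

# mean over f x f in-plane blocks of a (C, Z, Y, X) array
block_mean_inplane <- function(a, f) {
  d <- dim(a)
  dim(a) <- c(d[1], d[2], f, d[3] %/% f, f, d[4] %/% f)
  a <- apply(a, c(1, 2, 4, 6), mean)
  a
}

#' Preprocess one study into the network's input tensor
#'
#' Rescales intensities to [0, 1], then: if the study is already at the
#' model-input spatial shape it is used directly; otherwise it is zero-padded
#' to the canonical 32 x 256 x 256 grid and block-resampled down to
#' 32 x 64 x 64 (the mask following by majority vote).
#'
#' @param study an `lf_study`.
#' @param model_shape target spatial shape.
#' @return an `lf_model_input` with `data` (C, z, y, x) and `mask_lowres`.
#' @export
preprocess_study <- function(study, model_shape = c(32L, 64L, 64L)) {
  vol <- rescale_intensity(study$volume)
  if (length(dim(vol)) == 3L) dim(vol) <- c(1L, dim(vol))
  sp <- dim(vol)[2:4]
  if (all(sp == model_shape)) {
    structure(list(data = vol,
                   mask_lowres = array(as.integer(study$mask), dim(study$mask))),
              class = "lf_model_input")
  } else {
    cv <- pad_to_canonical(vol, canonical = c(model_shape[1],
                                              model_shape[2] * 4L,
                                              model_shape[3] * 4L))
    pm <- pad_to_canonical(array(as.double(study$mask),
                                 c(1L, dim(study$mask))),
                           canonical = dim(cv$data)[2:4])
    mask_canon <- pm$data[1, , , ]
    resample_to_model_input(cv, mask_canon)
  }
}
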