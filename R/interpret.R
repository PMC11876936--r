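# Interpretability: Grad-CAM saliency over the classification branch and
# the feature-significance-ranking (FSR) machinery over the radiomics
# attention weights.

# trilinear upsampling of a 3-D map by an integer factor per axis
# (aligned so output voxel i samples input coordinate (i + 0.5)/f - 0.5)
upsample_trilinear <- function(a, factor = c(4L, 4L, 4L)) {
  d <- dim(a)
  axes <- lapply(1:3, function(k) {
    pos <- (seq_len(d[k] * factor[k]) - 0.5) / factor[k] - 0.5
    lo <- pmax(pmin(floor(pos), d[k] - 1), 0)
    hi <- pmin(lo + 1, d[k] - 1)
    w <- pos - lo
    w[pos <= 0] <- 0
    w[pos >= d[k] - 1] <- 0
    list(lo = lo + 1, hi = hi + 1, w = w)
  })
  # interpolate one axis at a time
  out <- a
  for (k in 1:3) {
    ax <- axes[[k]]
    pick <- function(arr, idx) {
      if (k == 1) arr[idx, , , drop = FALSE]
      else if (k == 2) arr[, idx, , drop = FALSE]
      else arr[, , idx, drop = FALSE]
    }
    lo_a <- pick(out, ax$lo)
    hi_a <- pick(out, ax$hi)
    wdim <- c(1, 1, 1)
    wdim[k] <- length(ax$w)
    warr <- array(0, dim(lo_a))
    perm_w <- aperm(array(ax$w, c(wdim[k], dim(lo_a)[-k])),
                    order(c(k, (1:3)[-k])))
    warr[] <- perm_w
    out <- lo_a * (1 - warr) + hi_a * warr
  }
  out
}

#' Grad-CAM saliency map for the classification branch
#'
#' Channel weights are the global average of the gradient of the target
#' class score (pre-softmax logit) with respect to the target layer's
#' activation; the map is `ReLU(sum_c w_c A_c)`, trilinear-upsampled to the
#' model-input spatial shape and min-max normalized onto [0, 1]. With
#' global average pooling directly above the target layer the gradient is
#' spatially constant, so the channel weights reduce to the head gradient
#' divided by the voxel count (classic CAM). A constant (zero-gradient or
#' zero-activation) map is degenerate: an all-zero map is returned with
#' attribute `degenerate = TRUE`.
#'
#' @param model an `lf_model`.
#' @param input an `lf_model_input` (or 4-D array).
#' @param z standardized radiomics vector.
#' @param target_class class whose score is explained (0 or 1).
#' @param target_head `"cnn"` or `"combined"` (default): which head's logit
#'   is differentiated.
#' @param target_layer currently only `"cls3"`, the last (modulated)
#'   convolutional activation of the classification branch.
#' @return object of class `lf_saliency`: 3-D map in [0, 1] at model-input
#'   shape, with attributes `target_head`, `target_class`, `target_layer`,
#'   `degenerate`.
#' @export
grad_cam <- function(model, input, z, target_class = 1L,
                     target_head = c("combined", "cnn"),
                     target_layer = "cls3") {
  target_head <- match.arg(target_head)
  if (!identical(target_layer, "cls3"))
    stop("unknown target layer: ", target_layer)
  fw <- forward_fusion(model, input, z, keep = TRUE)
  cc <- fw$cache
  p <- model$par
  ci <- target_class + 1L
  # d logit / d sem
  if (target_head == "cnn") {
    g_sem <- p$cnn_W[ci, ]
  } else {
    g_f1 <- p$f2_W[ci, ] * (cc$f1z > 0)
    g_v <- as.vector(t(p$f1_W) %*% g_f1)
    g_sem <- g_v[seq_along(cc$sem)]
  }
  g_semz <- g_sem * (cc$sem_z > 0)
  g_gap <- as.vector(t(p$sem_W) %*% g_semz)
  A <- as_mat(cc$m3)  # voxels x channels
  V <- nrow(A)
  wts <- g_gap / V  # GAP makes d logit / d A spatially constant
  cam <- as.vector(A %*% wts)
  cam[cam < 0] <- 0
  sp3 <- dim(cc$m3)[1:3]
  cam <- array(cam, sp3)
  sp1 <- dim(cc$x)[1:3]
  cam_up <- upsample_trilinear(cam, factor = as.integer(sp1 / sp3))
  lo <- min(cam_up); hi <- max(cam_up)
  degenerate <- hi <= lo
  out <- if (degenerate) array(0, sp1) else (cam_up - lo) / (hi - lo)
  structure(out, class = "lf_saliency", target_head = target_head,
            target_class = as.integer(target_class),
            target_layer = target_layer, degenerate = degenerate)
}

#' Feature significance ranking from attention weights
#'
#' Overall significance of each radiomics feature is the columnwise mean of
#' the per-study attention-weight simplex vectors (so overall significances
#' sum to 1); per-class significances average over the studies predicted
#' (or labelled, if `predictions` carries true labels) in each class.
#' Features are ranked by descending overall significance, ties broken by
#' the fixed feature order.
#'
#' @param weight_rows matrix (studies x features) of simplex weight vectors.
#' @param predictions integer 0/1 vector, one per study.
#' @param top_k size of the top view (default 8).
#' @return object of class `lf_fsr`: data.frame (feature, family, overall,
#'   class0, class1, rank) sorted by rank, plus a `top_k` attribute.
#' @export
fsr_ranking <- function(weight_rows, predictions, top_k = 8L) {
  weight_rows <- as.matrix(weight_rows)
  stopifnot(nrow(weight_rows) >= 1,
            length(predictions) == nrow(weight_rows))
  overall <- colMeans(weight_rows)
  cls_mean <- function(k) {
    idx <- which(predictions == k)
    if (!length(idx)) rep(NA_real_, ncol(weight_rows))
    else colMeans(weight_rows[idx, , drop = FALSE])
  }
  nm <- colnames(weight_rows)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(weight_rows)))
  ord <- order(-overall, seq_along(overall))
  rank <- integer(length(overall))
  rank[ord] <- seq_along(ord)
  out <- data.frame(feature = nm,
                    family = sub("_.*$", "", nm),
                    overall = overall,
                    class0 = cls_mean(0L),
                    class1 = cls_mean(1L),
                    rank = rank,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$rank), ]
  structure(out, class = c("lf_fsr", "data.frame"), top_k = as.integer(top_k))
}

#' @export
print.lf_fsr <- function(x, ...) {
  k <- min(attr(x, "top_k"), nrow(x))
  cat(sprintf("<lf_fsr> top %d of %d features by average significance:\n",
              k, nrow(x)))
  print.data.frame(utils::head(x, k), digits = 4)
  invisible(x)
}

#' Top-k FSR bar plot
#'
#' @param fsr an `lf_fsr`.
#' @param k bars to show (default the ranking's `top_k`).
#' @export
plot_fsr <- function(fsr, k = attr(fsr, "top_k")) {
  k <- min(k, nrow(fsr))
  top <- utils::head(fsr, k)
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(top$overall), names.arg = rev(top$feature),
                    horiz = TRUE, las = 1,
                    xlab = "average significance",
                    main = sprintf("Top %d radiomics features", k))
  invisible(top)
}

#' Write a saliency map as NIfTI aligned to the model-input grid
#'
#' @param saliency an `lf_saliency`.
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_saliency <- function(saliency, path) {
  RNifti::writeNifti(unclass(saliency), path)
  invisible(path)
}
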