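#' lesionfuse: segmentation-guided multi-task 3D lesion classification
#'
#' Two-branch multi-task framework for 3-D medical-image classification: a
#' 3D U-Net segmentation branch supplies prior attention to a 3D CNN
#' classification branch, and self-attention-weighted radiomics features
#' are fused with the CNN semantic features for the final decision. The
#' package covers synthetic phantom generation, preprocessing, radiomics
#' (from definitions), the network and its two-stage training with
#' fivefold cross-validation, ROC-based evaluation with bootstrap CIs and
#' subgroup reports, and Grad-CAM / feature-significance interpretability.
#'
#' @useDynLib lesionfuse, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

#' Fit the two-branch fusion classifier with cross-validated training
#'
#' The main modelling front-end: extracts radiomics features, assigns
#' patient-level folds, trains the two-stage model per fold and keeps the
#' minimum-validation-loss checkpoints. The fitted object predicts new
#' studies by averaging the per-head probabilities of the fold models
#' (cross-fold ensembling) and reports out-of-fold performance on the
#' training cohort.
#'
#' @param cohort list of `lf_study` (e.g. from [generate_cohort()] or
#'   [load_cohort()]).
#' @param config an [lf_config()].
#' @return object of class `lesionfuse` with components `states` (fold
#'   checkpoints), `plan` (fold assignment), `features`, `scores`
#'   (out-of-fold per-study head probabilities), `config`.
#' @seealso [predict.lesionfuse()], [summary.lesionfuse()],
#'   [coef.lesionfuse()], [plot.lesionfuse()]
#' @export
lesionfuse <- function(cohort, config = lf_config()) {
  ids <- vapply(cohort, function(s) s$study_id, character(1))
  features <- extract_cohort_features(cohort, n_levels = config$n_levels)
  plan <- assign_folds(ids, k = config$k_folds,
                       seed = derive_seed(config$seed, 17L))
  states <- lapply(seq_len(config$k_folds) - 1L, function(f)
    train_fold(cohort, plan, f, config, features = features))
  rows <- lapply(seq_len(config$k_folds) - 1L, function(f) {
    idx <- which(plan$assignment[ids] == f)
    predict_fold(states[[f + 1]], cohort[idx], features = features)
  })
  scores <- do.call(rbind, rows)
  scores <- scores[match(ids, scores$study_id), ]
  structure(list(states = states, plan = plan, features = features,
                 scores = scores, config = config,
                 metadata = cohort_metadata(cohort)),
            class = "lesionfuse")
}

#' @export
print.lesionfuse <- function(x, ...) {
  cat(sprintf("<lesionfuse> %d-fold fitted model on %d studies (config %s)\n",
              x$config$k_folds, nrow(x$scores), x$config$hash))
  auc <- tryCatch(roc_auc(x$scores$p_com, x$scores$label), error = function(e) NA)
  cat(sprintf("  out-of-fold combined-head AUC: %.3f\n", auc))
  invisible(x)
}

#' Out-of-fold performance summary of a fitted model
#'
#' @param object a `lesionfuse` fit.
#' @param n_boot bootstrap resamples for the CIs.
#' @param ... unused.
#' @return named list of `lf_metrics`, one per head.
#' @export
summary.lesionfuse <- function(object, n_boot = 500L, ...) {
  out <- lapply(c(radiomics = "p_rad", cnn = "p_cnn", combined = "p_com"),
                function(col) evaluate_scores(
                  object$scores[[col]], object$scores$label, head = col,
                  n_boot = n_boot,
                  seed = derive_seed(object$config$seed, 23L)))
  class(out) <- "summary.lesionfuse"
  out
}

#' @export
print.summary.lesionfuse <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

#' Ensemble prediction for new studies
#'
#' @param object a `lesionfuse` fit.
#' @param newdata list of `lf_study`.
#' @param ... unused.
#' @return data.frame with per-head ensemble class-1 probabilities.
#' @export
predict.lesionfuse <- function(object, newdata, ...) {
  ensemble_predict(object$states, newdata)
}

#' Feature-significance coefficients of a fitted model
#'
#' Returns the cohort-mean radiomics attention weights (the FSR overall
#' significances) computed from the out-of-fold attention rows.
#'
#' @param object a `lesionfuse` fit.
#' @param ... unused.
#' @return named numeric vector summing to 1.
#' @export
coef.lesionfuse <- function(object, ...) {
  w <- fsr_weight_rows(object)
  colMeans(w)
}

# per-study out-of-fold attention-weight rows
fsr_weight_rows <- function(object) {
  ids <- rownames(object$features)
  t(vapply(seq_along(ids), function(i) {
    st <- object$states[[object$plan$assignment[ids[i]] + 1]]
    z <- apply_feature_scaler(st$scaler,
                              object$features[ids[i], , drop = FALSE])[1, ]
    as.vector(radiomics_attention(z, st$model$par$attn_a,
                                  st$model$par$attn_g)$weights)
  }, numeric(ncol(object$features)))) |>
    (\(m) { colnames(m) <- colnames(object$features); rownames(m) <- ids; m })()
}

#' ROC curves of the three heads (out-of-fold scores)
#'
#' @param x a `lesionfuse` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lesionfuse <- function(x, ...) {
  roc_points <- function(scores, labels) {
    th <- c(Inf, sort(unique(scores), decreasing = TRUE))
    t(vapply(th, function(t0) c(
      fpr = mean(scores[labels == 0] >= t0),
      tpr = mean(scores[labels == 1] >= t0)), numeric(2)))
  }
  cols <- c(p_rad = "steelblue", p_cnn = "darkorange", p_com = "firebrick")
  graphics::plot(0:1, 0:1, type = "l", lty = 3, col = "grey",
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  for (h in names(cols)) {
    rp <- roc_points(x$scores[[h]], x$scores$label)
    graphics::lines(rp[, "fpr"], rp[, "tpr"], col = cols[[h]], lwd = 2)
  }
  graphics::legend("bottomright", bty = "n", lwd = 2, col = cols,
                   legend = sprintf("%s (AUC %.2f)",
                                    c("radiomics", "cnn", "combined"),
                                    vapply(names(cols), function(h)
                                      roc_auc(x$scores[[h]], x$scores$label),
                                      numeric(1))))
  invisible(x)
}
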