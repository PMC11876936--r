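#' Area under the ROC curve
#'
#' Rank-based Mann-Whitney estimate: the probability that a random positive
#' scores above a random negative, ties counted 1/2. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels, both classes present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap confidence interval for the AUC
#'
#' Stratified bootstrap percentile interval: positives and negatives are
#' resampled within class (so both classes are always present in a
#' resample and no redraws are needed; the degenerate-resample counter is
#' reported for the contract and is always 0 under stratification).
#'
#' @inheritParams roc_auc
#' @param n_boot resamples (default 2000).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lo, hi)` with attribute `n_degenerate`.
#' @export
auc_ci <- function(scores, labels, n_boot = 2000L, seed = 1L, level = 0.95) {
  labels <- as.integer(labels)
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (!length(pos) || !length(neg)) stop("both classes must be present")
  aucs <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    i <- c(sample(pos, length(pos), replace = TRUE),
           sample(neg, length(neg), replace = TRUE))
    roc_auc(scores[i], labels[i])
  }, numeric(1)))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(aucs, c(alpha, 1 - alpha)))
  attr(ci, "n_degenerate") <- 0L
  ci
}

#' Operating point maximizing sensitivity + specificity
#'
#' Candidate thresholds are the midpoints between adjacent distinct scores
#' together with one below the minimum and one above the maximum; a score
#' `>= cutoff` is called positive. Ties in the objective are broken toward
#' higher specificity (the largest optimal cutoff).
#'
#' @inheritParams roc_auc
#' @return the selected cutoff (numeric scalar).
#' @export
optimal_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!any(labels == 1) || !any(labels == 0))
    stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  obj <- vapply(cand, function(th) {
    sens <- mean(scores[labels == 1] >= th)
    spec <- mean(scores[labels == 0] < th)
    sens + spec
  }, numeric(1))
  best <- max(obj)
  max(cand[obj >= best - 1e-12])  # tie-break: higher cutoff = higher spec
}

#' Confusion-matrix metrics at a cutoff
#'
#' Scores `>= cutoff` are called positive. Rates are percentages; a
#' zero-denominator rate (e.g. PPV with no positive calls) is returned as
#' `NA` (an explicit undefined marker), never propagated as NaN.
#'
#' @inheritParams roc_auc
#' @param cutoff decision threshold.
#' @return named list: tp, fp, tn, fn, sensitivity, specificity, accuracy,
#'   ppv, npv (percent), n_pos, n_neg.
#' @export
confusion_metrics <- function(scores, labels, cutoff) {
  stopifnot(is.finite(cutoff))
  labels <- as.integer(labels)
  pred <- scores >= cutoff
  tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0); fp <- sum(pred & labels == 0)
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = rate(tp, tp + fn),
       specificity = rate(tn, tn + fp),
       accuracy = rate(tp + tn, tp + tn + fp + fn),
       ppv = rate(tp, tp + fp),
       npv = rate(tn, tn + fn),
       n_pos = tp + fn, n_neg = tn + fp)
}

#' Full metrics report for one classifier head
#'
#' AUC with bootstrap CI, the max(sens + spec) operating point selected on
#' the evaluated scores themselves, and the confusion-matrix rates at that
#' point.
#'
#' @inheritParams auc_ci
#' @param head label for the classifier head.
#' @param cutoff optional externally supplied cutoff (e.g. fold-internal);
#'   default selects the optimum on these scores.
#' @return object of class `lf_metrics`.
#' @export
evaluate_scores <- function(scores, labels, head = "combined",
                            n_boot = 2000L, seed = 1L, cutoff = NULL) {
  auc <- roc_auc(scores, labels)
  ci <- auc_ci(scores, labels, n_boot = n_boot, seed = seed)
  if (is.null(cutoff)) cutoff <- optimal_cutoff(scores, labels)
  cm <- confusion_metrics(scores, labels, cutoff)
  structure(c(list(head = head, auc = auc, auc_ci = ci, cutoff = cutoff),
              cm),
            class = "lf_metrics")
}

#' @export
print.lf_metrics <- function(x, ...) {
  cat(sprintf(
    "<lf_metrics %s> AUC %.3f [%.3f, %.3f] | sens %.1f%% spec %.1f%% acc %.1f%% ppv %.1f%% npv %.1f%% (n+=%d n-=%d)\n",
    x$head, x$auc, x$auc_ci[1], x$auc_ci[2], x$sensitivity, x$specificity,
    x$accuracy, x$ppv, x$npv, x$n_pos, x$n_neg))
  invisible(x)
}

#' Mean and SD of metrics across folds
#'
#' @param reports list of `lf_metrics` (>= 2 folds).
#' @return matrix with rows `mean` and `sd` over auc, sensitivity,
#'   specificity, accuracy, ppv, npv.
#' @export
crossval_summary <- function(reports) {
  stopifnot(length(reports) >= 2)
  metrics <- c("auc", "sensitivity", "specificity", "accuracy", "ppv", "npv")
  vals <- vapply(reports, function(r)
    unlist(r[metrics]), numeric(length(metrics)))
  rbind(mean = rowMeans(vals, na.rm = TRUE),
        sd = apply(vals, 1, stats::sd, na.rm = TRUE))
}

#' Metrics within metadata-defined strata
#'
#' Default strata mirror the subgroup analysis: sex; age <= 70 vs > 70;
#' NIHSS <= 4 vs > 4; CHA2DS2-VASc <= 3 vs > 3. A stratum containing a
#' single class is reported as not evaluable (`NULL` report with
#' `evaluable = FALSE`).
#'
#' @inheritParams roc_auc
#' @param metadata data.frame with one row per score (columns used by
#'   `strata_spec`).
#' @param strata_spec named list of functions mapping the metadata frame to
#'   a factor/character stratum vector; default uses sex, age, nihss,
#'   chads_vasc.
#' @param n_boot,seed bootstrap settings for the per-stratum CIs.
#' @return nested list: `[[variable]][[stratum]]` is a list with
#'   `evaluable`, `n` and (if evaluable) `report` (an `lf_metrics`).
#' @export
subgroup_report <- function(scores, labels, metadata,
                            strata_spec = default_strata(),
                            n_boot = 200L, seed = 1L) {
  missing_keys <- setdiff(unlist(lapply(strata_spec, attr, "keys")),
                          names(metadata))
  if (length(missing_keys))
    stop("unknown metadata key(s): ", paste(missing_keys, collapse = ", "))
  out <- list()
  for (var in names(strata_spec)) {
    g <- strata_spec[[var]](metadata)
    out[[var]] <- list()
    for (lev in unique(g[!is.na(g)])) {
      idx <- which(!is.na(g) & g == lev)
      if (length(unique(labels[idx])) < 2) {
        out[[var]][[lev]] <- list(evaluable = FALSE, n = length(idx))
      } else {
        out[[var]][[lev]] <- list(
          evaluable = TRUE, n = length(idx),
          report = evaluate_scores(scores[idx], labels[idx],
                                   head = paste0(var, "=", lev),
                                   n_boot = n_boot, seed = seed))
      }
    }
  }
  out
}

#' @rdname subgroup_report
#' @export
default_strata <- function() {
  mk <- function(f, keys) structure(f, keys = keys)
  list(
    sex = mk(function(m) as.character(m$sex), "sex"),
    age = mk(function(m) ifelse(m$age <= 70, "<=70", ">70"), "age"),
    nihss = mk(function(m) ifelse(m$nihss <= 4, "<=4", ">4"), "nihss"),
    chads_vasc = mk(function(m) ifelse(m$chads_vasc <= 3, "<=3", ">3"),
                    "chads_vasc"))
}
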