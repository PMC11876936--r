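# Cohort manifests, NIfTI round-tripping and the end-to-end pipeline.

lf_error <- function(msg, class) {
  stop(structure(class = c(class, "lf_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Load and validate a cohort manifest
#'
#' A manifest is a CSV with columns `study_id`, `volume_path`, `mask_path`,
#' `label` and optional metadata columns (`sex`, `age`, `nihss`,
#' `chads_vasc`). Row order is preserved. Violations raise distinct,
#' named conditions: `lf_duplicate_id_error`, `lf_missing_file_error`,
#' `lf_label_domain_error`.
#'
#' @param path manifest CSV path.
#' @return data.frame of class `lf_manifest`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) lf_error(paste("manifest not found:", path),
                                   "lf_missing_file_error")
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("study_id", "volume_path", "mask_path", "label")
  missing <- setdiff(required, names(m))
  if (length(missing))
    lf_error(paste("manifest lacks columns:", paste(missing, collapse = ", ")),
             "lf_schema_error")
  if (anyDuplicated(m$study_id))
    lf_error(paste("duplicate study_id:",
                   paste(unique(m$study_id[duplicated(m$study_id)]),
                         collapse = ", ")), "lf_duplicate_id_error")
  gone <- c(m$volume_path[!file.exists(m$volume_path)],
            m$mask_path[!file.exists(m$mask_path)])
  if (length(gone))
    lf_error(paste("missing file(s):", paste(gone, collapse = ", ")),
             "lf_missing_file_error")
  if (!all(m$label %in% c(0L, 1L)))
    lf_error(paste("labels must be 0 or 1; saw:",
                   paste(unique(m$label[!m$label %in% c(0L, 1L)]),
                         collapse = ", ")), "lf_label_domain_error")
  class(m) <- c("lf_manifest", "data.frame")
  m
}

#' Read the studies listed in a manifest
#'
#' Volumes and masks are read with RNifti; image metadata (affine,
#' orientation) is passed through untouched — no reorientation is
#' performed.
#'
#' @param manifest an `lf_manifest` (or path to one).
#' @return list of `lf_study`.
#' @export
load_cohort <- function(manifest) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    vol <- as.array(RNifti::readNifti(r$volume_path))
    mask <- as.array(RNifti::readNifti(r$mask_path))
    meta <- as.list(r[setdiff(names(r), c("study_id", "volume_path",
                                          "mask_path", "label"))])
    structure(list(volume = vol, mask = array(as.integer(mask != 0),
                                              dim(mask)),
                   label = as.integer(r$label), study_id = r$study_id,
                   metadata = meta, lesions = NULL),
              class = "lf_study")
  })
}

cohort_metadata <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s)
    data.frame(study_id = s$study_id,
               sex = s$metadata$sex %||% NA,
               age = s$metadata$age %||% NA,
               nihss = s$metadata$nihss %||% NA,
               chads_vasc = s$metadata$chads_vasc %||% NA,
               stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline on a cohort
#'
#' preprocess -> radiomics -> k-fold two-stage training -> cross-fold
#' ensemble prediction -> evaluation -> interpretability, writing all
#' artifacts under `outdir`: `fold_plan.json`, `features.csv`, per-fold
#' checkpoints (`fold<k>.rds`) and loss curves (`loss_fold<k>.csv`),
#' `scores.csv`, `metrics.json`, `fsr.csv`, a sample saliency NIfTI and a
#' provenance log (config copy + hash + seeds). Deterministic: re-running
#' with the same cohort, config and seeds reproduces the metrics JSON
#' byte-identically.
#'
#' @param cohort list of `lf_study` (or a manifest path).
#' @param config an [lf_config()].
#' @param outdir output directory.
#' @return (invisibly) a list with `states`, `plan`, `scores` (out-of-fold
#'   ensemble-style per-study scores), `reports`, `fsr`.
#' @export
run_pipeline <- function(cohort, config, outdir) {
  if (is.character(cohort)) cohort <- load_cohort(cohort)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  ids <- vapply(cohort, function(s) s$study_id, character(1))
  labels <- vapply(cohort, function(s) s$label, integer(1))
  features <- stage("radiomics", extract_cohort_features(
    cohort, n_levels = config$n_levels))
  utils::write.csv(data.frame(study_id = ids, features,
                              check.names = FALSE),
                   file.path(outdir, "features.csv"), row.names = FALSE)
  plan <- assign_folds(ids, k = config$k_folds,
                       seed = derive_seed(config$seed, 17L))
  jsonlite::write_json(list(assignment = as.list(plan$assignment),
                            k = plan$k, seed = plan$seed),
                       file.path(outdir, "fold_plan.json"),
                       auto_unbox = TRUE)
  states <- vector("list", config$k_folds)
  for (f in seq_len(config$k_folds) - 1L) {
    states[[f + 1]] <- stage(sprintf("train fold %d", f),
                             train_fold(cohort, plan, f, config,
                                        features = features))
    saveRDS(states[[f + 1]], file.path(outdir, sprintf("fold%d.rds", f)))
    tr <- states[[f + 1]]$val_trace
    utils::write.csv(data.frame(
      epoch = seq_len(length(tr$stage1) + length(tr$stage2)) - 1L,
      stage = rep(1:2, c(length(tr$stage1), length(tr$stage2))),
      val_loss = c(tr$stage1, tr$stage2)),
      file.path(outdir, sprintf("loss_fold%d.csv", f)), row.names = FALSE)
  }
  # out-of-fold scores: each study scored by the model that held it out
  scores <- stage("predict", {
    rows <- lapply(seq_len(config$k_folds) - 1L, function(f) {
      st <- states[[f + 1]]
      idx <- which(plan$assignment[ids] == f)
      predict_fold(st, cohort[idx], features = features)
    })
    do.call(rbind, rows)
  })
  scores <- scores[match(ids, scores$study_id), ]
  utils::write.csv(scores, file.path(outdir, "scores.csv"),
                   row.names = FALSE)
  reports <- stage("evaluate", {
    lapply(c(radiomics = "p_rad", cnn = "p_cnn", combined = "p_com"),
           function(col) evaluate_scores(scores[[col]], scores$label,
                                         head = col,
                                         n_boot = config$n_boot,
                                         seed = derive_seed(config$seed, 23L)))
  })
  report_json <- lapply(reports, function(r)
    list(auc = r$auc, auc_ci = as.numeric(r$auc_ci), cutoff = r$cutoff,
         sensitivity = r$sensitivity, specificity = r$specificity,
         accuracy = r$accuracy, ppv = r$ppv, npv = r$npv,
         n_pos = r$n_pos, n_neg = r$n_neg))
  jsonlite::write_json(report_json, file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  interp <- stage("interpret", {
    wrows <- t(vapply(seq_along(cohort), function(i) {
      st <- states[[plan$assignment[ids[i]] + 1]]
      z <- apply_feature_scaler(st$scaler,
                                features[ids[i], , drop = FALSE])[1, ]
      forward_fusion(st$model,
                     preprocess_study(cohort[[i]],
                                      model_shape = config$model_shape),
                     z)$attention_weights
    }, numeric(ncol(features))))
    colnames(wrows) <- colnames(features)
    fsr <- fsr_ranking(wrows, as.integer(scores$p_com >= 0.5))
    utils::write.csv(as.data.frame(fsr), file.path(outdir, "fsr.csv"),
                     row.names = FALSE)
    st1 <- states[[plan$assignment[ids[1]] + 1]]
    z1 <- apply_feature_scaler(st1$scaler,
                               features[ids[1], , drop = FALSE])[1, ]
    sal <- grad_cam(st1$model,
                    preprocess_study(cohort[[1]],
                                     model_shape = config$model_shape),
                    z1, target_class = labels[1])
    write_saliency(sal, file.path(outdir, "saliency_example.nii.gz"))
    fsr
  })
  jsonlite::write_json(
    list(config = unclass(config)[setdiff(names(unclass(config)), "hash")],
         config_hash = config$hash,
         k_folds = config$k_folds,
         n_studies = length(cohort),
         package_version = as.character(utils::packageVersion("lesionfuse"))),
    file.path(outdir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(list(states = states, plan = plan, scores = scores,
                 reports = reports, fsr = interp))
}

#' Load the fold checkpoints of a finished run
#'
#' @param rundir a [run_pipeline()] output directory.
#' @param k expected number of folds.
#' @return list of `lf_train_state`; a missing checkpoint raises an
#'   `lf_ensemble_integrity_error`.
#' @export
load_checkpoints <- function(rundir, k = 5L) {
  paths <- file.path(rundir, sprintf("fold%d.rds", seq_len(k) - 1L))
  gone <- paths[!file.exists(paths)]
  if (length(gone))
    lf_error(paste("ensemble integrity: missing checkpoint(s):",
                   paste(basename(gone), collapse = ", ")),
             "lf_ensemble_integrity_error")
  lapply(paths, readRDS)
}
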