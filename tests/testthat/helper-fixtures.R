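# Shared fixtures built in code. Heavyweight objects are memoised in this
# environment so the suite builds them once.

.lf_test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .lf_test_cache))
    assign(key, force(expr), envir = .lf_test_cache)
  get(key, envir = .lf_test_cache)
}

small_params <- function(noise_sd = 0.05, ...) {
  phantom_params(grid_shape = c(16L, 16L, 16L),
                 lesion_radius_range = c(3, 5),
                 n_lesions_range = c(1L, 1L),
                 noise_sd = noise_sd, ...)
}

small_config <- function(epochs_stage1 = 2L, epochs_stage2 = 4L,
                         lr0 = 1e-3, ...) {
  lf_config(epochs_stage1 = epochs_stage1, epochs_stage2 = epochs_stage2,
            batch_size = 4L, lr0 = lr0, n_boot = 50L,
            model_shape = c(16L, 16L, 16L),
            base_channels = 4L, sem_dim = 16L, ...)
}

# a small trained fold state on 16^3 phantoms, shared by several tests
small_trained_state <- function() {
  memo("small_state", {
    cohort <- generate_cohort(small_params(), n_per_class = 8, seed = 301)
    ids <- vapply(cohort, function(s) s$study_id, character(1))
    plan <- assign_folds(ids, k = 5, seed = 302)
    feats <- extract_cohort_features(cohort)
    cfg <- small_config(epochs_stage1 = 3L, epochs_stage2 = 10L, lr0 = 3e-3)
    list(cohort = cohort, plan = plan, features = feats, config = cfg,
         state = train_fold(cohort, plan, 0L, cfg, features = feats))
  })
}
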