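test_that("AUC matches examples and exhaustive pair counting", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.3, 8), rep(0:1, 4)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               oracle_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  set.seed(120)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    sc <- round(rnorm(n), 1)  # ties likely
    lb <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_auc(sc, lb), oracle_auc(sc, lb), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms and antisymmetric
          under score negation", {
  set.seed(121)
  for (i in 1:20) {
    sc <- rnorm(40)
    lb <- c(0, 1, rbinom(38, 1, 0.4))
    a <- roc_auc(sc, lb)
    expect_equal(roc_auc(exp(2 * sc) + 3, lb), a)
    expect_equal(roc_auc(-sc, lb), 1 - a, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(122)
  sc <- rnorm(60); lb <- c(0, 1, rbinom(58, 1, 0.35))
  expect_equal(roc_auc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))))
})

test_that("bootstrap CI is seeded, bounded and stratified", {
  set.seed(123)
  sc <- c(rnorm(40, 2), rnorm(40))
  lb <- rep(1:0, each = 40)
  ci <- auc_ci(sc, lb, n_boot = 200, seed = 7)
  expect_identical(ci, auc_ci(sc, lb, n_boot = 200, seed = 7))
  expect_true(ci[1] <= ci[2])
  expect_true(ci[2] <= 1)
  expect_gt(ci[1], 0.8)
  expect_identical(attr(ci, "n_degenerate"), 0L)
})

test_that("null-data CIs cover 0.5 in at least 90% of seeded replicates", {
  set.seed(124)
  cover <- vapply(1:100, function(r) {
    sc <- rnorm(200)
    lb <- rep(0:1, 100)
    ci <- auc_ci(sc, lb, n_boot = 200, seed = r)
    ci[1] <= 0.5 && 0.5 <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("the operating point maximizes sensitivity + specificity with the
          documented tie-break", {
  sc <- c(1, 2, 3, 11, 12, 13)
  lb <- c(0, 0, 0, 1, 1, 1)
  cut <- optimal_cutoff(sc, lb)
  cm <- confusion_metrics(sc, lb, cut)
  expect_equal(cm$sensitivity + cm$specificity, 200)
  set.seed(125)
  for (i in 1:30) {
    scr <- round(rnorm(30), 1)
    lbr <- c(0, 1, rbinom(28, 1, 0.5))
    cutr <- optimal_cutoff(scr, lbr)
    cmr <- confusion_metrics(scr, lbr, cutr)
    expect_equal((cmr$sensitivity + cmr$specificity) / 100,
                 oracle_best_sens_spec(scr, lbr), tolerance = 1e-12)
  }
  # two equally good thresholds -> the higher (more specific) one wins
  sc2 <- c(1, 2, 3, 4)
  lb2 <- c(0, 1, 0, 1)
  # thresholds 1.5 and 3.5 both give sens+spec = 1.5
  expect_equal(optimal_cutoff(sc2, lb2), 3.5)
})

test_that("confusion metrics reproduce constructed counts and identities", {
  sc <- c(rep(1, 29), rep(1, 4), rep(0, 40))
  lb <- c(rep(1, 29), rep(0, 4), rep(0, 40))
  cm <- confusion_metrics(sc, lb, 0.5)
  expect_equal(cm$tp, 29); expect_equal(cm$fp, 4); expect_equal(cm$tn, 40)
  expect_equal(cm$sensitivity, 100)
  expect_equal(cm$specificity, 100 * 40 / 44)
  expect_equal(cm$ppv, 100 * 29 / 33)
  # all predicted positive: spec 0, npv undefined
  cm2 <- confusion_metrics(rep(1, 6), c(1, 1, 0, 0, 0, 1), 0.5)
  expect_equal(cm2$specificity, 0)
  expect_true(is.na(cm2$npv))
  set.seed(126)
  for (i in 1:20) {
    scr <- rnorm(25)
    lbr <- c(0, 1, rbinom(23, 1, 0.5))
    cmr <- confusion_metrics(scr, lbr, 0)
    expect_equal(cmr$accuracy,
                 (cmr$sensitivity * cmr$n_pos + cmr$specificity * cmr$n_neg) /
                   (cmr$n_pos + cmr$n_neg))
  }
})

test_that("cross-validation summaries are per-metric mean and sample SD", {
  mk <- function(sens) structure(list(head = "combined", auc = 0.9,
                                      auc_ci = c(0.8, 1), cutoff = 0.5,
                                      sensitivity = sens, specificity = 80,
                                      accuracy = 85, ppv = 70, npv = 90,
                                      n_pos = 10, n_neg = 10),
                                 class = "lf_metrics")
  same <- crossval_summary(list(mk(80), mk(80), mk(80)))
  expect_equal(unname(same["sd", ]), rep(0, 6))
  two <- crossval_summary(list(mk(80), mk(90)))
  expect_equal(unname(two["mean", "sensitivity"]), 85)
  expect_equal(unname(two["sd", "sensitivity"]), sd(c(80, 90)))
  set.seed(127)
  reps <- lapply(runif(5, 50, 100), mk)
  s <- crossval_summary(reps)
  sens <- vapply(reps, `[[`, numeric(1), "sensitivity")
  expect_true(s["mean", "sensitivity"] >= min(sens) &&
                s["mean", "sensitivity"] <= max(sens))
})

test_that("subgroup reports equal filter-then-recompute and flag
          single-class strata", {
  set.seed(128)
  n <- 120
  labels <- rbinom(n, 1, 0.5)
  scores <- labels * 0.5 + runif(n)
  meta <- data.frame(sex = sample(c("male", "female"), n, TRUE),
                     age = sample(40:90, n, TRUE),
                     nihss = sample(0:20, n, TRUE),
                     chads_vasc = sample(0:8, n, TRUE))
  rep <- subgroup_report(scores, labels, meta, n_boot = 50, seed = 3)
  idx <- which(meta$age <= 70)
  expect_equal(rep$age[["<=70"]]$report$auc,
               roc_auc(scores[idx], labels[idx]))
  expect_equal(rep$age[["<=70"]]$n, length(idx))
  # full-cohort stratum equals the unstratified report
  one <- subgroup_report(scores, labels,
                         data.frame(sex = rep("male", n), age = meta$age,
                                    nihss = meta$nihss,
                                    chads_vasc = meta$chads_vasc),
                         n_boot = 50, seed = 3)
  expect_equal(one$sex[["male"]]$report$auc, roc_auc(scores, labels))
  # a single-class stratum is not evaluable
  meta2 <- meta
  meta2$sex <- ifelse(labels == 1 & meta$sex == "female", "male", meta$sex)
  labels2 <- labels
  labels2[meta2$sex == "female"] <- 0
  rep2 <- subgroup_report(scores, labels2, meta2, n_boot = 50, seed = 3)
  expect_false(rep2$sex[["female"]]$evaluable)
  expect_error(subgroup_report(scores, labels, meta[, 1:2, drop = FALSE]),
               "unknown metadata key")
})
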