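test_that("stratified folds satisfy the 6-7 ER / 10-11 NER rule", {
  labels <- setNames(c(rep(1L, 65), rep(0L, 102)), sprintf("P%03d", 1:167))
  for (seed in 1:10) {
    f <- stratified_patient_folds(labels, k = 10, seed = seed)
    expect_setequal(names(f), names(labels))
    expect_true(all(table(f) %in% 16:17))
    er <- table(factor(f[labels == 1], levels = 1:10))
    ner <- table(factor(f[labels == 0], levels = 1:10))
    expect_true(all(er %in% 6:7))
    expect_true(all(ner %in% 10:11))
    # every patient in exactly one fold
    expect_length(f, 167)
  }
  # different seeds shuffle membership
  expect_false(identical(stratified_patient_folds(labels, 10, 1),
                         stratified_patient_folds(labels, 10, 2)))
  expect_identical(stratified_patient_folds(labels, 10, 3),
                   stratified_patient_folds(labels, 10, 3))
  expect_error(stratified_patient_folds(labels[1:20], k = 10),
               "at least k patients")
})

test_that("slice selection follows the central-slice rule", {
  expect_identical(select_slices(c(3, 9, 5), margin = 2), 1:3)
  expect_identical(select_slices(9, margin = 2), 1L)
  # tie on the maximum breaks toward the lower index
  expect_identical(select_slices(c(4, 9, 9, 2), margin = 1), 1:3)
  # clipped to slices that contain tumor
  expect_identical(select_slices(c(0, 0, 5, 3), margin = 2), 3:4)
  expect_identical(select_slices(c(1, 2, 3, 4, 5, 6, 7), margin = 2), 5:7)
  expect_error(select_slices(c(0, 0, 0)), "no slice contains tumor")
})

test_that("AUC equals the pairwise oracle, ties included", {
  expect_identical(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_identical(auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               auc_oracle(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both classes")
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_identical(auc(scores, labels), auc_oracle(scores, labels))
  }
})

test_that("AUC agrees with the ROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (i in 1:20) {
    labels <- c(0, 1, rbinom(30, 1, 0.4))
    scores <- round(runif(32), 2)
    ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                direction = "<")))
    expect_equal(auc(scores, labels), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("cross-validation keeps patients out of their own training folds", {
  coh <- tiny_cohort()
  rep <- cross_validate(coh, k = 3, seed = 4, variant = "fusion",
                        loss_mode = "joint", epochs = 1)
  expect_s3_class(rep, "dpa_cv_report")
  expect_identical(nrow(rep$per_fold), 3L)
  # structural leakage check: fold map partitions the patients
  expect_length(rep$folds, length(coh))
  expect_true(all(table(rep$folds) >= 1))
  # aggregation is the plain arithmetic mean
  expect_equal(rep$mean_auc, mean(rep$per_fold$auc), tolerance = 1e-12)
  expect_equal(rep$mean_accuracy, mean(rep$per_fold$accuracy), tolerance = 1e-12)
  expect_equal(rep$sd_auc, sd(rep$per_fold$auc), tolerance = 1e-12)
  expect_true(all(rep$per_fold$accuracy >= 0 & rep$per_fold$accuracy <= 1))
  expect_true(all(rep$per_fold$auc >= 0 & rep$per_fold$auc <= 1))
})

test_that("cross-validation runs are replayable and level-switchable", {
  coh <- tiny_cohort()
  r1 <- cross_validate(coh, k = 3, seed = 11, variant = "clinical", epochs = 2)
  r2 <- cross_validate(coh, k = 3, seed = 11, variant = "clinical", epochs = 2)
  expect_identical(r1$per_fold, r2$per_fold)
  rp <- cross_validate(coh, k = 3, seed = 11, variant = "clinical", epochs = 2,
                       level = "patient")
  expect_true(all(rp$per_fold$n_test < r1$per_fold$n_test))
  dir <- withr::local_tempdir()
  write_cv_report(r1, file.path(dir, "cv.json"), file.path(dir, "cv.csv"))
  parsed <- jsonlite::read_json(file.path(dir, "cv.json"))
  expect_equal(parsed$mean_auc, r1$mean_auc, tolerance = 1e-9)
  expect_identical(nrow(read.csv(file.path(dir, "cv.csv"))), 3L)
})

test_that("slice datasets repeat the patient clinical vector across slices", {
  coh <- tiny_cohort()
  ids <- vapply(coh, `[[`, character(1), "patient_id")[1:5]
  ds <- build_slice_dataset(coh, ids, margin = 1)
  expect_identical(dim(ds$phases$NC)[1:2], c(32L, 32L))
  expect_identical(length(ds$labels), dim(ds$phases$ART)[3])
  for (pid in ids) {
    rows <- which(ds$patient == pid)
    expect_true(length(rows) >= 1 && length(rows) <= 3)
    expect_identical(unique(ds$labels[rows]),
                     coh[[which(ids == pid)]]$label)
    expect_true(all(apply(ds$clinical[rows, , drop = FALSE], 2,
                          function(col) length(unique(col)) == 1)))
  }
})
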