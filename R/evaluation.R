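# Patient-stratified cross-validation, slice selection and metrics.

#' Stratified patient-level fold assignment
#'
#' Patients are shuffled within each outcome class (seeded) and dealt into
#' k folds so fold sizes differ by at most one within each class; the
#' larger class's odd patients go to the highest-numbered folds and the
#' smaller class's to the lowest, keeping fold totals balanced. With 65 ER
#' and 102 NER patients and k = 10 every fold holds 6-7 ER and 10-11 NER
#' patients (16-17 in total). Splitting is by patient, never by slice.
#'
#' @param labels Named integer vector (patient id -> 0/1 label).
#' @param k Number of folds.
#' @param seed Integer seed for the within-class shuffles.
#' @return Named integer vector (patient id -> fold index in 1..k).
#' @export
stratified_patient_folds <- function(labels, k = 10L, seed = 1L) {
  stopifnot(!is.null(names(labels)), all(labels %in% c(0L, 1L)), k >= 2)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 < k || n0 < k) {
    stop("each class needs at least k patients (have ", n1, " ER, ", n0, " NER)")
  }
  fold_sizes <- function(n, extras_low) {
    base <- n %/% k; r <- n %% k
    sizes <- rep(base, k)
    if (r > 0) {
      idx <- if (extras_low) seq_len(r) else rev(seq_len(k))[seq_len(r)]
      sizes[idx] <- sizes[idx] + 1L
    }
    sizes
  }
  out <- integer(length(labels))
  names(out) <- names(labels)
  with_seed(seed, {
    for (cls in c(1L, 0L)) {
      ids <- names(labels)[labels == cls]
      ids <- sample(ids)
      sizes <- fold_sizes(length(ids), extras_low = cls == 1L)
      out[ids] <- rep(seq_len(k), times = sizes)
    }
  })
  out
}

#' Select the central slice and its neighbours
#'
#' The central slice is the one with the largest tumor cross-section (ties
#' broken toward the lower index); the selection is the central index plus
#' `margin` slices on each side, clipped to slices that contain tumor.
#'
#' @param areas Per-slice tumor areas for one patient.
#' @param margin Slices to keep on each side of the central one (default 2).
#' @return Integer vector of selected slice indices.
#' @export
select_slices <- function(areas, margin = 2L) {
  stopifnot(length(areas) >= 1, margin >= 0)
  if (all(areas <= 0)) stop("no slice contains tumor (all areas are zero)")
  central <- which.max(areas)
  idx <- max(1L, central - margin):min(length(areas), central + margin)
  idx[areas[idx] > 0]
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the normalized Wilcoxon statistic:
#' the fraction of (ER, NER) pairs in which the ER case has the higher
#' score, counting ties as one half.
#'
#' @param scores Numeric per-sample scores (higher = more ER-like).
#' @param labels 0/1 labels (1 = ER).
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC requires both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Dichotomized records and encoded 9-element vectors for a whole cohort.
cohort_clinical_vectors <- function(cohort) {
  raw <- do.call(rbind, lapply(cohort, `[[`, "clinical"))
  dich <- dichotomize_records(raw)
  encode_clinical_vectors(dich)
}

#' Assemble the slice-level dataset for a set of patients
#'
#' Applies the central-slice selection rule per patient and stacks the
#' selected slices of all three phases, the per-patient encoded clinical
#' vector (repeated across that patient's slices) and the labels.
#'
#' @param cohort A `dpa_cohort` with images.
#' @param patient_ids Patient ids to include.
#' @param margin Slice-selection margin (see [select_slices()]).
#' @param clinical_vectors Optional precomputed matrix from the cohort's
#'   clinical records (rows named by patient id).
#' @param labels Optional named label vector overriding the cohort labels
#'   (used by the label-shuffle control).
#' @return Dataset list (`phases`, `clinical`, `labels`, `patient`) for
#'   [train_dpa()].
#' @export
build_slice_dataset <- function(cohort, patient_ids, margin = 2L,
                                clinical_vectors = NULL, labels = NULL) {
  if (is.null(clinical_vectors)) clinical_vectors <- cohort_clinical_vectors(cohort)
  byid <- stats::setNames(cohort, vapply(cohort, `[[`, character(1), "patient_id"))
  sel <- lapply(patient_ids, function(pid) select_slices(byid[[pid]]$areas, margin))
  total <- sum(lengths(sel))
  d <- dim(byid[[patient_ids[1]]]$images$NC)[1:2]
  phases <- list(NC = array(0, c(d, total)), ART = array(0, c(d, total)),
                 PV = array(0, c(d, total)))
  clin <- matrix(0L, total, ncol(clinical_vectors))
  labs <- integer(total)
  pat <- character(total)
  at <- 0L
  for (j in seq_along(patient_ids)) {
    pid <- patient_ids[j]
    p <- byid[[pid]]
    idx <- at + seq_along(sel[[j]])
    for (ph in c("NC", "ART", "PV")) {
      phases[[ph]][, , idx] <- p$images[[ph]][, , sel[[j]], drop = FALSE]
    }
    clin[idx, ] <- matrix(clinical_vectors[pid, ], length(idx),
                          ncol(clinical_vectors), byrow = TRUE)
    labs[idx] <- if (is.null(labels)) p$label else labels[[pid]]
    pat[idx] <- pid
    at <- at + length(sel[[j]])
  }
  list(phases = phases, clinical = clin, labels = labs, patient = pat)
}

#' Patient-stratified k-fold cross-validation of a DPA model variant
#'
#' For each fold a fresh model is trained on the slices of the other k-1
#' folds' patients and evaluated on the held-out fold's slices. Metrics are
#' slice-level by default (a patient-level option averages each patient's
#' slice probabilities first); the report carries per-fold accuracy and
#' AUC and their mean and sample (n-1) standard deviation, plus every seed
#' used, so a run can be replayed exactly.
#'
#' @param cohort A `dpa_cohort` with images.
#' @param k Number of folds (default 10).
#' @param seed Master seed: drives fold assignment and per-fold model
#'   initialization and shuffling.
#' @param variant `"fusion"` (image + clinical), `"image"` or `"clinical"`.
#' @param loss_mode `"joint"` or `"combined"`.
#' @param depth Backbone depth (default `"small"`).
#' @param epochs,batch_size,lr Training parameters (defaults 50 / 8 / 1e-4).
#' @param margin Slice-selection margin.
#' @param level `"slice"` or `"patient"` metric level.
#' @param shuffle_labels Permute patient labels (seeded) before splitting
#'   and training - a null control whose AUC should hover near 0.5.
#' @param verbose Print per-fold progress.
#' @return A `dpa_cv_report`.
#' @export
cross_validate <- function(cohort, k = 10L, seed = 1L,
                           variant = c("fusion", "image", "clinical"),
                           loss_mode = c("joint", "combined"),
                           depth = "small", epochs = 50L, batch_size = 8L,
                           lr = 1e-4, margin = 2L,
                           level = c("slice", "patient"),
                           shuffle_labels = FALSE, verbose = FALSE) {
  variant <- match.arg(variant)
  loss_mode <- match.arg(loss_mode)
  level <- match.arg(level)
  stopifnot(inherits(cohort, "dpa_cohort"))
  ids <- vapply(cohort, `[[`, character(1), "patient_id")
  labels <- stats::setNames(vapply(cohort, `[[`, integer(1), "label"), ids)
  if (shuffle_labels) {
    labels <- with_seed(seed + 77L, stats::setNames(sample(as.integer(labels)), ids))
  }
  folds <- stratified_patient_folds(labels, k, seed)
  use_image <- variant != "clinical"
  use_clinical <- variant != "image"
  if (variant != "fusion") loss_mode <- "combined"
  cv <- cohort_clinical_vectors(cohort)
  d <- dim(cohort[[1]]$images$NC)[1:2]
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    fold_seed <- seed + 1000L * f
    test_ids <- ids[folds[ids] == f]
    train_ids <- ids[folds[ids] != f]
    tr <- build_slice_dataset(cohort, train_ids, margin, cv, labels)
    te <- build_slice_dataset(cohort, test_ids, margin, cv, labels)
    if (!use_image) { tr$phases <- NULL; te$phases <- NULL }
    if (!use_clinical) { tr$clinical <- NULL; te$clinical <- NULL }
    model <- dpa_model(depth = depth, input_size = d, loss_mode = loss_mode,
                       use_image = use_image, use_clinical = use_clinical,
                       seed = fold_seed)
    fit <- train_dpa(model, tr,
                     train_config(batch_size = batch_size, epochs = epochs,
                                  lr = lr, seed = fold_seed + 1L))
    scores <- predict_dpa(fit$model, te$phases, te$clinical)
    truth <- te$labels
    if (level == "patient") {
      scores <- tapply(scores, te$patient, mean)
      truth <- tapply(truth, te$patient, function(x) x[1])
      scores <- as.numeric(scores); truth <- as.numeric(truth)
    }
    rows[[f]] <- data.frame(
      fold = f, n_test = length(truth),
      accuracy = mean((scores >= 0.5) == (truth == 1)),
      auc = auc(scores, truth), seed = fold_seed)
    if (isTRUE(verbose)) {
      message(sprintf("fold %d/%d: acc %.3f auc %.3f", f, k,
                      rows[[f]]$accuracy, rows[[f]]$auc))
    }
  }
  per_fold <- do.call(rbind, rows)
  structure(list(
    per_fold = per_fold,
    mean_accuracy = mean(per_fold$accuracy),
    sd_accuracy = stats::sd(per_fold$accuracy),
    mean_auc = mean(per_fold$auc),
    sd_auc = stats::sd(per_fold$auc),
    config = list(k = k, seed = seed, variant = variant,
                  loss_mode = loss_mode, depth = depth, epochs = epochs,
                  batch_size = batch_size, lr = lr, margin = margin,
                  level = level, shuffle_labels = shuffle_labels),
    folds = folds), class = "dpa_cv_report")
}

#' @export
print.dpa_cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s, %s loss, %s-level): accuracy %.1f%% +/- %.1f, AUC %.3f +/- %.2f\n",
              x$config$k, x$config$variant, x$config$loss_mode,
              x$config$level, 100 * x$mean_accuracy, 100 * x$sd_accuracy,
              x$mean_auc, x$sd_auc))
  invisible(x)
}

#' Write a cross-validation report
#'
#' The full report (config, seeds, fold assignment, per-fold and aggregate
#' metrics) as JSON, and the per-fold rows as CSV.
#'
#' @param report A `dpa_cv_report`.
#' @param json_path,csv_path Output paths (either may be NULL).
#' @return Invisibly, the report.
#' @export
write_cv_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "dpa_cv_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      config = report$config,
      folds = as.list(report$folds),
      per_fold = report$per_fold,
      mean_accuracy = report$mean_accuracy, sd_accuracy = report$sd_accuracy,
      mean_auc = report$mean_auc, sd_auc = report$sd_auc),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) utils::write.csv(report$per_fold, csv_path, row.names = FALSE)
  invisible(report)
}
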