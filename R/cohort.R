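# Seeded synthetic study generator.
#
# Emulates the statistical structure of the 167-patient resected-HCC
# cohort: ER prevalence 38.9%, 3-7 tumor slices per patient, three
# co-registered phase images per slice, and clinical categories drawn from
# the reference cohort's class-conditional frequencies. Images are
# background fields with an elliptical lesion; the arterial phase carries
# class-dependent rim and interior enhancement, the portal-vein phase
# washout, and ER lesions get boundary irregularity and heavier speckle.
# No radiological realism is attempted - only the class-conditional
# statistical structure a classifier can consume.

#' Specification of a synthetic cohort
#'
#' Defaults are the study conditions this package emulates: 167 patients at
#' 38.9% ER prevalence, 3-7 slices per patient, and clinical
#' class-conditional frequencies equal to the reference cohort's observed
#' proportions (e.g. P(tumor size >= 50 mm | ER) = 37/65).
#'
#' @param n_patients Number of patients.
#' @param er_prevalence Probability of the ER label.
#' @param slices_range Integer range (min, max) of slices per patient.
#' @param image_size Image (H, W) in pixels.
#' @param phase_effect Named list (`NC`, `ART`, `PV`) of length-2 vectors
#'   (NER, ER): mean lesion intensity offset relative to background, per
#'   class. Per-patient offsets are normal around these with sd
#'   `effect_sd`.
#' @param rim_effect Length-2 vector (NER, ER): additional arterial-phase
#'   rim enhancement.
#' @param effect_sd Between-patient sd of the lesion offsets.
#' @param texture_noise Length-2 vector (NER, ER): within-lesion speckle sd.
#' @param irregularity Length-2 vector (NER, ER): lesion boundary
#'   irregularity amplitude (fraction of radius).
#' @param clinical_freqs Per-variable class-conditional category
#'   probability matrices (rows = categories, columns = NER, ER); defaults
#'   derived from [hcc_reference_counts()].
#' @param seed Integer master seed; the whole cohort is a deterministic
#'   function of the spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 167L, er_prevalence = 0.389,
                        slices_range = c(3L, 7L), image_size = c(64L, 64L),
                        phase_effect = list(NC = c(-0.05, -0.05),
                                            ART = c(0.15, 0.20),
                                            PV = c(-0.05, -0.09)),
                        rim_effect = c(0.10, 0.14),
                        effect_sd = 0.06,
                        texture_noise = c(0.03, 0.05),
                        irregularity = c(0.05, 0.10),
                        clinical_freqs = NULL,
                        seed = 1L) {
  stopifnot(n_patients >= 2, er_prevalence > 0, er_prevalence < 1,
            slices_range[1] >= 1, slices_range[2] >= slices_range[1],
            all(image_size >= 16))
  if (is.null(clinical_freqs)) {
    clinical_freqs <- lapply(hcc_reference_counts(), function(tb) {
      sweep(tb$counts, 2, colSums(tb$counts), "/")
    })
  }
  for (f in clinical_freqs) {
    stopifnot(all(f >= 0), all(f <= 1), all(abs(colSums(f) - 1) < 1e-8))
  }
  structure(list(n_patients = as.integer(n_patients),
                 er_prevalence = er_prevalence,
                 slices_range = as.integer(slices_range),
                 image_size = as.integer(image_size),
                 phase_effect = phase_effect, rim_effect = rim_effect,
                 effect_sd = effect_sd, texture_noise = texture_noise,
                 irregularity = irregularity,
                 clinical_freqs = clinical_freqs,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Continuous raw value consistent with a dichotomized category, so that
# re-dichotomizing the exported CSV recovers the drawn category exactly.
raw_value_ranges <- list(
  age = list(c(30, 59.9), c(60, 88)),
  tumor_size_mm = list(c(12, 49.9), c(50, 140)),
  nlr = list(c(0.8, 2.79), c(2.8, 8)),
  alt = list(c(10, 39.9), c(40, 200)),
  ast = list(c(10, 49.9), c(50, 180)),
  akp = list(c(40, 124.9), c(125, 300)),
  ggt = list(c(10, 44.9), c(45, 250)),
  alb = list(c(30, 39.9), c(40, 55)),
  tb = list(c(5, 20.4), c(20.5, 60)),
  afp = list(c(1, 8.9), c(9, 3000))
)

draw_clinical_record <- function(label, freqs, defs) {
  rec <- list()
  for (nm in names(defs)) {
    d <- defs[[nm]]
    p <- freqs[[nm]][, label + 1L]
    cat <- sample.int(length(p), 1L, prob = p) - 1L
    if (d$kind == "binary-cutoff") {
      rg <- raw_value_ranges[[nm]][[cat + 1L]]
      rec[[nm]] <- round(stats::runif(1, rg[1], rg[2]), 2)
    } else {
      rec[[nm]] <- d$categories[cat + 1L]
    }
  }
  rec
}

# Boundary irregularity profile: a low-order random Fourier perturbation of
# the lesion radius as a function of polar angle.
irregularity_profile <- function(amp) {
  ks <- 2:5
  a <- stats::rnorm(length(ks))
  ph <- stats::runif(length(ks), 0, 2 * pi)
  a <- a / max(1, sqrt(sum(a^2)))
  function(theta) {
    s <- 0
    for (i in seq_along(ks)) s <- s + a[i] * sin(ks[i] * theta + ph[i])
    1 + amp * s
  }
}

#' Generate the three-phase slice stack for one synthetic patient
#'
#' Builds a background intensity field with an elliptical lesion whose
#' cross-section is maximal at the central slice, then applies the
#' class-dependent phase effects: arterial rim/interior enhancement,
#' portal-vein washout, and (for ER) boundary irregularity and heavier
#' speckle. All pixel values are quantized to the 16-bit grid in [0, 1].
#'
#' @param label 0 (NER) or 1 (ER).
#' @param spec A [cohort_spec()].
#' @param seed Geometry seed for this patient.
#' @param size_mm Optional tumor size in mm used to scale the lesion radius.
#' @return List with `images` (named list NC/ART/PV of (H, W, S) arrays),
#'   `areas` (per-slice lesion pixel counts) and `lesion_means` (S x 3
#'   matrix of mean within-lesion intensity per phase).
#' @export
generate_phase_images <- function(label, spec, seed, size_mm = NULL) {
  stopifnot(label %in% c(0, 1))
  with_seed(seed, {
    H <- spec$image_size[1]; W <- spec$image_size[2]
    S <- sample(seq(spec$slices_range[1], spec$slices_range[2]), 1L)
    cls <- label + 1L
    if (is.null(size_mm)) size_mm <- stats::runif(1, 12, 140)
    r0 <- (0.10 + 0.20 * (min(max(size_mm, 12), 140) - 12) / 128) * min(H, W)
    if (r0 >= min(H, W) / 2) stop("lesion larger than image")
    ecc <- stats::runif(1, 0.65, 1)
    ang <- stats::runif(1, 0, pi)
    cx <- W / 2 + stats::runif(1, -0.05, 0.05) * W
    cy <- H / 2 + stats::runif(1, -0.05, 0.05) * H
    irr <- irregularity_profile(spec$irregularity[cls])
    base <- stats::runif(1, 0.30, 0.40)
    gx <- stats::runif(1, -0.06, 0.06); gy <- stats::runif(1, -0.06, 0.06)
    off <- list()
    for (ph in c("NC", "ART", "PV")) {
      off[[ph]] <- stats::rnorm(1, spec$phase_effect[[ph]][cls], spec$effect_sd)
    }
    rim_amp <- max(0, stats::rnorm(1, spec$rim_effect[cls], spec$effect_sd))
    xg <- matrix(rep(seq_len(W), each = H), H, W)
    yg <- matrix(rep(seq_len(H), W), H, W)
    u <- (xg - cx) * cos(ang) + (yg - cy) * sin(ang)
    v <- -(xg - cx) * sin(ang) + (yg - cy) * cos(ang)
    theta <- atan2(v, u)
    bshape <- irr(theta)
    prof <- sqrt(pmax(0, 1 - ((seq_len(S) - (S + 1) / 2) / (S / 2 + 0.5))^2))
    images <- list(NC = array(0, c(H, W, S)), ART = array(0, c(H, W, S)),
                   PV = array(0, c(H, W, S)))
    areas <- integer(S)
    lesion_means <- matrix(NA_real_, S, 3,
                           dimnames = list(NULL, c("NC", "ART", "PV")))
    for (s in seq_len(S)) {
      rs <- r0 * prof[s]
      rad <- sqrt((u / rs)^2 + (v / (rs * ecc))^2)
      mask <- rad <= bshape
      rim <- rad > 0.7 * bshape & mask
      areas[s] <- sum(mask)
      bg <- base + gx * (xg / W - 0.5) + gy * (yg / H - 0.5)
      for (ph in c("NC", "ART", "PV")) {
        img <- bg + matrix(stats::rnorm(H * W, sd = 0.02), H, W)
        if (any(mask)) {
          img[mask] <- img[mask] + off[[ph]] +
            stats::rnorm(sum(mask), sd = spec$texture_noise[cls])
          if (ph == "ART" && any(rim)) img[rim] <- img[rim] + rim_amp
        }
        img <- round(pmin(pmax(img, 0), 1) * 65535) / 65535
        images[[ph]][, , s] <- img
        lesion_means[s, ph] <- if (any(mask)) mean(img[mask]) else NA_real_
      }
    }
    list(images = images, areas = areas, lesion_means = lesion_means)
  })
}

#' Generate a synthetic cohort
#'
#' Draws labels at the specified ER prevalence, clinical records from the
#' class-conditional category frequencies, and per-patient three-phase
#' slice stacks. Fully deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param images Set FALSE to skip image synthesis (labels and clinical
#'   records only), e.g. for large statistical checks.
#' @return A `dpa_cohort`: list of patients, each with `patient_id`,
#'   `label`, `clinical` (raw one-row data frame), `areas`, `images` and
#'   `lesion_means`.
#' @export
generate_cohort <- function(spec, images = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  defs <- clinical_variables()
  cohort <- with_seed(spec$seed, {
    labels <- stats::rbinom(spec$n_patients, 1L, spec$er_prevalence)
    geo_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_patients)
    lapply(seq_len(spec$n_patients), function(i) {
      rec <- draw_clinical_record(labels[i], spec$clinical_freqs, defs)
      p <- list(patient_id = sprintf("P%04d", i), label = labels[i],
                clinical = data.frame(patient_id = sprintf("P%04d", i),
                                      label = if (labels[i] == 1) "ER" else "NER",
                                      rec, stringsAsFactors = FALSE))
      if (images) {
        im <- generate_phase_images(labels[i], spec, geo_seeds[i],
                                    size_mm = rec$tumor_size_mm)
        p$images <- im$images
        p$areas <- im$areas
        p$lesion_means <- im$lesion_means
      } else {
        p$areas <- rep(1L, spec$slices_range[1])
      }
      p
    })
  })
  structure(cohort, class = "dpa_cohort", spec = spec)
}

#' Cohort summary report
#'
#' Class counts, ER prevalence (as the percentage a study report would
#' print), and slice bookkeeping.
#'
#' @param cohort A `dpa_cohort`, or an integer vector of 0/1 labels.
#' @return List with `n`, `n_er`, `n_ner`, `prevalence_percent`,
#'   `total_slices`.
#' @export
cohort_summary <- function(cohort) {
  labels <- if (inherits(cohort, "dpa_cohort")) {
    vapply(cohort, `[[`, integer(1), "label")
  } else as.integer(cohort)
  slices <- if (inherits(cohort, "dpa_cohort")) {
    sum(vapply(cohort, function(p) length(p$areas), integer(1)))
  } else NA_integer_
  n <- length(labels)
  ner <- sum(labels == 0)
  er <- sum(labels == 1)
  list(n = n, n_er = er, n_ner = ner,
       prevalence_percent = round(100 * er / n, 1),
       total_slices = slices)
}

#' @export
print.dpa_cohort <- function(x, ...) {
  s <- cohort_summary(x)
  cat("Synthetic cohort: ", s$n, " patients (", s$n_er, " ER / ", s$n_ner,
      " NER, ", s$prevalence_percent, "% ER), ", s$total_slices,
      " slices\n", sep = "")
  invisible(x)
}

#' Export a cohort to disk
#'
#' Writes `<dir>/<patient_id>/{NC,ART,PV}/slice_###.tif` (16-bit grayscale
#' TIFF), `clinical.csv` (raw records) and `manifest.csv` (per-slice tumor
#' areas). The tree round-trips losslessly through [load_cohort()].
#'
#' @param cohort A `dpa_cohort` generated with images.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dpa_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  clin <- do.call(rbind, lapply(cohort, `[[`, "clinical"))
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  man <- do.call(rbind, lapply(cohort, function(p) {
    data.frame(patient_id = p$patient_id, slice = seq_along(p$areas),
               tumor_area = p$areas, stringsAsFactors = FALSE)
  }))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  for (p in cohort) {
    if (is.null(p$images)) stop("cohort was generated without images")
    for (ph in c("NC", "ART", "PV")) {
      pdir <- file.path(dir, p$patient_id, ph)
      dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
      for (s in seq_along(p$areas)) {
        tiff::writeTIFF(p$images[[ph]][, , s],
                        file.path(pdir, sprintf("slice_%03d.tif", s)),
                        bits.per.sample = 16L, compression = "LZW")
      }
    }
  }
  invisible(dir)
}

#' Load an exported cohort
#'
#' @param dir Directory written by [export_cohort()].
#' @return A `dpa_cohort` (without the generator-only `lesion_means`).
#' @export
load_cohort <- function(dir) {
  clin <- read_clinical_csv(file.path(dir, "clinical.csv"))
  man <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  cohort <- lapply(seq_len(nrow(clin)), function(i) {
    pid <- clin$patient_id[i]
    areas <- man$tumor_area[man$patient_id == pid]
    images <- list()
    for (ph in c("NC", "ART", "PV")) {
      files <- file.path(dir, pid, ph, sprintf("slice_%03d.tif", seq_along(areas)))
      if (!all(file.exists(files))) stop("missing slice files for patient ", pid)
      sl <- lapply(files, tiff::readTIFF)
      images[[ph]] <- array(unlist(sl), dim = c(dim(sl[[1]])[1:2], length(sl)))
    }
    list(patient_id = pid, label = as.integer(clin$label[i] == "ER"),
         clinical = clin[i, , drop = FALSE], areas = as.integer(areas),
         images = images)
  })
  structure(cohort, class = "dpa_cohort")
}
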