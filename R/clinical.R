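#' Clinical variable definitions for the HCC early-recurrence cohort
#'
#' Returns the dichotomization scheme used for the routine clinical variables
#' of a resected-HCC cohort. Continuous variables are split at a clinical
#' cutoff (value below the cutoff maps to category 0, at or above to 1);
#' categorical variables map to the 0-based index of their ordered levels.
#'
#' The scheme: age (60 years), tumor size (50 mm), neutrophil/lymphocyte
#' ratio (2.8), ALT (40 U/L), AST (50 U/L), AKP (125 U/L), GGT (45 U/L),
#' ALB (40 g/L), total bilirubin (20.5 umol/L), AFP (9 ug/L); and the
#' categorical variables sex (female/male), tumor number (single/multiple),
#' portal vein invasion (no/yes), cirrhosis (no/yes), HBV infection (no/yes),
#' Child-Pugh level (A/B) and BCLC stage (0/A/B/C).
#'
#' @return A named list of variable definitions. Each element is a list with
#'   `name`, `kind` (`"binary-cutoff"` or `"categorical"`), and either
#'   `cutoff` (numeric) or `categories` (ordered character vector).
#' @export
clinical_variables <- function() {
  cutoff <- function(name, cut) list(name = name, kind = "binary-cutoff", cutoff = cut)
  categ  <- function(name, levels) list(name = name, kind = "categorical", categories = levels)
  defs <- list(
    sex                  = categ("sex", c("female", "male")),
    age                  = cutoff("age", 60),
    tumor_size_mm        = cutoff("tumor_size_mm", 50),
    tumor_number         = categ("tumor_number", c("single", "multiple")),
    portal_vein_invasion = categ("portal_vein_invasion", c("no", "yes")),
    cirrhosis            = categ("cirrhosis", c("no", "yes")),
    hbv                  = categ("hbv", c("no", "yes")),
    nlr                  = cutoff("nlr", 2.8),
    alt                  = cutoff("alt", 40),
    ast                  = cutoff("ast", 50),
    akp                  = cutoff("akp", 125),
    ggt                  = cutoff("ggt", 45),
    alb                  = cutoff("alb", 40),
    tb                   = cutoff("tb", 20.5),
    afp                  = cutoff("afp", 9),
    cp_level             = categ("cp_level", c("A", "B")),
    bclc                 = categ("bclc", c("0", "A", "B", "C"))
  )
  for (n in names(defs)) {
    d <- defs[[n]]
    stopifnot(d$kind != "binary-cutoff" || is.numeric(d$cutoff),
              d$kind != "categorical" || length(d$categories) >= 2)
  }
  defs
}

#' Canonical ordering of clinical variables
#'
#' The seven variables that enter the 9-element binary clinical vector come
#' first, in their encoding order (age, tumor size, portal vein invasion,
#' N/L ratio, total bilirubin, AFP, BCLC stage); the remaining variables
#' follow in schema order.
#'
#' @return Character vector of variable names.
#' @export
clinical_variable_order <- function() {
  first <- c("age", "tumor_size_mm", "portal_vein_invasion", "nlr", "tb", "afp", "bclc")
  rest <- setdiff(names(clinical_variables()), first)
  c(first, rest)
}

#' Dichotomize raw clinical records
#'
#' Maps raw clinical values to 0-based category indices: for cutoff
#' variables, `value < cutoff` gives 0 and `value >= cutoff` gives 1; for
#' categorical variables the index of the label within its ordered levels.
#'
#' @param records Data frame with columns `patient_id`, `label` (`"ER"`,
#'   `"NER"`, or 0/1) and one column per defined variable holding raw values.
#' @param defs Variable definitions, as from [clinical_variables()].
#' @return Data frame with `patient_id`, integer `label` (NER = 0, ER = 1)
#'   and one integer category-index column per variable.
#' @export
dichotomize_records <- function(records, defs = clinical_variables()) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  for (col in c("patient_id", "label")) {
    if (!col %in% names(records)) stop("clinical data lacks required column '", col, "'")
  }
  lab <- records$label
  if (is.character(lab) || is.factor(lab)) {
    lab <- as.character(lab)
    bad <- !lab %in% c("ER", "NER")
    if (any(bad)) {
      stop("unknown outcome label '", lab[which(bad)[1]], "' for patient ",
           records$patient_id[which(bad)[1]])
    }
    lab <- as.integer(lab == "ER")
  }
  stopifnot(all(lab %in% c(0L, 1L)))
  out <- data.frame(patient_id = as.character(records$patient_id),
                    label = as.integer(lab), stringsAsFactors = FALSE)
  for (nm in names(defs)) {
    d <- defs[[nm]]
    if (!nm %in% names(records)) stop("variable '", nm, "' missing from clinical data")
    v <- records[[nm]]
    if (anyNA(v)) {
      stop("missing value of '", nm, "' for patient ",
           out$patient_id[which(is.na(v))[1]])
    }
    if (d$kind == "binary-cutoff") {
      if (!is.numeric(v)) stop("variable '", nm, "' must be numeric")
      out[[nm]] <- as.integer(v >= d$cutoff)
    } else {
      v <- as.character(v)
      idx <- match(v, d$categories)
      if (anyNA(idx)) {
        j <- which(is.na(idx))[1]
        stop("unknown category '", v[j], "' of variable '", nm,
             "' for patient ", out$patient_id[j])
      }
      out[[nm]] <- idx - 1L
    }
  }
  out
}

#' Build a category-by-outcome contingency table
#'
#' Tallies a dichotomized cohort into an r x 2 table of counts, with rows the
#' variable's categories and columns the outcome classes (NER, ER).
#'
#' @param dich Dichotomized cohort from [dichotomize_records()].
#' @param variable Name of one defined variable.
#' @param defs Variable definitions.
#' @return A `contingency_table` object: integer matrix of counts with the
#'   variable name attached.
#' @export
contingency_table <- function(dich, variable, defs = clinical_variables()) {
  stopifnot(is.data.frame(dich))
  if (nrow(dich) == 0) stop("empty cohort")
  if (!variable %in% names(dich)) stop("variable '", variable, "' absent from records")
  d <- defs[[variable]]
  if (d$kind == "binary-cutoff") {
    row_labels <- paste0(c("<", ">="), d$cutoff)
    nr <- 2L
  } else {
    row_labels <- d$categories
    nr <- length(d$categories)
  }
  counts <- matrix(0L, nr, 2L, dimnames = list(row_labels, c("NER", "ER")))
  tab <- table(factor(dich[[variable]], levels = 0:(nr - 1L)),
               factor(dich$label, levels = 0:1))
  counts[] <- as.integer(tab)
  structure(list(variable = variable, counts = counts), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Contingency table for", x$variable, "\n")
  print(x$counts)
  invisible(x)
}

#' Pearson chi-square test of independence on an r x 2 table
#'
#' Computes the Pearson statistic sum((O - E)^2 / E) with expected counts
#' from the row/column marginals, no continuity correction, df = r - 1, and
#' the upper-tail p-value. Zero cells are permitted; a zero row or column
#' marginal is an error.
#'
#' @param table A `contingency_table`, or a bare numeric matrix of counts
#'   with at least two rows and two columns.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
pearson_chi_square <- function(table) {
  counts <- if (inherits(table, "contingency_table")) table$counts else as.matrix(table)
  vname <- if (inherits(table, "contingency_table")) table$variable else "table"
  stopifnot(is.numeric(counts), all(counts >= 0))
  if (nrow(counts) < 2) stop("contingency table for '", vname, "' has fewer than 2 rows")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero row or column marginal in contingency table for '", vname, "'")
  }
  expected <- outer(rs, cs) / sum(counts)
  statistic <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df = df, lower.tail = FALSE))
}

#' Chi-square screen of every clinical variable against the outcome
#'
#' @inheritParams contingency_table
#' @param alpha Significance level for selection (default 0.05).
#' @return Data frame with one row per variable (in canonical order):
#'   `variable`, `statistic`, `df`, `p_value`, `selected`.
#' @export
chi_square_screen <- function(dich, defs = clinical_variables(), alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  vars <- intersect(clinical_variable_order(), names(defs))
  rows <- lapply(vars, function(v) {
    res <- pearson_chi_square(contingency_table(dich, v, defs))
    data.frame(variable = v, statistic = res$statistic, df = res$df,
               p_value = res$p_value, selected = res$p_value < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select significant clinical variables
#'
#' Variables with chi-square p-value strictly below `alpha`, returned in the
#' canonical encoding order.
#'
#' @param results Named list of chi-square results (each with a `p_value`)
#'   or a screen data frame from [chi_square_screen()].
#' @param alpha Significance level, in (0, 1).
#' @return Character vector of selected variable names.
#' @export
select_significant_variables <- function(results, alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 1)
  if (is.data.frame(results)) {
    p <- stats::setNames(results$p_value, results$variable)
  } else {
    if (length(results) == 0) stop("empty result set")
    p <- vapply(results, function(r) r$p_value, numeric(1))
  }
  ord <- intersect(clinical_variable_order(), names(p))
  ord[p[ord] < alpha]
}

#' Encode the 9-element binary clinical vector
#'
#' Elements c1..c6 are the binary categories of age, tumor size, portal vein
#' invasion, N/L ratio, total bilirubin and AFP; (c7, c8, c9) encode BCLC
#' stage as (0,0,0) = 0, (0,0,1) = A, (0,1,0) = B, (1,0,0) = C.
#'
#' @param dich Dichotomized records containing the seven encoded variables.
#' @return Integer matrix with one row per patient and columns c1..c9,
#'   rownames the patient ids.
#' @export
encode_clinical_vectors <- function(dich) {
  need <- c("age", "tumor_size_mm", "portal_vein_invasion", "nlr", "tb", "afp", "bclc")
  miss <- setdiff(need, names(dich))
  if (length(miss)) stop("missing selected variable(s): ", paste(miss, collapse = ", "))
  bclc_map <- rbind("0" = c(0L, 0L, 0L), "A" = c(0L, 0L, 1L),
                    "B" = c(0L, 1L, 0L), "C" = c(1L, 0L, 0L))
  stopifnot(all(dich$bclc %in% 0:3))
  v <- cbind(dich$age, dich$tumor_size_mm, dich$portal_vein_invasion,
             dich$nlr, dich$tb, dich$afp, bclc_map[dich$bclc + 1L, , drop = FALSE])
  storage.mode(v) <- "integer"
  dimnames(v) <- list(dich$patient_id, paste0("c", 1:9))
  stopifnot(all(v %in% c(0L, 1L)))
  v
}

#' Decode a 9-element clinical vector back to category indices
#'
#' Inverse of [encode_clinical_vectors()] for a single vector; the BCLC
#' triplet must be one of its four legal codes.
#'
#' @param v Integer vector of length 9 with entries in {0, 1}.
#' @return Named integer vector of category indices for the seven encoded
#'   variables.
#' @export
decode_clinical_vector <- function(v) {
  stopifnot(length(v) == 9, all(v %in% c(0, 1)))
  codes <- list("0" = c(0, 0, 0), "A" = c(0, 0, 1), "B" = c(0, 1, 0), "C" = c(1, 0, 0))
  hit <- which(vapply(codes, function(cd) all(cd == v[7:9]), logical(1)))
  if (length(hit) != 1) stop("illegal BCLC code: (", paste(v[7:9], collapse = ","), ")")
  c(age = as.integer(v[1]), tumor_size_mm = as.integer(v[2]),
    portal_vein_invasion = as.integer(v[3]), nlr = as.integer(v[4]),
    tb = as.integer(v[5]), afp = as.integer(v[6]), bclc = as.integer(hit - 1L))
}

#' Reference contingency counts of the 167-patient resected-HCC cohort
#'
#' Category-by-outcome counts (columns NER then ER) for each clinical
#' variable of the published 167-patient cohort (102 NER, 65 ER). These
#' counts are the statistical fixture for the chi-square screen and supply
#' the class-conditional category frequencies the synthetic cohort
#' generator emulates.
#'
#' @return Named list of `contingency_table` objects in canonical order.
#' @export
hcc_reference_counts <- function() {
  defs <- clinical_variables()
  raw <- list(
    sex                  = rbind(c(17, 10), c(85, 55)),
    age                  = rbind(c(55, 47), c(47, 18)),
    tumor_size_mm        = rbind(c(74, 28), c(28, 37)),
    tumor_number         = rbind(c(97, 58), c(5, 7)),
    portal_vein_invasion = rbind(c(95, 48), c(7, 17)),
    cirrhosis            = rbind(c(31, 21), c(71, 44)),
    hbv                  = rbind(c(25, 8), c(77, 57)),
    nlr                  = rbind(c(71, 35), c(31, 30)),
    alt                  = rbind(c(66, 38), c(36, 27)),
    ast                  = rbind(c(77, 46), c(25, 19)),
    akp                  = rbind(c(85, 46), c(17, 19)),
    ggt                  = rbind(c(46, 20), c(56, 45)),
    alb                  = rbind(c(2, 0), c(100, 65)),
    tb                   = rbind(c(81, 41), c(21, 24)),
    afp                  = rbind(c(39, 11), c(63, 54)),
    cp_level             = rbind(c(89, 51), c(13, 14)),
    bclc                 = rbind(c(17, 5), c(78, 39), c(1, 3), c(6, 18))
  )
  out <- lapply(clinical_variable_order(), function(nm) {
    d <- defs[[nm]]
    row_labels <- if (d$kind == "binary-cutoff") paste0(c("<", ">="), d$cutoff) else d$categories
    counts <- raw[[nm]]
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(row_labels, c("NER", "ER"))
    structure(list(variable = nm, counts = counts), class = "contingency_table")
  })
  stats::setNames(out, clinical_variable_order())
}

#' Read a clinical CSV
#'
#' One row per patient with columns `patient_id`, `label` (ER/NER) and the
#' raw clinical variables. Missing values or missing columns are errors.
#'
#' @param path Path to the CSV file.
#' @param defs Variable definitions.
#' @return Data frame of raw records, validated against the schema.
#' @export
read_clinical_csv <- function(path, defs = clinical_variables()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "label", names(defs))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical CSV lacks column(s): ", paste(miss, collapse = ", "))
  if (anyNA(df[need])) {
    bad <- which(rowSums(is.na(df[need])) > 0)[1]
    stop("missing value(s) in clinical CSV, first at patient ", df$patient_id[bad])
  }
  df
}

#' Write the chi-square screening report
#'
#' @param screen Data frame from [chi_square_screen()].
#' @param path Output CSV path.
#' @export
write_chi_square_report <- function(screen, path) {
  utils::write.csv(screen, path, row.names = FALSE)
  invisible(path)
}
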