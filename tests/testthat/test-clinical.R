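test_that("dichotomization follows the strict-inequality cutoff rule", {
  defs <- clinical_variables()
  rec <- records_from_counts()[1, ]
  rec$age <- 65; rec$bclc <- "B"
  d <- dichotomize_records(rec, defs)
  expect_identical(d$age, 1L)
  rec$age <- 59.999
  expect_identical(dichotomize_records(rec, defs)$age, 0L)
  rec$age <- 60
  expect_identical(dichotomize_records(rec, defs)$age, 1L)
  expect_identical(d$bclc, 2L)

  rec$bclc <- "D"
  expect_error(dichotomize_records(rec, defs), "unknown category 'D'.*bclc")
  rec$bclc <- NULL
  expect_error(dichotomize_records(rec, defs), "missing")
})

test_that("contingency tables equal a brute-force tally", {
  set.seed(11)
  n <- 80
  df <- records_from_counts()[rep(1, n), ]
  df$patient_id <- sprintf("S%03d", 1:n)
  df$label <- sample(c("ER", "NER"), n, replace = TRUE)
  df$bclc <- sample(c("0", "A", "B", "C"), n, replace = TRUE)
  df$age <- sample(c(40, 70), n, replace = TRUE)
  d <- dichotomize_records(df)
  defs <- clinical_variables()
  for (v in c("age", "bclc")) {
    tab <- contingency_table(d, v)
    ncat <- if (defs[[v]]$kind == "categorical") length(defs[[v]]$categories) else 2L
    manual <- t(vapply(seq_len(ncat) - 1L, function(cat) {
      c(sum(d[[v]] == cat & d$label == 0L), sum(d[[v]] == cat & d$label == 1L))
    }, integer(2)))
    expect_equal(unname(tab$counts), unname(manual))
    expect_equal(sum(tab$counts), n)
  }
  expect_error(contingency_table(d[0, ], "age"), "empty")
  expect_error(contingency_table(d, "nosuch"), "absent")
})

test_that("reference cohort records reproduce the published counts", {
  df <- records_from_counts()
  d <- dichotomize_records(df)
  ref <- hcc_reference_counts()
  for (v in names(ref)) {
    expect_identical(contingency_table(d, v)$counts, ref[[v]]$counts)
  }
  expect_identical(unname(ref$age$counts), rbind(c(55L, 47L), c(47L, 18L)))
})

test_that("Pearson chi-square matches independent references", {
  # closed-form cases
  even <- pearson_chi_square(rbind(c(10, 10), c(10, 10)))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  # dual check: explicit O/E oracle and stats::chisq.test without correction
  set.seed(23)
  for (i in 1:1000) {
    r <- sample(2:4, 1)
    counts <- matrix(rpois(2 * r, lambda = 12) + 1, r, 2)
    res <- pearson_chi_square(counts)
    ora <- chisq_oracle(counts)
    expect_lt(abs(res$statistic - ora$statistic), 1e-10)
    expect_lt(abs(res$p_value - ora$p_value), 1e-10)
    ref <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    expect_lt(abs(res$statistic - unname(ref$statistic)), 1e-8)
    expect_lt(abs(res$p_value - ref$p.value), 1e-8)
    expect_identical(res$df, as.integer(r - 1))
  }
})

test_that("chi-square statistic is invariant under row permutation", {
  set.seed(5)
  counts <- matrix(rpois(8, 9) + 1, 4, 2)
  base <- pearson_chi_square(counts)
  for (i in 1:10) {
    perm <- sample(4)
    res <- pearson_chi_square(counts[perm, ])
    expect_equal(res$statistic, base$statistic)
  }
})

test_that("degenerate tables are rejected, zero cells allowed", {
  expect_error(pearson_chi_square(matrix(c(5, 3), 1, 2)), "fewer than 2 rows")
  expect_error(pearson_chi_square(rbind(c(0, 0), c(5, 3))), "zero row")
  expect_error(pearson_chi_square(rbind(c(5, 0), c(3, 0))), "zero row or column")
  # the reference ALB table has a zero cell and must work
  expect_silent(res <- pearson_chi_square(hcc_reference_counts()$alb))
  expect_equal(round(res$p_value, 3), 0.256)
})

test_that("variable selection applies p < alpha in canonical order", {
  screen <- chi_square_screen(dichotomize_records(records_from_counts()))
  sel <- select_significant_variables(screen, alpha = 0.05)
  expect_identical(sel, c("age", "tumor_size_mm", "portal_vein_invasion",
                          "nlr", "tb", "afp", "bclc"))
  expect_identical(select_significant_variables(screen, alpha = 1),
                   clinical_variable_order())
  flat <- lapply(setNames(nm = c("a", "b")), function(x) list(p_value = 0.5))
  expect_length(select_significant_variables(flat, 0.05), 0)
  expect_error(select_significant_variables(list(), 0.05), "empty")
})

test_that("clinical vector encoding matches the element map", {
  df <- records_from_counts()[1:3, ]
  df$patient_id <- c("A", "B", "C")
  # A: everything at/above cutoff, BCLC B
  df$age[1] <- 70; df$tumor_size_mm[1] <- 80; df$portal_vein_invasion[1] <- "yes"
  df$nlr[1] <- 4; df$tb[1] <- 30; df$afp[1] <- 100; df$bclc[1] <- "B"
  # B: everything below, BCLC 0
  df$age[2] <- 40; df$tumor_size_mm[2] <- 20; df$portal_vein_invasion[2] <- "no"
  df$nlr[2] <- 1; df$tb[2] <- 10; df$afp[2] <- 2; df$bclc[2] <- "0"
  # C: BCLC A with arbitrary other values
  df$bclc[3] <- "A"
  v <- encode_clinical_vectors(dichotomize_records(df))
  expect_identical(unname(v["A", ]), c(1L, 1L, 1L, 1L, 1L, 1L, 0L, 1L, 0L))
  expect_identical(unname(v["B", ]), rep(0L, 9L))
  expect_identical(unname(v["C", 7:9]), c(0L, 0L, 1L))
})

test_that("every legal clinical vector decodes uniquely and re-encodes to itself", {
  bclc_codes <- list(c(0, 0, 0), c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
  grid <- expand.grid(rep(list(0:1), 6))
  seen <- character(0)
  for (bi in seq_along(bclc_codes)) {
    for (g in seq_len(nrow(grid))) {
      v <- c(as.integer(grid[g, ]), as.integer(bclc_codes[[bi]]))
      dec <- decode_clinical_vector(v)
      expect_identical(unname(dec["bclc"]), bi - 1L)
      d <- data.frame(patient_id = "x", age = dec["age"],
                      tumor_size_mm = dec["tumor_size_mm"],
                      portal_vein_invasion = dec["portal_vein_invasion"],
                      nlr = dec["nlr"], tb = dec["tb"], afp = dec["afp"],
                      bclc = dec["bclc"])
      expect_identical(unname(encode_clinical_vectors(d)[1, ]), v)
      seen <- c(seen, paste(dec, collapse = ","))
    }
  }
  expect_identical(anyDuplicated(seen), 0L)
  expect_error(decode_clinical_vector(c(rep(0, 6), 1, 1, 0)), "illegal BCLC")
})

test_that("clinical CSV round-trips through the reader with validation", {
  df <- records_from_counts()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  back <- read_clinical_csv(path)
  expect_identical(dichotomize_records(back), dichotomize_records(df))
  df2 <- df; df2$afp[3] <- NA
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df2, path2, row.names = FALSE)
  expect_error(read_clinical_csv(path2), "missing value")
  expect_error(read_clinical_csv({
    p <- withr::local_tempfile(fileext = ".csv")
    write.csv(df[, -3], p, row.names = FALSE); p
  }), "lacks column")
})
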