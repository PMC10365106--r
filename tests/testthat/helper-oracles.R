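# Independent oracles and small fixtures shared across tests.

# Brute-force 2-d convolution on (H, W, N, Cin) arrays, direct quadruple
# loop; the reference the compiled path is checked against.
brute_conv <- function(x, w, b, stride, pad) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  KH <- dim(w)[1]; KW <- dim(w)[2]; Cout <- dim(w)[4]
  OH <- (H + 2 * pad - KH) %/% stride + 1
  OW <- (W + 2 * pad - KW) %/% stride + 1
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, N, Cin))
  xp[pad + (1:H), pad + (1:W), , ] <- x
  y <- array(0, c(OH, OW, N, Cout))
  for (oc in 1:Cout) for (n in 1:N) for (ow in 1:OW) for (oh in 1:OH) {
    acc <- b[oc]
    for (c in 1:Cin) for (kj in 1:KW) for (ki in 1:KH) {
      acc <- acc + xp[(oh - 1) * stride + ki, (ow - 1) * stride + kj, n, c] *
        w[ki, kj, c, oc]
    }
    y[oh, ow, n, oc] <- acc
  }
  y
}

# O(n^2) concordant-pair AUC oracle with explicit tie handling.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Explicit observed/expected chi-square oracle.
chisq_oracle <- function(counts) {
  rs <- rowSums(counts); cs <- colSums(counts); tot <- sum(counts)
  stat <- 0
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    e <- rs[i] * cs[j] / tot
    stat <- stat + (counts[i, j] - e)^2 / e
  }
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}

# Zero out all learnable attention weights (forces every sigmoid to 0.5).
zero_attention <- function(p) {
  for (nm in c("fc1", "fc2", "conv")) {
    p[[nm]]$w[] <- 0
    p[[nm]]$b[] <- 0
  }
  p
}

# Raw clinical records whose category tallies reproduce the reference
# cohort's contingency counts exactly.
records_from_counts <- function(counts_list = hcc_reference_counts()) {
  defs <- clinical_variables()
  n_ner <- sum(counts_list[[1]]$counts[, "NER"])
  n_er <- sum(counts_list[[1]]$counts[, "ER"])
  labels <- c(rep("NER", n_ner), rep("ER", n_er))
  df <- data.frame(patient_id = sprintf("P%03d", seq_along(labels)),
                   label = labels, stringsAsFactors = FALSE)
  for (nm in names(counts_list)) {
    d <- defs[[nm]]
    counts <- counts_list[[nm]]$counts
    vals <- character(0)
    for (cls in c("NER", "ER")) {
      cats <- rep(seq_len(nrow(counts)) - 1L, counts[, cls])
      if (d$kind == "binary-cutoff") {
        v <- ifelse(cats == 0, d$cutoff - 1, d$cutoff + 1)
      } else {
        v <- d$categories[cats + 1L]
      }
      vals <- c(vals, as.character(v))
    }
    df[[nm]] <- if (d$kind == "binary-cutoff") as.numeric(vals) else vals
  }
  df
}

# A small cached cohort for cross-module tests.
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(n_patients = 24, er_prevalence = 0.5,
                          slices_range = c(2L, 4L), image_size = c(32L, 32L),
                          seed = 42)
      cache <<- generate_cohort(spec)
    }
    cache
  }
})
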