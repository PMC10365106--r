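tiny_model <- function(...) {
  dpa_model(depth = "small", input_size = 32, loss_mode = "joint", seed = 3, ...)
}

tiny_inputs <- function(n = 3, seed = 9) {
  with_seed(seed, list(
    phases = lapply(1:3, function(i) array(runif(32 * 32 * n), c(32, 32, n))),
    clin = matrix(rbinom(n * 9, 1, 0.5), n, 9),
    labels = rep_len(c(0, 1), n)))
}

test_that("softmax fusion head reproduces closed forms", {
  m <- tiny_model()
  m$fusion_fc$w[] <- 0
  m$fusion_fc$b <- c(log(3), 0)
  probs <- fusion_forward(m, matrix(0, 2, 30), matrix(0, 2, 30))
  expect_equal(probs, matrix(c(0.75, 0.75, 0.25, 0.25), 2, 2), tolerance = 1e-12)
  m$fusion_fc$b <- c(1.3, 1.3)
  expect_equal(fusion_forward(m, matrix(0, 1, 30), matrix(0, 1, 30)),
               matrix(0.5, 1, 2), tolerance = 1e-12)
  set.seed(4)
  m$fusion_fc$w <- matrix(rnorm(120), 60, 2)
  probs <- fusion_forward(m, matrix(rnorm(150), 5, 30), matrix(rnorm(150), 5, 30))
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-12)
})

test_that("cross-entropy matches its closed forms", {
  expect_equal(cross_entropy(matrix(c(0.5, 0.5), 1), 1), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy(matrix(c(0.5, 0.5), 1), 0), log(2), tolerance = 1e-12)
  expect_lt(cross_entropy(matrix(c(1, 0), 1), 1), 1e-6)
  expect_equal(cross_entropy(matrix(c(0.9, 0.1), 1), 1), -log(0.9), tolerance = 1e-9)
  expect_equal(cross_entropy(matrix(c(0.1, 0.9), 1), 0), -log(0.9), tolerance = 1e-9)
  # batch averaging
  p <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  expect_equal(cross_entropy(p, c(1, 0)), (-log(0.9) + log(2)) / 2, tolerance = 1e-9)
})

test_that("joint loss decomposes with the quarter/quarter/half weights", {
  u <- matrix(0.5, 2, 2)
  jl <- joint_loss(u, u, u, c(0, 1))
  expect_equal(jl$total, log(2), tolerance = 1e-12)
  g <- rbind(c(0.9, 0.1), c(0.9, 0.1))
  jg <- joint_loss(g, g, g, c(1, 1))
  expect_equal(jg$total, -log(0.9), tolerance = 1e-9)
  perfect <- rbind(c(1, 0), c(1, 0))
  jm <- joint_loss(perfect, u, u, c(1, 1))
  expect_equal(jm$total, 0.75 * log(2), tolerance = 1e-6)
  expect_equal(jm$total, jm$L_image / 4 + jm$L_clinical / 4 + jm$L_combine / 2)
})

test_that("clinical pathway is a 9->30 FC with rectifier", {
  m <- tiny_model()
  out <- clinical_pathway_forward(m, rep(0L, 9))
  expect_identical(dim(out$feature), c(1L, 30L))
  # zero vector with zero bias gives a zero feature
  m0 <- m; m0$clin_fc$b[] <- 0
  expect_true(all(clinical_pathway_forward(m0, rep(0L, 9))$feature == 0))
  # hand 9x30 matrix-vector oracle
  v <- rbinom(9, 1, 0.5)
  manual <- pmax(v %*% m$clin_fc$w + m$clin_fc$b, 0)
  expect_equal(clinical_pathway_forward(m, v)$feature, manual, tolerance = 1e-12)
  expect_equal(rowSums(clinical_pathway_forward(m, v)$probs), 1, tolerance = 1e-12)
  expect_error(clinical_pathway_forward(m, rep(0, 8)), "length 9")
})

test_that("image pathway composes backbone, attention, pooling and FC", {
  m <- tiny_model()
  inp <- tiny_inputs(2)
  out <- image_pathway_forward(m, inp$phases)
  expect_identical(dim(out$feature), c(2L, 30L))
  expect_equal(rowSums(out$probs), c(1, 1), tolerance = 1e-12)
  # deterministic in eval mode
  expect_identical(out$feature, image_pathway_forward(m, inp$phases)$feature)
  # compositional oracle through the exported module surface
  maps <- backbone_forward(inp$phases, m$branches)
  att <- lapply(1:3, function(i) intra_phase_attention(maps[[i]], m$intra[[i]]))
  fused <- inter_phase_attention(att, m$inter)
  pooled <- apply(fused, 3:4, mean)
  manual <- pmax(pooled %*% m$image_fc$w + rep(m$image_fc$b, each = 2), 0)
  expect_equal(out$feature, manual, tolerance = 1e-10)
})

test_that("model gradients agree with finite differences", {
  m <- tiny_model()
  inp <- tiny_inputs(3)
  weights <- c(image = 0.25, clinical = 0.25, combine = 0.5)
  fw <- dpanet:::dpa_fwd(m, inp$phases, inp$clin, training = TRUE)
  g <- dpanet:::dpa_bwd(m, fw, inp$labels, weights)
  loss_of <- function(model) {
    f <- dpanet:::dpa_fwd(model, inp$phases, inp$clin, training = TRUE)
    joint_loss(f$image_probs, f$clinical_probs, f$combined_probs, inp$labels)$total
  }
  check <- function(get, set, gv, k = 3) {
    vals <- get(m)
    set.seed(17)
    for (i in sample(length(vals), k)) {
      eps <- 1e-4
      m1 <- set(m, replace(vals, i, vals[i] + eps))
      m2 <- set(m, replace(vals, i, vals[i] - eps))
      num <- (loss_of(m1) - loss_of(m2)) / (2 * eps)
      expect_equal(gv[i], num, tolerance = 1e-4)
    }
  }
  check(function(m) m$fusion_fc$w, function(m, v) { m$fusion_fc$w[] <- v; m },
        g$fusion_fc$w)
  check(function(m) m$clin_fc$w, function(m, v) { m$clin_fc$w[] <- v; m },
        g$clin_fc$w)
  check(function(m) m$branches[[2]]$params$stem$conv$w,
        function(m, v) { m$branches[[2]]$params$stem$conv$w[] <- v; m },
        g$branches[[2]]$stem$conv$w)
  check(function(m) m$intra[[1]]$fc2$w,
        function(m, v) { m$intra[[1]]$fc2$w[] <- v; m },
        g$intra[[1]]$fc2$w)
  check(function(m) m$inter[[3]]$fc1$w,
        function(m, v) { m$inter[[3]]$fc1$w[] <- v; m },
        g$inter[[3]]$fc1$w)
})

test_that("training descends and logs the exact loss decomposition", {
  set.seed(30)
  n <- 16
  labels <- rep(0:1, each = n / 2)
  # separable toy: class-shifted images and class-informative clinical bits
  phases <- lapply(1:3, function(i) {
    a <- array(runif(16 * 16 * n, 0.2, 0.4), c(16, 16, n))
    a[, , labels == 1] <- a[, , labels == 1] + 0.4
    a
  })
  clin <- cbind(matrix(labels, n, 5), matrix(rbinom(n * 4, 1, 0.5), n, 4))
  ds <- list(phases = phases, clinical = clin, labels = labels)
  m <- dpa_model(depth = "small", input_size = 16, loss_mode = "joint", seed = 2)
  one <- train_dpa(m, ds, train_config(epochs = 1, seed = 5))
  expect_identical(nrow(one$history), 1L)
  fit <- train_dpa(m, ds, train_config(epochs = 15, lr = 1e-3, seed = 5))
  h <- fit$history
  expect_lt(h$total[nrow(h)], h$total[1])
  expect_true(all(c("L_image", "L_clinical", "L_combine") %in% names(h)))
  expect_equal(h$total, h$L_image / 4 + h$L_clinical / 4 + h$L_combine / 2,
               tolerance = 1e-12)
  # combined-only mode: objective is the fused cross-entropy alone
  mc <- dpa_model(depth = "small", input_size = 16, loss_mode = "combined", seed = 2)
  fc <- train_dpa(mc, ds, train_config(epochs = 2, seed = 5))
  expect_equal(fc$history$total, fc$history$L_combine, tolerance = 1e-12)
  expect_true(all(is.na(fc$history$L_image)))
  expect_error(train_dpa(mc, ds, train_config(epochs = 1, loss_mode = "joint")),
               "without auxiliary heads")
  expect_error(train_dpa(m, list(labels = integer(0)), train_config(epochs = 1)),
               "empty")
})

test_that("checkpoints round-trip with identical predictions", {
  m <- tiny_model()
  inp <- tiny_inputs(2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_dpa_model(m, path, history = data.frame(epoch = 1, total = 0.5))
  back <- load_dpa_model(path)
  expect_identical(back$history$total, 0.5)
  expect_identical(predict_dpa(back$model, inp$phases, inp$clin),
                   predict_dpa(m, inp$phases, inp$clin))
  saveRDS(list(a = 1), path)
  expect_error(load_dpa_model(path), "not a dpanet checkpoint")
})

test_that("ablation variants drop the corresponding pathway", {
  inp <- tiny_inputs(2)
  mi <- dpa_model(depth = "small", input_size = 32, use_clinical = FALSE,
                  loss_mode = "combined", seed = 1)
  expect_length(predict_dpa(mi, phases = inp$phases), 2)
  expect_null(mi$clin_fc)
  mc <- dpa_model(depth = "small", use_image = FALSE, loss_mode = "combined", seed = 1)
  expect_length(predict_dpa(mc, clinical = inp$clin), 2)
  expect_null(mc$branches)
  expect_error(dpa_model(use_image = FALSE, use_clinical = FALSE))
})
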