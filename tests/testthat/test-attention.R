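rand_map <- function(h, w, n, c, seed) {
  with_seed(seed, array(rnorm(h * w * n * c), c(h, w, n, c)))
}

test_that("zeroed parameters force every attention weight to one half", {
  p <- zero_attention(attention_params(8, r = 4, seed = 1))
  x <- rand_map(6, 6, 2, 8, 3)
  a <- channel_attention_weights(x, p)
  expect_identical(dim(a), c(2L, 8L))
  expect_true(all(a == 0.5))
  s <- spatial_attention_map(x, p)
  expect_identical(dim(s), c(6L, 6L, 2L))
  expect_true(all(s == 0.5))
  # intra-phase module reduces to the identity
  expect_equal(intra_phase_attention(x, p), x)
  # inter-phase module reduces to the plain sum of the three inputs
  xs <- lapply(4:6, function(sd) rand_map(6, 6, 2, 8, sd))
  ps <- lapply(1:3, function(i) zero_attention(attention_params(8, 4, i)))
  expect_equal(inter_phase_attention(xs, ps), xs[[1]] + xs[[2]] + xs[[3]])
})

test_that("attention weights always lie strictly in (0, 1)", {
  p <- attention_params(16, r = 16, seed = 2)
  x <- rand_map(8, 8, 3, 16, 9) * 10
  a <- channel_attention_weights(x, p)
  s <- spatial_attention_map(x, p)
  expect_true(all(a > 0 & a < 1))
  expect_true(all(s > 0 & s < 1))
  expect_identical(dim(intra_phase_attention(x, p)), dim(x))
  # reduction ratio floors at one neuron
  p1 <- attention_params(3, r = 16, seed = 1)
  expect_identical(ncol(p1$fc1$w), 1L)
})

test_that("channel attention matches a pencil-and-paper computation", {
  p <- attention_params(2, r = 1, seed = 1)
  p$fc1$w <- matrix(c(1, -1, 0.5, 0.25), 2, 2)
  p$fc1$b <- c(0.1, -0.2)
  p$fc2$w <- matrix(c(0.3, -0.4, 0.2, 0.6), 2, 2)
  p$fc2$b <- c(0, 0.5)
  x <- array(c(1, 2, 3, 4, 5, 6, 7, 8), c(2, 2, 1, 2))
  s <- c(mean(x[, , 1, 1]), mean(x[, , 1, 2]))          # (2.5, 6.5)
  h <- pmax(0, s %*% p$fc1$w + p$fc1$b)                  # rectified bottleneck
  z <- h %*% p$fc2$w + p$fc2$b
  expect_equal(channel_attention_weights(x, p),
               1 / (1 + exp(-z)), tolerance = 1e-12)
})

test_that("spatial attention matches the brute-force convolution oracle", {
  p <- attention_params(1, r = 1, seed = 4)
  x <- rand_map(8, 8, 1, 1, 11)
  # with one channel, max and mean pooling both equal the input plane
  pooled <- array(c(x, x), c(8, 8, 1, 2))
  z <- brute_conv(pooled, p$conv$w, p$conv$b, 1, 3)
  expect_equal(spatial_attention_map(x, p),
               array(1 / (1 + exp(-z)), c(8, 8, 1)), tolerance = 1e-10)
  # channel-constant input: both pooled planes identical
  xc <- array(rep(rand_map(5, 5, 1, 1, 2), 3), c(5, 5, 1, 3))
  cp <- dpanet:::channel_pool_fwd(xc)$out
  expect_equal(cp[, , , 1], cp[, , , 2])
})

test_that("intra-phase output is the sum of its two branch oracles", {
  p <- attention_params(4, r = 2, seed = 5)
  x <- rand_map(7, 7, 2, 4, 6)
  a <- channel_attention_weights(x, p)
  s <- spatial_attention_map(x, p)
  manual <- x * rep(as.vector(a), each = 49) + x * as.vector(s)
  expect_equal(intra_phase_attention(x, p), manual, tolerance = 1e-12)
  # nonnegative input stays bounded by twice the input
  xp <- abs(x)
  out <- intra_phase_attention(xp, p)
  expect_true(all(out >= 0))
  expect_true(all(out <= 2 * xp + 1e-12))
})

test_that("inter-phase attention averages, fuses and is phase-symmetric", {
  xs <- lapply(1:3, function(i) rand_map(6, 6, 2, 4, 20 + i))
  ps <- lapply(1:3, function(i) attention_params(4, 2, 30 + i))
  out <- inter_phase_attention(xs, ps)
  # shared channel vector is the elementwise mean of the per-phase vectors
  avec <- Reduce(`+`, lapply(1:3, function(i) channel_attention_weights(xs[[i]], ps[[i]]))) / 3
  smap <- Reduce(`+`, lapply(1:3, function(i) spatial_attention_map(xs[[i]], ps[[i]]))) / 3
  manual <- Reduce(`+`, lapply(xs, function(x) {
    x * rep(as.vector(avec), each = 36) + x * as.vector(smap)
  }))
  expect_equal(out, manual, tolerance = 1e-10)
  # permutation of the (map, params) pairs leaves the output unchanged
  for (perm in list(c(2, 3, 1), c(3, 1, 2), c(2, 1, 3))) {
    expect_equal(inter_phase_attention(xs[perm], ps[perm]), out, tolerance = 1e-12)
  }
  # identical maps and identical params: output is 3x the intra output
  x1 <- xs[[1]]
  expect_equal(inter_phase_attention(list(x1, x1, x1), list(ps[[1]], ps[[1]], ps[[1]])),
               3 * intra_phase_attention(x1, ps[[1]]), tolerance = 1e-12)
  expect_error(inter_phase_attention(xs[1:2], ps), "length")
})

test_that("frozen attention application is linear in the feature map", {
  p <- attention_params(4, 2, seed = 8)
  x <- rand_map(5, 5, 1, 4, 40)
  a <- channel_attention_weights(x, p)
  s <- spatial_attention_map(x, p)
  apply_frozen <- function(z) z * rep(as.vector(a), each = 25) + z * as.vector(s)
  expect_equal(apply_frozen(3 * x), 3 * apply_frozen(x), tolerance = 1e-12)
  expect_equal(apply_frozen(x + x), apply_frozen(x) + apply_frozen(x), tolerance = 1e-12)
})
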