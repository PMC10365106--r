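# Neural-network building blocks on (H, W, N, C) activation arrays.
# Convolution and max-pooling call the compiled primitives; batch
# normalization, fully connected layers, activations and the Adam optimizer
# are plain vectorized R. Every layer comes as a fwd/bwd pair so the model
# backward pass is explicit and finite-difference checkable.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so deterministic initialization does not disturb user
#' simulations.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

init_conv <- function(kh, kw, cin, cout) {
  list(w = array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
                 dim = c(kh, kw, cin, cout)),
       b = numeric(cout))
}

init_fc <- function(fin, fout) {
  list(w = matrix(stats::rnorm(fin * fout, sd = sqrt(2 / fin)), fin, fout),
       b = numeric(fout))
}

# Near-zero initialization for classifier heads.
init_head <- function(fin, fout) {
  list(w = matrix(stats::rnorm(fin * fout, sd = 0.01), fin, fout),
       b = numeric(fout))
}

init_bn <- function(c) {
  st <- new.env(parent = emptyenv())
  st$rm <- numeric(c)
  st$rv <- rep(1, c)
  list(gamma = rep(1, c), beta = numeric(c), stats = st)
}

conv_fwd <- function(x, p, stride = 1L, pad = 0L) {
  out <- cpp_conv2d_forward(x, p$w, p$b, as.integer(stride), as.integer(pad))
  list(out = out, cache = list(x = x, stride = stride, pad = pad))
}

conv_bwd <- function(g, p, cache, need_gx = TRUE) {
  r <- cpp_conv2d_backward(cache$x, p$w, g, as.integer(cache$stride),
                           as.integer(cache$pad), need_gx)
  list(gx = r$gx, gp = list(w = r$gw, b = r$gb))
}

maxpool_fwd <- function(x, k = 3L, stride = 2L, pad = 1L) {
  r <- cpp_maxpool_forward(x, as.integer(k), as.integer(stride), as.integer(pad))
  list(out = r$out, cache = list(amax = r$amax, xdim = dim(x)))
}

maxpool_bwd <- function(g, cache) {
  cpp_maxpool_backward(g, cache$amax, as.integer(cache$xdim))
}

# Batch normalization over (H, W, N) per channel. In training mode batch
# statistics are used and the running statistics (kept in the `stats`
# environment so they update in place) move with momentum; in eval mode the
# running statistics are used.
bn_fwd <- function(x, p, training = FALSE, momentum = 0.1, eps = 1e-5) {
  r <- cpp_bn_forward(x, p$gamma, p$beta, p$stats$rm, p$stats$rv,
                      training, momentum, eps)
  if (training) {
    p$stats$rm <- r$rm
    p$stats$rv <- r$rv
  }
  list(out = r$out, cache = list(xhat = r$xhat, invstd = r$invstd,
                                 d = dim(x), training = training))
}

bn_bwd <- function(g, p, cache) {
  r <- cpp_bn_backward(g, cache$xhat, cache$invstd, p$gamma,
                       as.integer(cache$d), cache$training)
  list(gx = r$gx, gp = list(gamma = r$ggamma, beta = r$gbeta))
}

relu_fwd <- function(x) {
  out <- cpp_relu_forward(x)
  list(out = out, cache = out)
}

relu_bwd <- function(g, cache) cpp_relu_backward(g, cache)

sigmoid <- function(x) 1 / (1 + exp(-x))

fc_fwd <- function(x, p) {
  out <- x %*% p$w + rep(p$b, each = nrow(x))
  list(out = out, cache = x)
}

fc_bwd <- function(g, p, cache) {
  list(gx = tcrossprod(g, p$w),
       gp = list(w = crossprod(cache, g), b = colSums(g)))
}

# Two-class softmax on an (N, 2) logit matrix; numerically stabilized.
softmax2 <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Two-class cross-entropy
#'
#' Mean of `-[y * log(p1) + (1 - y) * log(p2)]` over the batch, where `p1`
#' is the predicted probability of the positive class (ER). Probabilities
#' are clamped to `[eps, 1 - eps]` before the log.
#'
#' @param probs Matrix (N, 2) of class probabilities, column 1 = ER.
#' @param labels Integer vector of 0/1 labels (1 = ER).
#' @param eps Clamping epsilon.
#' @return Nonnegative scalar loss.
#' @export
cross_entropy <- function(probs, labels, eps = 1e-7) {
  probs <- matrix(probs, ncol = 2)
  stopifnot(nrow(probs) == length(labels), all(labels %in% c(0, 1)))
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(labels * log(p[, 1]) + (1 - labels) * log(p[, 2]))
}

# Gradient of cross_entropy wrt the logits that produced `probs` via
# softmax2: (p - onehot)/N.
ce_softmax_grad <- function(probs, labels) {
  n <- length(labels)
  g <- probs
  g[, 1] <- g[, 1] - labels
  g[, 2] <- g[, 2] - (1 - labels)
  g / n
}

# ---- Adam optimizer over nested parameter lists -------------------------
# Gradient trees mirror the parameter trees but may omit leaves (e.g. the
# `stats` environments of batch-norm layers, which carry no gradient).

adam_init <- function() list(m = list(), v = list(), t = 0L)

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  rec <- function(p, g, m, v) {
    if (is.numeric(g)) {
      if (is.null(m)) { m <- g * 0; v <- g * 0 }
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / (1 - beta1^t)) / (sqrt(v / (1 - beta2^t)) + eps)
      list(p = p, m = m, v = v)
    } else {
      for (nm in names(g)) {
        if (is.null(g[[nm]]) || is.environment(g[[nm]])) next
        r <- rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p
        if (is.null(m)) m <- list()
        if (is.null(v)) v <- list()
        m[[nm]] <- r$m
        v[[nm]] <- r$v
      }
      list(p = p, m = m, v = v)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# Elementwise sum of two gradient trees (NULL treated as zero).
tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  for (nm in union(names(a), names(b))) a[[nm]] <- tree_add(a[[nm]], b[[nm]])
  a
}
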