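# Intra-phase and inter-phase attention.
#
# Intra-phase attention combines squeeze-excite channel attention and a
# CBAM-style spatial attention in parallel on one phase's feature map:
#   out = fmap (x) channel_weights + fmap (x) spatial_map.
# Inter-phase attention computes each phase's channel vector and spatial
# map, averages them across the three phases, applies the shared vector and
# the shared map to each phase's original feature map, and sums all six
# resulting maps into one fused map.

#' Attention parameters for a C-channel feature map
#'
#' Channel attention: two fully connected layers C -> floor(C/r) -> C
#' (reduction ratio `r`, rectifier between, sigmoid after). Spatial
#' attention: one 7x7 convolution from the 2 pooled planes (channel max,
#' channel mean) to 1, same-padded, sigmoid after.
#'
#' @param channels Channel count C of the feature maps this module acts on.
#' @param r Reduction ratio (default 16); the bottleneck width is
#'   `max(1, floor(C/r))`.
#' @param seed Integer seed for deterministic initialization.
#' @return An `attention_params` object.
#' @export
attention_params <- function(channels, r = 16L, seed = 1L) {
  stopifnot(channels >= 1, r >= 1)
  cr <- max(1L, channels %/% as.integer(r))
  p <- with_seed(seed, list(
    fc1 = init_fc(channels, cr),
    fc2 = init_fc(cr, channels),
    conv = init_conv(7L, 7L, 2L, 1L)
  ))
  structure(c(p, list(channels = as.integer(channels), r = as.integer(r))),
            class = "attention_params")
}

gap_fwd <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  s <- matrix(colMeans(matrix(x, hw, d[3] * d[4])), d[3], d[4])
  list(out = s, cache = d)
}

gap_bwd <- function(g, d) {
  hw <- d[1] * d[2]
  array(rep(as.vector(g), each = hw) / hw, dim = d)
}

channel_att_fwd <- function(x, p) {
  gp <- gap_fwd(x)
  f1 <- fc_fwd(gp$out, p$fc1)
  r1 <- relu_fwd(f1$out)
  f2 <- fc_fwd(r1$out, p$fc2)
  a <- sigmoid(f2$out)
  list(out = a, cache = list(gp = gp, f1 = f1, r1 = r1, f2 = f2, a = a))
}

# ga: gradient wrt the (N, C) weight matrix. Returns gradient wrt x (through
# the squeeze pooling) and wrt the two FC layers.
channel_att_bwd <- function(ga, p, cache) {
  gz <- ga * cache$a * (1 - cache$a)
  f2 <- fc_bwd(gz, p$fc2, cache$f2$cache)
  gr <- relu_bwd(f2$gx, cache$r1$cache)
  f1 <- fc_bwd(gr, p$fc1, cache$f1$cache)
  list(gx = gap_bwd(f1$gx, cache$gp$cache),
       gp = list(fc1 = f1$gp, fc2 = f2$gp))
}

channel_pool_fwd <- function(x) {
  d <- dim(x)
  n <- prod(d[1:3])
  C <- d[4]
  xm <- matrix(x, n, C)
  mx <- xm[, 1]
  amax <- rep(1L, n)
  if (C > 1) for (c in 2:C) {
    sel <- xm[, c] > mx
    mx[sel] <- xm[sel, c]
    amax[sel] <- c
  }
  mn <- rowMeans(xm)
  s2 <- array(c(mx, mn), dim = c(d[1:3], 2L))
  list(out = s2, cache = list(amax = amax, d = d))
}

channel_pool_bwd <- function(g2, cache) {
  d <- cache$d
  n <- prod(d[1:3])
  gm <- matrix(0, n, d[4])
  g2m <- matrix(g2, n, 2L)
  gm[cbind(seq_len(n), cache$amax)] <- g2m[, 1]
  gm <- gm + g2m[, 2] / d[4]
  array(gm, dim = d)
}

spatial_att_fwd <- function(x, p) {
  cp <- channel_pool_fwd(x)
  cv <- conv_fwd(cp$out, p$conv, stride = 1L, pad = 3L)
  s <- sigmoid(cv$out)
  dim(s) <- dim(s)[1:3]
  list(out = s, cache = list(cp = cp, cv = cv, s = s))
}

spatial_att_bwd <- function(gs, p, cache) {
  gz <- gs * cache$s * (1 - cache$s)
  dim(gz) <- c(dim(gz), 1L)
  cv <- conv_bwd(gz, p$conv, cache$cv$cache)
  list(gx = channel_pool_bwd(cv$gx, cache$cp$cache),
       gp = list(conv = cv$gp))
}

# Broadcast helpers on (H, W, N, C) arrays.
bc_channel <- function(x, a) {
  d <- dim(x)
  x * rep(as.vector(a), each = d[1] * d[2])
}
bc_spatial <- function(x, s) x * as.vector(s)
sum_over_hw <- function(v, d) matrix(colSums(matrix(v, d[1] * d[2], d[3] * d[4])), d[3], d[4])
sum_over_c <- function(v, d) array(rowSums(matrix(v, prod(d[1:3]), d[4])), dim = d[1:3])

#' Channel attention weights (squeeze-excite)
#'
#' Global average pooling over H x W, FC to C/r, rectifier, FC back to C,
#' sigmoid. All weights lie strictly in (0, 1).
#'
#' @param fmap Feature map array (H, W, N, C).
#' @param params An [attention_params()].
#' @return Matrix (N, C) of per-sample channel weights (the C x 1 x 1
#'   attention vector of each sample).
#' @export
channel_attention_weights <- function(fmap, params) {
  stopifnot(dim(fmap)[4] == params$channels)
  channel_att_fwd(fmap, params)$out
}

#' Spatial attention map
#'
#' Per-pixel channel max and channel mean pooled to two planes, a 7x7
#' same-padded convolution down to one plane, then a sigmoid.
#'
#' @inheritParams channel_attention_weights
#' @return Array (H, W, N) of per-pixel weights in (0, 1).
#' @export
spatial_attention_map <- function(fmap, params) {
  spatial_att_fwd(fmap, params)$out
}

intra_fwd <- function(x, p) {
  ca <- channel_att_fwd(x, p)
  sa <- spatial_att_fwd(x, p)
  out <- bc_channel(x, ca$out) + bc_spatial(x, sa$out)
  list(out = out, cache = list(x = x, ca = ca, sa = sa))
}

intra_bwd <- function(g, p, cache) {
  x <- cache$x
  d <- dim(x)
  gx <- bc_channel(g, cache$ca$out) + bc_spatial(g, cache$sa$out)
  ga <- sum_over_hw(g * x, d)
  gs <- sum_over_c(g * x, d)
  cb <- channel_att_bwd(ga, p, cache$ca$cache)
  sb <- spatial_att_bwd(gs, p, cache$sa$cache)
  list(gx = gx + cb$gx + sb$gx,
       gp = tree_add(cb$gp, sb$gp))
}

#' Intra-phase attention
#'
#' Channel and spatial attention applied in parallel to one phase's feature
#' map and summed:
#' `out = fmap * channel_weights + fmap * spatial_map`.
#' With all attention weights forced to 0.5 (zeroed parameters) the module
#' is the identity.
#'
#' @inheritParams channel_attention_weights
#' @return Feature map with the same dimensions as `fmap`.
#' @export
intra_phase_attention <- function(fmap, params) {
  stopifnot(inherits(params, "attention_params"),
            dim(fmap)[4] == params$channels)
  intra_fwd(fmap, params)$out
}

inter_fwd <- function(xs, ps) {
  stopifnot(length(xs) == 3L, length(ps) == 3L)
  d <- dim(xs[[1]])
  stopifnot(identical(d, dim(xs[[2]])), identical(d, dim(xs[[3]])))
  cas <- lapply(1:3, function(i) channel_att_fwd(xs[[i]], ps[[i]]))
  sas <- lapply(1:3, function(i) spatial_att_fwd(xs[[i]], ps[[i]]))
  abar <- (cas[[1]]$out + cas[[2]]$out + cas[[3]]$out) / 3
  sbar <- (sas[[1]]$out + sas[[2]]$out + sas[[3]]$out) / 3
  xsum <- xs[[1]] + xs[[2]] + xs[[3]]
  out <- bc_channel(xsum, abar) + bc_spatial(xsum, sbar)
  list(out = out, cache = list(xs = xs, cas = cas, sas = sas,
                               abar = abar, sbar = sbar, xsum = xsum, d = d))
}

inter_bwd <- function(g, ps, cache) {
  d <- cache$d
  g_xsum <- bc_channel(g, cache$abar) + bc_spatial(g, cache$sbar)
  gabar <- sum_over_hw(g * cache$xsum, d) / 3
  gsbar <- sum_over_c(g * cache$xsum, d) / 3
  gxs <- vector("list", 3L)
  gps <- vector("list", 3L)
  for (i in 1:3) {
    cb <- channel_att_bwd(gabar, ps[[i]], cache$cas[[i]]$cache)
    sb <- spatial_att_bwd(gsbar, ps[[i]], cache$sas[[i]]$cache)
    gxs[[i]] <- g_xsum + cb$gx + sb$gx
    gps[[i]] <- tree_add(cb$gp, sb$gp)
  }
  list(gxs = gxs, gps = gps)
}

#' Inter-phase attention
#'
#' Each phase's channel attention vector and spatial attention map are
#' averaged across the three phases into one shared vector and one shared
#' map; each phase's original feature map is scaled by the shared vector
#' and, in parallel, multiplied by the shared map; all six resulting maps
#' are summed into a single fused feature map. With zeroed parameters the
#' module returns the plain sum of the three inputs.
#'
#' @param fmaps List of three feature maps with identical dimensions
#'   (phase order NC, ART, PV).
#' @param params List of three [attention_params()], one per phase.
#' @return Fused feature map with the common input dimensions.
#' @export
inter_phase_attention <- function(fmaps, params) {
  inter_fwd(fmaps, params)$out
}
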