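# Residual branch CNNs: one branch per contrast phase (NC, ART, PV).
# Depths "18" and "50" follow the classical residual-network stage layout
# (input 224, stem 7x7/2 + 3x3/2 max pool, four stages halving the spatial
# size to 7x7); "small" is a two-stage 16/32-channel variant for 64x64
# inputs that keeps every contract but runs at desk scale.

#' Branch configuration
#'
#' @param depth One of `"small"`, `"18"`, `"50"`.
#' @param input_size Input (H, W) in pixels. Defaults: 64 for `"small"`,
#'   224 otherwise.
#' @param replicate_gray_to_3 Replicate the single-channel phase image to 3
#'   channels at the stem so branch weights stay shape-compatible with
#'   natural-image pretrained checkpoints. Default TRUE for depths 18/50,
#'   FALSE for `"small"`.
#' @param conv5_width Channel width of the last stage for depth 18. The
#'   default 256 follows the reference table of the architecture this
#'   package implements; set 512 for the classical layout.
#' @return A `branch_config` list with the stem and per-stage specification.
#' @export
branch_config <- function(depth = c("small", "18", "50"), input_size = NULL,
                          replicate_gray_to_3 = NULL, conv5_width = 256L) {
  depth <- match.arg(as.character(depth), c("small", "18", "50"))
  if (is.null(input_size)) input_size <- if (depth == "small") c(64L, 64L) else c(224L, 224L)
  if (length(input_size) == 1) input_size <- rep(input_size, 2)
  if (is.null(replicate_gray_to_3)) replicate_gray_to_3 <- depth != "small"
  cfg <- switch(depth,
    "small" = list(
      stem = list(kernel = 3L, channels = 8L, stride = 2L, pad = 1L),
      stages = list(
        list(kind = "basic", out = 16L, blocks = 1L, stride = 2L),
        list(kind = "basic", out = 32L, blocks = 1L, stride = 2L))),
    "18" = list(
      stem = list(kernel = 7L, channels = 64L, stride = 2L, pad = 3L),
      stages = list(
        list(kind = "basic", out = 64L, blocks = 2L, stride = 1L),
        list(kind = "basic", out = 128L, blocks = 2L, stride = 2L),
        list(kind = "basic", out = 256L, blocks = 2L, stride = 2L),
        list(kind = "basic", out = as.integer(conv5_width), blocks = 2L, stride = 2L))),
    "50" = list(
      stem = list(kernel = 7L, channels = 64L, stride = 2L, pad = 3L),
      stages = list(
        list(kind = "bottleneck", out = 256L, mid = 64L, blocks = 3L, stride = 1L),
        list(kind = "bottleneck", out = 512L, mid = 128L, blocks = 4L, stride = 2L),
        list(kind = "bottleneck", out = 1024L, mid = 256L, blocks = 6L, stride = 2L),
        list(kind = "bottleneck", out = 2048L, mid = 512L, blocks = 3L, stride = 2L)))
  )
  structure(list(depth = depth, input_size = as.integer(input_size),
                 replicate_gray_to_3 = isTRUE(replicate_gray_to_3),
                 stem = cfg$stem, stages = cfg$stages),
            class = "branch_config")
}

#' Channel count of a branch's final feature map
#' @param config A `branch_config`.
#' @return Integer channel count.
#' @export
branch_out_channels <- function(config) {
  config$stages[[length(config$stages)]]$out
}

init_basic_block <- function(cin, cout, stride) {
  b <- list(conv1 = init_conv(3L, 3L, cin, cout), bn1 = init_bn(cout),
            conv2 = init_conv(3L, 3L, cout, cout), bn2 = init_bn(cout),
            stride = stride)
  if (stride != 1L || cin != cout) {
    b$down <- list(conv = init_conv(1L, 1L, cin, cout), bn = init_bn(cout))
  }
  b
}

init_bottleneck_block <- function(cin, mid, cout, stride) {
  b <- list(conv1 = init_conv(1L, 1L, cin, mid), bn1 = init_bn(mid),
            conv2 = init_conv(3L, 3L, mid, mid), bn2 = init_bn(mid),
            conv3 = init_conv(1L, 1L, mid, cout), bn3 = init_bn(cout),
            stride = stride)
  if (stride != 1L || cin != cout) {
    b$down <- list(conv = init_conv(1L, 1L, cin, cout), bn = init_bn(cout))
  }
  b
}

#' Build one residual branch
#'
#' Parameter initialization is deterministic given `seed`; three branches
#' built with three seeds have fully independent weights.
#'
#' @param config A [branch_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `dpa_branch` object (config + parameters).
#' @export
build_branch <- function(config, seed = 1L) {
  stopifnot(inherits(config, "branch_config"))
  params <- with_seed(seed, {
    cin <- if (config$replicate_gray_to_3) 3L else 1L
    stem <- list(conv = init_conv(config$stem$kernel, config$stem$kernel,
                                  cin, config$stem$channels),
                 bn = init_bn(config$stem$channels))
    c_prev <- config$stem$channels
    stages <- lapply(config$stages, function(st) {
      blocks <- vector("list", st$blocks)
      for (i in seq_len(st$blocks)) {
        s <- if (i == 1L) st$stride else 1L
        blocks[[i]] <- if (st$kind == "basic") {
          init_basic_block(c_prev, st$out, s)
        } else {
          init_bottleneck_block(c_prev, st$mid, st$out, s)
        }
        c_prev <<- st$out
      }
      blocks
    })
    list(stem = stem, stages = stages)
  })
  structure(list(config = config, params = params), class = "dpa_branch")
}

#' @export
print.dpa_branch <- function(x, ...) {
  cat("Residual branch (depth ", x$config$depth, ", input ",
      paste(x$config$input_size, collapse = "x"), ", ",
      branch_out_channels(x$config), " output channels, ",
      branch_param_count(x), " parameters)\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters in a branch
#' @param branch A `dpa_branch`.
#' @return Integer count of weights (convolutions, biases, batch-norm
#'   scale/shift).
#' @export
branch_param_count <- function(branch) {
  n <- 0L
  rec <- function(p) {
    nms <- if (is.null(names(p))) rep("", length(p)) else names(p)
    for (i in seq_along(p)) {
      v <- p[[i]]
      if (is.numeric(v) && nms[i] != "stride") n <<- n + length(v)
      else if (is.list(v)) rec(v)
    }
  }
  rec(branch$params)
  n
}

#' Save / load branch weights
#'
#' Writes one branch's parameters to a single RDS container, or initializes
#' a branch from an externally supplied checkpoint (e.g. weights converted
#' from a natural-image pretrained model). Loading validates every layer's
#' shape against the branch configuration and reports all mismatching
#' layers by name; nothing is ever downloaded.
#'
#' @param branch A `dpa_branch`.
#' @param path Checkpoint file path.
#' @return `save_branch_weights` returns `path` invisibly;
#'   `load_branch_weights` returns the branch with weights replaced.
#' @export
save_branch_weights <- function(branch, path) {
  stopifnot(inherits(branch, "dpa_branch"))
  saveRDS(list(format = "dpanet-branch-1", depth = branch$config$depth,
               params = freeze_stats(branch$params)), path)
  invisible(path)
}

#' @rdname save_branch_weights
#' @export
load_branch_weights <- function(branch, path) {
  stopifnot(inherits(branch, "dpa_branch"))
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "dpanet-branch-1")) {
    stop("not a dpanet branch checkpoint: ", path)
  }
  new <- thaw_stats(obj$params)
  mismatches <- character(0)
  walk <- function(cur, cand, prefix) {
    nms <- names(cur) %||% as.character(seq_along(cur))
    for (i in seq_along(cur)) {
      path_nm <- paste0(prefix, nms[i])
      el <- cur[[i]]
      ca <- if (i <= length(cand)) cand[[i]] else NULL
      if (is.environment(el)) next
      if (is.numeric(el)) {
        dd <- dim(el) %||% length(el)
        cd <- dim(ca) %||% length(ca)
        if (is.null(ca) || !identical(as.integer(cd), as.integer(dd))) {
          mismatches <<- c(mismatches, sprintf(
            "%s: expected [%s], checkpoint [%s]", path_nm,
            paste(dd, collapse = "x"),
            if (is.null(ca)) "missing" else paste(cd, collapse = "x")))
        }
      } else if (is.list(el)) {
        walk(el, ca %||% list(), paste0(path_nm, "."))
      }
    }
  }
  walk(branch$params, new, "")
  if (length(mismatches)) {
    stop("checkpoint layer mismatch:\n  ", paste(mismatches, collapse = "\n  "))
  }
  branch$params <- new
  branch
}

basic_block_fwd <- function(x, p, training) {
  c1 <- conv_fwd(x, p$conv1, stride = p$stride, pad = 1L)
  b1 <- bn_fwd(c1$out, p$bn1, training)
  r1 <- relu_fwd(b1$out)
  c2 <- conv_fwd(r1$out, p$conv2, stride = 1L, pad = 1L)
  b2 <- bn_fwd(c2$out, p$bn2, training)
  if (!is.null(p$down)) {
    dc <- conv_fwd(x, p$down$conv, stride = p$stride, pad = 0L)
    db <- bn_fwd(dc$out, p$down$bn, training)
    sc <- db$out
  } else {
    dc <- db <- NULL
    sc <- x
  }
  ro <- relu_fwd(b2$out + sc)
  list(out = ro$out,
       cache = list(c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2,
                    dc = dc, db = db, ro = ro))
}

basic_block_bwd <- function(g, p, cache) {
  gs <- relu_bwd(g, cache$ro$cache)
  b2 <- bn_bwd(gs, p$bn2, cache$b2$cache)
  c2 <- conv_bwd(b2$gx, p$conv2, cache$c2$cache)
  gr1 <- relu_bwd(c2$gx, cache$r1$cache)
  b1 <- bn_bwd(gr1, p$bn1, cache$b1$cache)
  c1 <- conv_bwd(b1$gx, p$conv1, cache$c1$cache)
  gp <- list(conv1 = c1$gp, bn1 = b1$gp, conv2 = c2$gp, bn2 = b2$gp)
  if (!is.null(p$down)) {
    db <- bn_bwd(gs, p$down$bn, cache$db$cache)
    dc <- conv_bwd(db$gx, p$down$conv, cache$dc$cache)
    gp$down <- list(conv = dc$gp, bn = db$gp)
    gx <- c1$gx + dc$gx
  } else {
    gx <- c1$gx + gs
  }
  list(gx = gx, gp = gp)
}

bottleneck_block_fwd <- function(x, p, training) {
  c1 <- conv_fwd(x, p$conv1, stride = 1L, pad = 0L)
  b1 <- bn_fwd(c1$out, p$bn1, training); r1 <- relu_fwd(b1$out)
  c2 <- conv_fwd(r1$out, p$conv2, stride = p$stride, pad = 1L)
  b2 <- bn_fwd(c2$out, p$bn2, training); r2 <- relu_fwd(b2$out)
  c3 <- conv_fwd(r2$out, p$conv3, stride = 1L, pad = 0L)
  b3 <- bn_fwd(c3$out, p$bn3, training)
  if (!is.null(p$down)) {
    dc <- conv_fwd(x, p$down$conv, stride = p$stride, pad = 0L)
    db <- bn_fwd(dc$out, p$down$bn, training)
    sc <- db$out
  } else {
    dc <- db <- NULL
    sc <- x
  }
  ro <- relu_fwd(b3$out + sc)
  list(out = ro$out,
       cache = list(c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2, r2 = r2,
                    c3 = c3, b3 = b3, dc = dc, db = db, ro = ro))
}

bottleneck_block_bwd <- function(g, p, cache) {
  gs <- relu_bwd(g, cache$ro$cache)
  b3 <- bn_bwd(gs, p$bn3, cache$b3$cache)
  c3 <- conv_bwd(b3$gx, p$conv3, cache$c3$cache)
  gr2 <- relu_bwd(c3$gx, cache$r2$cache)
  b2 <- bn_bwd(gr2, p$bn2, cache$b2$cache)
  c2 <- conv_bwd(b2$gx, p$conv2, cache$c2$cache)
  gr1 <- relu_bwd(c2$gx, cache$r1$cache)
  b1 <- bn_bwd(gr1, p$bn1, cache$b1$cache)
  c1 <- conv_bwd(b1$gx, p$conv1, cache$c1$cache)
  gp <- list(conv1 = c1$gp, bn1 = b1$gp, conv2 = c2$gp, bn2 = b2$gp,
             conv3 = c3$gp, bn3 = b3$gp)
  if (!is.null(p$down)) {
    db <- bn_bwd(gs, p$down$bn, cache$db$cache)
    dc <- conv_bwd(db$gx, p$down$conv, cache$dc$cache)
    gp$down <- list(conv = dc$gp, bn = db$gp)
    gx <- c1$gx + dc$gx
  } else {
    gx <- c1$gx + gs
  }
  list(gx = gx, gp = gp)
}

# Normalize an image batch to (H, W, N, C) and replicate gray to 3 channels
# if the config asks for it.
prepare_branch_input <- function(x, config) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] != config$input_size[1] || d[2] != config$input_size[2]) {
    stop("image size ", d[1], "x", d[2], " does not match branch input size ",
         paste(config$input_size, collapse = "x"))
  }
  if (config$replicate_gray_to_3 && d[4] == 1L) {
    x <- array(rep(x, 3L), dim = c(d[1:3], 3L))
  }
  x
}

branch_fwd <- function(x, branch, training = FALSE) {
  cfg <- branch$config
  p <- branch$params
  x <- prepare_branch_input(x, cfg)
  sc <- conv_fwd(x, p$stem$conv, stride = cfg$stem$stride, pad = cfg$stem$pad)
  sb <- bn_fwd(sc$out, p$stem$bn, training)
  sr <- relu_fwd(sb$out)
  mp <- maxpool_fwd(sr$out, 3L, 2L, 1L)
  h <- mp$out
  stages <- vector("list", length(p$stages))
  for (si in seq_along(p$stages)) {
    blocks <- vector("list", length(p$stages[[si]]))
    for (bi in seq_along(p$stages[[si]])) {
      blk <- p$stages[[si]][[bi]]
      f <- if (branch$config$stages[[si]]$kind == "basic") basic_block_fwd else bottleneck_block_fwd
      r <- f(h, blk, training)
      h <- r$out
      blocks[[bi]] <- r$cache
    }
    stages[[si]] <- blocks
  }
  list(out = h, cache = list(sc = sc, sb = sb, sr = sr, mp = mp, stages = stages))
}

branch_bwd <- function(g, branch, cache) {
  p <- branch$params
  gstages <- vector("list", length(p$stages))
  for (si in rev(seq_along(p$stages))) {
    gblocks <- vector("list", length(p$stages[[si]]))
    bwd <- if (branch$config$stages[[si]]$kind == "basic") basic_block_bwd else bottleneck_block_bwd
    for (bi in rev(seq_along(p$stages[[si]]))) {
      r <- bwd(g, p$stages[[si]][[bi]], cache$stages[[si]][[bi]])
      g <- r$gx
      gblocks[[bi]] <- r$gp
    }
    gstages[[si]] <- gblocks
  }
  g <- maxpool_bwd(g, cache$mp$cache)
  g <- relu_bwd(g, cache$sr$cache)
  sb <- bn_bwd(g, p$stem$bn, cache$sb$cache)
  sc <- conv_bwd(sb$gx, p$stem$conv, cache$sc$cache, need_gx = FALSE)
  list(gp = list(stem = list(conv = sc$gp, bn = sb$gp), stages = gstages))
}

#' Forward pass of one branch
#'
#' Runs a single-phase ROI image batch through a residual branch and
#' returns the final-stage feature map (before any pooling), in evaluation
#' mode (running batch-norm statistics).
#'
#' @param image Array (H, W) for one image, (H, W, N) for a batch, or
#'   (H, W, N, C).
#' @param branch A `dpa_branch` from [build_branch()].
#' @return Feature map array (H', W', N, C').
#' @export
branch_forward <- function(image, branch) {
  stopifnot(inherits(branch, "dpa_branch"))
  branch_fwd(image, branch, training = FALSE)$out
}

#' Forward pass of the three-phase backbone
#'
#' Runs the NC, ART and PV phase images through their respective branches.
#' Phase order is fixed and preserved.
#'
#' @param phases List of exactly three image batches, in order NC, ART, PV.
#' @param branches List of exactly three `dpa_branch` objects.
#' @return Named list (`NC`, `ART`, `PV`) of feature maps with identical
#'   dimensions.
#' @export
backbone_forward <- function(phases, branches) {
  if (length(phases) != 3L) stop("exactly three phase images (NC, ART, PV) required")
  if (length(branches) != 3L) stop("exactly three branches required")
  maps <- lapply(1:3, function(i) branch_forward(phases[[i]], branches[[i]]))
  names(maps) <- c("NC", "ART", "PV")
  d <- dim(maps[[1]])
  stopifnot(identical(d, dim(maps[[2]])), identical(d, dim(maps[[3]])))
  maps
}
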