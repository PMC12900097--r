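#' Network configuration
#'
#' Assembles and validates the full architectural hyperparameter record for the
#' hybrid convolution / channel-wise-transformer U-shape. The reference
#' configuration (all defaults) uses four resolution levels with transformer
#' block counts `c(1, 2, 4, 8)` on the encoder path and bottleneck, attention
#' head counts `c(1, 2, 4, 8)`, channel widths `c(36, 72, 144, 288)`, a
#' query/key pooling factor `r = 2`, dense 3x3x3 stem and head convolutions,
#' depth-wise separable 4x4x4 stride-2 down/up resampling, additive skip
#' fusion, and a sigmoid head thresholded at 0.5.
#'
#' The feed-forward expansion `ffn_expansion` defaults to 2.25; together with
#' the other defaults this calibrates the reference configuration to a
#' parameter budget of 8.84 M trainable scalars (see the methods vignette for
#' the calibration and its residuals on the MAC/FLOP budgets).
#'
#' @param in_channels input channels (9 = 3 fiber-orientation peaks x xyz).
#' @param out_channels one sigmoid output channel per tract (72 in the
#'   reference setting).
#' @param level_channels,blocks_per_level,heads_per_level length-4 integer
#'   vectors; `level_channels` must be divisible by `heads_per_level`.
#' @param pool_factor max-pooling factor `r` applied to queries and keys
#'   before channel-wise attention.
#' @param ffn_expansion channel expansion factor of the gated feed-forward
#'   network; `ffn_expansion * level_channels` must be whole numbers.
#' @param conv_kernel,resample_kernel,resample_stride spatial kernel sizes of
#'   the dense convolutions and the stride-2 resampling convolutions.
#' @param use_norm apply per-voxel channel layer normalization before the
#'   attention and feed-forward sublayers (pre-norm).
#' @param qk_l2_normalize L2-normalize per-channel query/key token vectors
#'   before the dot product (off in the reference configuration).
#' @param threshold probability threshold for binarizing the sigmoid output.
#' @param nominal_patch nominal training patch side used to initialize the
#'   attention temperature to `1/sqrt(pooled token count)`.
#' @return an object of class `network_config`.
#' @export
network_config <- function(in_channels = 9L,
                           out_channels = 72L,
                           level_channels = c(36L, 72L, 144L, 288L),
                           blocks_per_level = c(1L, 2L, 4L, 8L),
                           heads_per_level = c(1L, 2L, 4L, 8L),
                           pool_factor = 2L,
                           ffn_expansion = 2.25,
                           conv_kernel = 3L,
                           resample_kernel = 4L,
                           resample_stride = 2L,
                           use_norm = TRUE,
                           qk_l2_normalize = FALSE,
                           threshold = 0.5,
                           nominal_patch = 64L) {
  stopifnot(length(level_channels) == 4L, length(blocks_per_level) == 4L,
            length(heads_per_level) == 4L)
  if (any(level_channels %% heads_per_level != 0))
    stop("level_channels must be divisible by heads_per_level", call. = FALSE)
  if (pool_factor < 1L) stop("pool_factor must be >= 1", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly in (0, 1)", call. = FALSE)
  gC <- ffn_expansion * level_channels
  if (any(abs(gC - round(gC)) > 1e-9))
    stop("ffn_expansion * level_channels must be whole numbers", call. = FALSE)
  cfg <- list(in_channels = as.integer(in_channels),
              out_channels = as.integer(out_channels),
              level_channels = as.integer(level_channels),
              blocks_per_level = as.integer(blocks_per_level),
              heads_per_level = as.integer(heads_per_level),
              pool_factor = as.integer(pool_factor),
              ffn_expansion = ffn_expansion,
              conv_kernel = as.integer(conv_kernel),
              resample_kernel = as.integer(resample_kernel),
              resample_stride = as.integer(resample_stride),
              use_norm = isTRUE(use_norm),
              qk_l2_normalize = isTRUE(qk_l2_normalize),
              threshold = threshold,
              nominal_patch = as.integer(nominal_patch))
  structure(cfg, class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat("network_config:", x$in_channels, "->", x$out_channels, "channels\n")
  cat("  levels   :", paste(x$level_channels, collapse = "/"), "channels,",
      paste(x$blocks_per_level, collapse = "/"), "blocks,",
      paste(x$heads_per_level, collapse = "/"), "heads\n")
  cat("  attention: pool r =", x$pool_factor,
      "| ffn expansion =", x$ffn_expansion,
      "| pre-norm =", x$use_norm, "\n")
  invisible(x)
}

# spatial divisibility required by the deepest pooling: 2^(levels-1) * r
resolution_factor <- function(cfg) 8L * cfg$pool_factor

ffn_channels <- function(cfg, l) as.integer(round(cfg$ffn_expansion * cfg$level_channels[l]))

# He-style fan-in init for conv weights
init_w <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

init_block <- function(cfg, l) {
  C <- cfg$level_channels[l]
  h <- cfg$heads_per_level[l]
  gC <- ffn_channels(cfg, l)
  k <- cfg$conv_kernel
  np <- max(cfg$nominal_patch %/% (2L^(l - 1L)), cfg$pool_factor)
  tokens <- (np %/% cfg$pool_factor)^3
  b <- list(
    q = list(dw = init_w(c(k, k, k, C), k^3), pw = init_w(c(C, C), C), pb = numeric(C)),
    k = list(dw = init_w(c(k, k, k, C), k^3), pw = init_w(c(C, C), C), pb = numeric(C)),
    v = list(dw = init_w(c(k, k, k, C), k^3), pw = init_w(c(C, C), C), pb = numeric(C)),
    refine = list(pw = init_w(c(C, C), C), pb = numeric(C)),
    alpha = rep(1 / sqrt(tokens), h),
    a = list(dw = init_w(c(k, k, k, C), k^3), pw = init_w(c(C, gC), C), pb = numeric(gC)),
    g = list(dw = init_w(c(k, k, k, C), k^3), pw = init_w(c(C, gC), C), pb = numeric(gC)),
    proj = list(pw = init_w(c(gC, C), gC), pb = numeric(C))
  )
  if (cfg$use_norm) {
    b$ln1 <- list(g = rep(1, C), b = numeric(C))
    b$ln2 <- list(g = rep(1, C), b = numeric(C))
  }
  b
}

#' Build a network from a configuration
#'
#' Instantiates all trainable parameters. Encoder level l consists of the
#' dense stem convolution (level 1) or a depth-wise separable stride-2 down
#' convolution, followed by `blocks_per_level[l]` transformer blocks; level 4
#' is the bottleneck. The decoder mirrors the spatial ladder with depth-wise
#' separable stride-2 up convolutions and additive skip fusion, and the dense
#' head convolution maps to per-tract logits (sigmoid probabilities at
#' inference). Weight initialization is deterministic given `seed`.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `tractformer_net`.
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  set.seed(seed)
  k <- cfg$conv_kernel
  rk <- cfg$resample_kernel
  ch <- cfg$level_channels
  params <- list(
    stem = list(w = init_w(c(k, k, k, cfg$in_channels, ch[1]), cfg$in_channels * k^3),
                b = numeric(ch[1])),
    enc = lapply(1:4, function(l)
      lapply(seq_len(cfg$blocks_per_level[l]), function(i) init_block(cfg, l))),
    down = lapply(1:3, function(l)
      list(dw = init_w(c(rk, rk, rk, ch[l]), rk^3),
           pw = init_w(c(ch[l], ch[l + 1]), ch[l]),
           pb = numeric(ch[l + 1]))),
    up = lapply(1:3, function(l)  # up[[l]] maps level l+1 -> level l
      list(dw = init_w(c(rk, rk, rk, ch[l + 1]), rk^3),
           pw = init_w(c(ch[l + 1], ch[l]), ch[l + 1]),
           pb = numeric(ch[l]))),
    # zero-init head: initial output is exactly sigmoid(0) = 0.5 per channel,
    # so the starting loss equals ln 2 regardless of network depth
    head = list(w = array(0, c(k, k, k, ch[1], cfg$out_channels)),
                b = numeric(cfg$out_channels))
  )
  structure(list(cfg = cfg, params = params, seed = as.integer(seed)),
            class = "tractformer_net")
}

#' @export
print.tractformer_net <- function(x, ...) {
  cat("tractformer_net with", format(n_params(x$params), big.mark = ","),
      "trainable parameters\n")
  print(x$cfg)
  invisible(x)
}

# total trainable scalar count of a (nested) parameter list
n_params <- function(p) {
  if (is.list(p)) return(sum(vapply(p, n_params, numeric(1))))
  length(p)
}

# ---- transformer block -----------------------------------------------------

ds_fwd <- function(x, p) {
  d <- dw_fwd(x, p$dw)
  o <- pw_fwd(d$y, p$pw, p$pb)
  list(y = o$y, cache = list(dwc = d$cache, pwc = o$cache))
}

ds_bwd <- function(dy, cache) {
  r1 <- pw_bwd(dy, cache$pwc)
  r2 <- dw_bwd(r1$dx, cache$dwc)
  list(dx = r2$dx, grads = list(dw = r2$grads$w, pw = r1$grads$w, pb = r1$grads$b))
}

#' Multi-head convolution-based channel-wise attention
#'
#' Queries and keys are depth-wise separable projections of the input, max
#' pooled by factor `r`; values are an unpooled projection. Tokens are the
#' per-channel spatial maps, so each head's attention matrix is
#' `(C/h) x (C/h)` with softmax rows summing to one; a learnable positive
#' per-head temperature scales the logits. The refined attention output is
#' added residually to the input.
#'
#' @param x feature map `[H, W, D, C]` with spatial dims divisible by `r`.
#' @param p block parameter list (fields `q`, `k`, `v`, `refine`, `alpha`).
#' @param r pooling factor.
#' @param heads number of attention heads (must divide C).
#' @param cache logical; return the backward cache.
#' @param l2norm L2-normalize per-channel query/key tokens before the dot
#'   product.
#' @return list with the output feature map `y` (and `cache` if requested).
#' @export
mcca <- function(x, p, r, heads, cache = FALSE, l2norm = FALSE) {
  C <- dim(x)[4]
  if (any(spatial_dim(x) %% r != 0))
    stop("spatial dims must be divisible by the pool factor r", call. = FALSE)
  if (C %% heads != 0)
    stop("channel count must be divisible by the head count", call. = FALSE)
  qp <- ds_fwd(x, p$q); kp <- ds_fwd(x, p$k); vp <- ds_fwd(x, p$v)
  qpl <- pool_fwd(qp$y, r); kpl <- pool_fwd(kp$y, r)
  at <- chan_attn_fwd(as_mat(qpl$y), as_mat(kpl$y), as_mat(vp$y), p$alpha,
                      heads, l2norm = l2norm)
  ref <- pw_fwd(as_vol(at$y, spatial_dim(x)), p$refine$pw, p$refine$pb)
  y <- ref$y + x
  if (!cache) return(list(y = y))
  list(y = y, cache = list(qc = qp$cache, kc = kp$cache, vc = vp$cache,
                           qplc = qpl$cache, kplc = kpl$cache,
                           atc = at$cache, refc = ref$cache,
                           sdim = spatial_dim(x), pdim = spatial_dim(qpl$y)))
}

mcca_bwd_full <- function(dy, cache) {
  rref <- pw_bwd(dy, cache$refc)
  da <- chan_attn_bwd(as_mat(rref$dx), cache$atc)
  rqp <- pool_bwd(as_vol(da$dq, cache$pdim), cache$qplc)
  rkp <- pool_bwd(as_vol(da$dk, cache$pdim), cache$kplc)
  rq <- ds_bwd(rqp$dx, cache$qc)
  rk <- ds_bwd(rkp$dx, cache$kc)
  rv <- ds_bwd(as_vol(da$dv, cache$sdim), cache$vc)
  dx <- rq$dx + rk$dx + rv$dx + dy   # + residual identity
  list(dx = dx,
       grads = list(q = rq$grads, k = rk$grads, v = rv$grads,
                    refine = list(pw = rref$grads$w, pb = rref$grads$b),
                    alpha = da$dalpha))
}

# ---- gated context-enhanced feed-forward -----------------------------------

#' Context-enhanced feed-forward network
#'
#' Two depth-wise separable branches expand the channels by the configured
#' factor; the value branch is gated elementwise by the GELU of the gate
#' branch, projected back to the input width by a pointwise convolution, and
#' added residually to the input.
#'
#' @param x feature map `[H, W, D, C]`.
#' @param p block parameter list (fields `a`, `g`, `proj`).
#' @param cache logical; return the backward cache.
#' @return list with the output feature map `y` (and `cache` if requested).
#' @export
cffn <- function(x, p, cache = FALSE) {
  av <- ds_fwd(x, p$a)
  gv <- ds_fwd(x, p$g)
  ge <- gelu_fwd(gv$y)
  gated <- av$y * ge$y
  pr <- pw_fwd(gated, p$proj$pw, p$proj$pb)
  y <- pr$y + x
  if (!cache) return(list(y = y))
  list(y = y, cache = list(ac = av$cache, gc = gv$cache, gec = ge$cache,
                           ay = av$y, gey = ge$y, prc = pr$cache))
}

cffn_bwd <- function(dy, cache) {
  rpr <- pw_bwd(dy, cache$prc)
  dav <- rpr$dx * cache$gey
  dge <- rpr$dx * cache$ay
  rge <- gelu_bwd(dge, cache$gec)
  ra <- ds_bwd(dav, cache$ac)
  rg <- ds_bwd(rge$dx, cache$gc)
  list(dx = ra$dx + rg$dx + dy,
       grads = list(a = ra$grads, g = rg$grads,
                    proj = list(pw = rpr$grads$w, pb = rpr$grads$b)))
}

#' Transformer block: pre-norm MCCA then pre-norm CFFN
#'
#' @param x feature map `[H, W, D, C]`.
#' @param p block parameter list from the network builder.
#' @param r pooling factor.
#' @param heads head count.
#' @param use_norm apply the pre-normalizations.
#' @param cache logical; return the backward cache.
#' @param l2norm L2-normalize query/key tokens in the attention sublayer.
#' @return list with output `y` (and `cache` if requested).
#' @export
transformer_block <- function(x, p, r, heads, use_norm = TRUE, cache = FALSE,
                              l2norm = FALSE) {
  if (use_norm) {
    n1 <- ln_fwd(x, p$ln1$g, p$ln1$b)
    m <- mcca(n1$y, p, r, heads, cache = cache, l2norm = l2norm)
    f1 <- m$y - n1$y + x   # residual around the *unnormalized* input
    n2 <- ln_fwd(f1, p$ln2$g, p$ln2$b)
    c2 <- cffn(n2$y, p, cache = cache)
    y <- c2$y - n2$y + f1
    if (!cache) return(list(y = y))
    return(list(y = y, cache = list(n1c = n1$cache, mc = m$cache, n2c = n2$cache,
                                    c2c = c2$cache, use_norm = TRUE)))
  }
  m <- mcca(x, p, r, heads, cache = cache, l2norm = l2norm)
  c2 <- cffn(m$y, p, cache = cache)
  if (!cache) return(list(y = c2$y))
  list(y = c2$y, cache = list(mc = m$cache, c2c = c2$cache, use_norm = FALSE))
}

block_bwd <- function(dy, cache) {
  if (cache$use_norm) {
    # y = (c2$y - n2$y) + f1 ; c2$y = cffn(n2$y); d n2$y = (dcffn - 1); etc.
    rc <- cffn_bwd(dy, cache$c2c)        # grad w.r.t. n2$y including +identity
    dn2 <- rc$dx - dy                     # remove identity: y has -n2$y term
    rn2 <- ln_bwd(dn2, cache$n2c)
    df1 <- rn2$dx + dy
    rm <- mcca_bwd_full(df1, cache$mc)
    dn1 <- rm$dx - df1
    rn1 <- ln_bwd(dn1, cache$n1c)
    dx <- rn1$dx + df1
    g <- rm$grads
    g$a <- rc$grads$a; g$g <- rc$grads$g; g$proj <- rc$grads$proj
    g$ln1 <- rn1$grads; g$ln2 <- rn2$grads
    return(list(dx = dx, grads = g))
  }
  rc <- cffn_bwd(dy, cache$c2c)
  rm <- mcca_bwd_full(rc$dx, cache$mc)
  g <- rm$grads
  g$a <- rc$grads$a; g$g <- rc$grads$g; g$proj <- rc$grads$proj
  list(dx = rm$dx, grads = g)
}

# ---- whole-network forward / backward --------------------------------------

pad_to_factor <- function(x, f) {
  sdim <- spatial_dim(x)
  target <- as.integer(ceiling(sdim / f) * f)
  if (all(target == sdim)) return(list(x = x, off = c(0L, 0L, 0L), orig = sdim))
  pad <- target - sdim
  lo <- pad %/% 2L
  out <- array(0, c(target, dim(x)[4]))
  out[lo[1] + seq_len(sdim[1]), lo[2] + seq_len(sdim[2]),
      lo[3] + seq_len(sdim[3]), ] <- x
  list(x = out, off = lo, orig = sdim)
}

crop_from_pad <- function(y, off, orig) {
  if (all(off == 0L) && all(spatial_dim(y) == orig)) return(y)
  y[off[1] + seq_len(orig[1]), off[2] + seq_len(orig[2]),
    off[3] + seq_len(orig[3]), , drop = FALSE]
}

# core forward on an already-divisible volume; returns logits
net_core_fwd <- function(net, x, cache = FALSE) {
  cfg <- net$cfg
  p <- net$params
  r <- cfg$pool_factor
  cc <- if (cache) list() else NULL
  st <- conv_fwd(x, p$stem$w, p$stem$b)
  f <- st$y
  if (cache) cc$stem <- st$cache
  skips <- vector("list", 3)
  if (cache) { cc$enc <- vector("list", 4); cc$down <- vector("list", 3) }
  for (l in 1:4) {
    if (cache) cc$enc[[l]] <- vector("list", cfg$blocks_per_level[l])
    for (i in seq_len(cfg$blocks_per_level[l])) {
      b <- transformer_block(f, p$enc[[l]][[i]], r, cfg$heads_per_level[l],
                             use_norm = cfg$use_norm, cache = cache,
                             l2norm = cfg$qk_l2_normalize)
      f <- b$y
      if (cache) cc$enc[[l]][[i]] <- b$cache
    }
    if (l < 4) {
      skips[[l]] <- f
      d <- down_fwd(f, p$down[[l]])
      f <- d$y
      if (cache) cc$down[[l]] <- d$cache
    }
  }
  if (cache) cc$up <- vector("list", 3)
  for (l in 3:1) {
    u <- up_fwd(f, p$up[[l]])
    f <- u$y + skips[[l]]
    if (cache) cc$up[[l]] <- u$cache
  }
  hd <- conv_fwd(f, p$head$w, p$head$b)
  if (cache) cc$head <- hd$cache
  list(logits = hd$y, cache = cc)
}

net_core_bwd <- function(net, cache, dlogits) {
  cfg <- net$cfg
  g <- list()
  rh <- conv_bwd(dlogits, cache$head)
  g$head <- list(w = rh$grads$w, b = rh$grads$b)
  df <- rh$dx
  dskips <- vector("list", 3)
  g$up <- vector("list", 3)
  for (l in 1:3) {
    dskips[[l]] <- df          # additive fusion passes gradient to the skip
    ru <- up_bwd(df, cache$up[[l]])
    g$up[[l]] <- ru$grads
    df <- ru$dx
  }
  g$enc <- vector("list", 4)
  g$down <- vector("list", 3)
  for (l in 4:1) {
    if (l < 4) {
      rd <- down_bwd(df, cache$down[[l]])
      g$down[[l]] <- rd$grads
      df <- rd$dx + dskips[[l]]
    }
    g$enc[[l]] <- vector("list", cfg$blocks_per_level[l])
    for (i in rev(seq_len(cfg$blocks_per_level[l]))) {
      rb <- block_bwd(df, cache$enc[[l]][[i]])
      g$enc[[l]][[i]] <- rb$grads
      df <- rb$dx
    }
  }
  rs <- conv_bwd(df, cache$stem)
  g$stem <- list(w = rs$grads$w, b = rs$grads$b)
  # reorder to match the parameter list layout
  list(grads = g[c("stem", "enc", "down", "up", "head")], dx = rs$dx)
}

#' Whole-volume inference
#'
#' Runs the network on a peak volume of arbitrary spatial size. Sizes that are
#' not divisible by the network's resolution factor (16 with the defaults) are
#' symmetrically zero-padded internally and the output is cropped back, so the
#' returned probability grid always matches the input spatial dimensions. No
#' patch splitting or merging is performed.
#'
#' @param net a built [build_network()] object.
#' @param peaks a `peak_volume` or a numeric `[H, W, D, C]` array with
#'   `in_channels` channels.
#' @return numeric array `[H, W, D, out_channels]` of probabilities in (0, 1).
#' @export
net_forward <- function(net, peaks) {
  x <- if (inherits(peaks, "peak_volume")) peaks$data else peaks
  if (length(dim(x)) != 4L)
    stop("input must be a 4D [H, W, D, C] array", call. = FALSE)
  if (dim(x)[4] != net$cfg$in_channels)
    stop(sprintf("input has %d channels; network expects %d",
                 dim(x)[4], net$cfg$in_channels), call. = FALSE)
  pp <- pad_to_factor(x, resolution_factor(net$cfg))
  out <- net_core_fwd(net, pp$x, cache = FALSE)
  prob <- 1 / (1 + exp(-out$logits))
  crop_from_pad(prob, pp$off, pp$orig)
}

#' Threshold a probability grid into a multi-label mask
#'
#' A voxel-channel is set iff its probability strictly exceeds `tau`, so a
#' probability exactly equal to the threshold maps to background.
#'
#' @param prob numeric array of probabilities in \[0, 1\].
#' @param tau threshold in (0, 1); default 0.5.
#' @param template optional `peak_volume`/`tract_labels` supplying spacing and
#'   affine for the returned `tract_labels`.
#' @return a `tract_labels` object with binary data of the same dimensions.
#' @export
threshold_probabilities <- function(prob, tau = 0.5, template = NULL) {
  if (tau <= 0 || tau >= 1) stop("tau must lie strictly in (0, 1)", call. = FALSE)
  if (min(prob) < 0 || max(prob) > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  m <- array(as.integer(prob > tau), dim(prob))
  tract_labels(m, spacing = if (!is.null(template)) template$spacing,
               affine = if (!is.null(template)) template$affine)
}

#' Save / load a network checkpoint
#'
#' Weights are stored in R's native serialization format with a JSON sidecar
#' (`<path>.json`) recording the full configuration and initialization seed.
#'
#' @param net a `tractformer_net`.
#' @param path checkpoint file path (`.rds`).
#' @return `save_network` returns `path` invisibly; `load_network` the network.
#' @export
save_network <- function(net, path) {
  saveRDS(net, path)
  sidecar <- sub("\\.rds$", "", path)
  jsonlite::write_json(unclass(net$cfg), paste0(sidecar, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "tractformer_net"))
  net
}
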