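# Independent dense-loop oracles used to validate the layer implementations.
# These deliberately share no code with the package internals: plain nested
# loops over voxels, kernel offsets and channels.

naive_dense_conv <- function(x, w, b = NULL) {
  d <- dim(x); k <- dim(w)[1]; cout <- dim(w)[5]; pad <- (k - 1) %/% 2
  y <- array(0, c(d[1:3], cout))
  for (co in 1:cout) for (h in 1:d[1]) for (wd in 1:d[2]) for (dd in 1:d[3]) {
    acc <- 0
    for (ci in 1:d[4]) for (kh in 1:k) for (kw in 1:k) for (kd in 1:k) {
      hi <- h + kh - 1 - pad; wi <- wd + kw - 1 - pad; di <- dd + kd - 1 - pad
      if (hi >= 1 && hi <= d[1] && wi >= 1 && wi <= d[2] && di >= 1 && di <= d[3])
        acc <- acc + x[hi, wi, di, ci] * w[kh, kw, kd, ci, co]
    }
    y[h, wd, dd, co] <- acc + if (is.null(b)) 0 else b[co]
  }
  y
}

naive_dw_conv <- function(x, w) {
  d <- dim(x); k <- dim(w)[1]; pad <- (k - 1) %/% 2
  y <- array(0, d)
  for (c in 1:d[4]) for (h in 1:d[1]) for (wd in 1:d[2]) for (dd in 1:d[3]) {
    acc <- 0
    for (kh in 1:k) for (kw in 1:k) for (kd in 1:k) {
      hi <- h + kh - 1 - pad; wi <- wd + kw - 1 - pad; di <- dd + kd - 1 - pad
      if (hi >= 1 && hi <= d[1] && wi >= 1 && wi <= d[2] && di >= 1 && di <= d[3])
        acc <- acc + x[hi, wi, di, c] * w[kh, kw, kd, c]
    }
    y[h, wd, dd, c] <- acc
  }
  y
}

naive_pw_conv <- function(x, w, b = NULL) {
  d <- dim(x); cout <- ncol(w)
  y <- array(0, c(d[1:3], cout))
  for (co in 1:cout) for (h in 1:d[1]) for (wd in 1:d[2]) for (dd in 1:d[3]) {
    acc <- 0
    for (ci in 1:d[4]) acc <- acc + x[h, wd, dd, ci] * w[ci, co]
    y[h, wd, dd, co] <- acc + if (is.null(b)) 0 else b[co]
  }
  y
}

naive_maxpool <- function(x, r) {
  d <- dim(x)
  y <- array(-Inf, c(d[1:3] %/% r, d[4]))
  dy <- dim(y)
  for (c in 1:d[4]) for (h in 1:dy[1]) for (wd in 1:dy[2]) for (dd in 1:dy[3])
    y[h, wd, dd, c] <- max(x[(r * (h - 1) + 1):(r * h),
                             (r * (wd - 1) + 1):(r * wd),
                             (r * (dd - 1) + 1):(r * dd), c])
  y
}

naive_ds_conv <- function(x, p) naive_pw_conv(naive_dw_conv(x, p$dw), p$pw, p$pb)

# Dense-loop evaluation of the channel-wise attention equation:
# per head, Q', K' are (C/h) x Vp, V' is (C/h) x V; S = softmax(alpha Q'K'^T)
# rowwise; output rows are S V'.
oracle_mcca <- function(x, p, r, heads) {
  q <- naive_maxpool(naive_ds_conv(x, p$q), r)
  k <- naive_maxpool(naive_ds_conv(x, p$k), r)
  v <- naive_ds_conv(x, p$v)
  C <- dim(x)[4]; cp <- C %/% heads
  vp <- prod(dim(q)[1:3]); vf <- prod(dim(v)[1:3])
  out <- array(0, dim(v))
  for (hd in 1:heads) {
    ch <- ((hd - 1) * cp + 1):(hd * cp)
    qp <- t(matrix(q[, , , ch], vp, cp))      # C' x Vp rows = channel tokens
    kp <- t(matrix(k[, , , ch], vp, cp))
    vpm <- t(matrix(v[, , , ch], vf, cp))
    logits <- p$alpha[hd] * (qp %*% t(kp))
    s <- matrix(0, cp, cp)
    for (i in 1:cp) {
      e <- exp(logits[i, ] - max(logits[i, ]))
      s[i, ] <- e / sum(e)
    }
    o <- s %*% vpm                             # (C/h) x V
    out[, , , ch] <- array(t(o), c(dim(v)[1:3], cp))
  }
  naive_pw_conv(out, p$refine$pw, p$refine$pb) + x
}

oracle_cffn <- function(x, p) {
  a <- naive_ds_conv(x, p$a)
  g <- naive_ds_conv(x, p$g)
  gate <- g * pnorm(g)                         # exact GELU
  naive_pw_conv(a * gate, p$proj$pw, p$proj$pb) + x
}

# brute-force two-tailed signed-rank p over all 2^n sign patterns
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  stat_obs <- min(sum(rk[d > 0]), sum(rk[d < 0]))
  total <- 2^n
  count <- 0
  for (m in 0:(total - 1)) {
    signs <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    wp <- sum(rk[signs])
    if (min(wp, sum(rk) - wp) <= stat_obs) count <- count + 1
  }
  count / total
}

# a tiny random network configuration used across model tests
tiny_config <- function(...) {
  network_config(in_channels = 2L, out_channels = 3L,
                 level_channels = c(4L, 8L, 8L, 16L),
                 blocks_per_level = c(1L, 1L, 1L, 1L),
                 heads_per_level = c(1L, 2L, 2L, 2L),
                 ffn_expansion = 2, nominal_patch = 16L, ...)
}

zero_weights <- function(net) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  net$params <- zero(net$params)
  net
}

random_block_params <- function(C, gC, heads, seed, scale = 0.3) {
  set.seed(seed)
  rw <- function(d) array(rnorm(prod(d), 0, scale), d)
  list(q = list(dw = rw(c(3, 3, 3, C)), pw = rw(c(C, C)), pb = rnorm(C, 0, scale)),
       k = list(dw = rw(c(3, 3, 3, C)), pw = rw(c(C, C)), pb = rnorm(C, 0, scale)),
       v = list(dw = rw(c(3, 3, 3, C)), pw = rw(c(C, C)), pb = rnorm(C, 0, scale)),
       refine = list(pw = rw(c(C, C)), pb = rnorm(C, 0, scale)),
       alpha = abs(rnorm(heads, 1, 0.2)),
       a = list(dw = rw(c(3, 3, 3, C)), pw = rw(c(C, gC)), pb = rnorm(gC, 0, scale)),
       g = list(dw = rw(c(3, 3, 3, C)), pw = rw(c(C, gC)), pb = rnorm(gC, 0, scale)),
       proj = list(pw = rw(c(gC, C)), pb = rnorm(C, 0, scale)),
       ln1 = list(g = rnorm(C, 1, 0.1), b = rnorm(C, 0, 0.1)),
       ln2 = list(g = rnorm(C, 1, 0.1), b = rnorm(C, 0, 0.1)))
}
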