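# Differentiable layer primitives. Every layer exposes a forward returning
# list(y, cache) and a backward taking (dy, cache) and returning list(dx, grads)
# with grads named congruently to the parameter list. Feature maps are dense
# [H, W, D, C] arrays; pointwise work is done on the V x C matrix view (BLAS),
# spatial kernels in compiled code.

as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

as_vol <- function(m, sdim) {
  dim(m) <- c(sdim, ncol(m))
  m
}

spatial_dim <- function(x) dim(x)[1:3]

# ---- pointwise (1x1x1) convolution -----------------------------------------

pw_fwd <- function(x, w, b = NULL) {
  sdim <- spatial_dim(x)
  xm <- as_mat(x)
  ym <- xm %*% w
  if (!is.null(b)) ym <- sweep(ym, 2L, b, "+")
  list(y = as_vol(ym, sdim), cache = list(xm = xm, w = w, sdim = sdim,
                                          bias = !is.null(b)))
}

pw_bwd <- function(dy, cache) {
  dym <- as_mat(dy)
  dx <- as_vol(dym %*% t(cache$w), cache$sdim)
  g <- list(w = crossprod(cache$xm, dym))
  if (cache$bias) g$b <- colSums(dym)
  list(dx = dx, grads = g)
}

# ---- dense kxkxk convolution, stride 1 -------------------------------------

conv_fwd <- function(x, w, b = NULL) {
  dn <- dim(w)            # [k,k,k,Cin,Cout]
  y <- cpp_conv3d_fwd(x, dim(x), w, dn[5], dn[1])
  dim(y) <- c(spatial_dim(x), dn[5])
  if (!is.null(b)) y <- sweep(y, 4L, b, "+")
  list(y = y, cache = list(x = x, w = w, bias = !is.null(b)))
}

conv_bwd <- function(dy, cache) {
  dn <- dim(cache$w)
  r <- cpp_conv3d_bwd(cache$x, dim(cache$x), cache$w, dn[5], dn[1], dy)
  dx <- r$dx; dim(dx) <- dim(cache$x)
  dw <- r$dw; dim(dw) <- dn
  g <- list(w = dw)
  if (cache$bias) g$b <- colSums(as_mat(dy))
  list(dx = dx, grads = g)
}

# ---- depth-wise 3x3x3 convolution ------------------------------------------

dw_fwd <- function(x, w) {
  y <- cpp_dwconv3d_fwd(x, dim(x), w, dim(w)[1])
  dim(y) <- dim(x)
  list(y = y, cache = list(x = x, w = w))
}

dw_bwd <- function(dy, cache) {
  r <- cpp_dwconv3d_bwd(cache$x, dim(cache$x), cache$w, dim(cache$w)[1], dy)
  dx <- r$dx; dim(dx) <- dim(cache$x)
  dw <- r$dw; dim(dw) <- dim(cache$w)
  list(dx = dx, grads = list(w = dw))
}

# ---- depth-wise separable resampling, kernel 4 stride 2 --------------------

down_fwd <- function(x, p) {
  h <- cpp_dwconv3d_s2_fwd(x, dim(x), p$dw)
  dim(h) <- c(spatial_dim(x) %/% 2L, dim(x)[4])
  pw_out <- pw_fwd(h, p$pw, p$pb)
  list(y = pw_out$y, cache = list(x = x, dw = p$dw, pwc = pw_out$cache, hdim = dim(h)))
}

down_bwd <- function(dy, cache) {
  r1 <- pw_bwd(dy, cache$pwc)
  r2 <- cpp_dwconv3d_s2_bwd(cache$x, dim(cache$x), cache$dw, r1$dx)
  dx <- r2$dx; dim(dx) <- dim(cache$x)
  dwg <- r2$dw; dim(dwg) <- dim(cache$dw)
  list(dx = dx, grads = list(dw = dwg, pw = r1$grads$w, pb = r1$grads$b))
}

up_fwd <- function(x, p) {
  h <- cpp_dwconv3d_t2_fwd(x, dim(x), p$dw)
  dim(h) <- c(spatial_dim(x) * 2L, dim(x)[4])
  pw_out <- pw_fwd(h, p$pw, p$pb)
  list(y = pw_out$y, cache = list(x = x, dw = p$dw, pwc = pw_out$cache))
}

up_bwd <- function(dy, cache) {
  r1 <- pw_bwd(dy, cache$pwc)
  r2 <- cpp_dwconv3d_t2_bwd(cache$x, dim(cache$x), cache$dw, r1$dx)
  dx <- r2$dx; dim(dx) <- dim(cache$x)
  dwg <- r2$dw; dim(dwg) <- dim(cache$dw)
  list(dx = dx, grads = list(dw = dwg, pw = r1$grads$w, pb = r1$grads$b))
}

# ---- max pooling -----------------------------------------------------------

pool_fwd <- function(x, r) {
  out <- cpp_maxpool3d_fwd(x, dim(x), r)
  y <- out$y
  dim(y) <- c(spatial_dim(x) %/% r, dim(x)[4])
  list(y = y, cache = list(argmax = out$argmax, nx = length(x), xdim = dim(x)))
}

pool_bwd <- function(dy, cache) {
  dx <- cpp_maxpool3d_bwd(dy, cache$argmax, cache$nx)
  dim(dx) <- cache$xdim
  list(dx = dx)
}

# ---- per-voxel channel layer normalization ---------------------------------

ln_fwd <- function(x, g, b, eps = 1e-6) {
  sdim <- spatial_dim(x)
  xm <- as_mat(x)
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  ym <- sweep(xhat, 2L, g, "*")
  ym <- sweep(ym, 2L, b, "+")
  list(y = as_vol(ym, sdim),
       cache = list(xhat = xhat, istd = istd, g = g, sdim = sdim))
}

ln_bwd <- function(dy, cache) {
  dym <- as_mat(dy)
  C <- ncol(dym)
  dxhat <- sweep(dym, 2L, cache$g, "*")
  # dx = istd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dxm <- cache$istd * (dxhat - m1 - cache$xhat * m2)
  list(dx = as_vol(dxm, cache$sdim),
       grads = list(g = colSums(dym * cache$xhat), b = colSums(dym)))
}

# ---- GELU (exact, Gaussian CDF form) ---------------------------------------

gelu_fwd <- function(x) {
  ph <- stats::pnorm(x)
  list(y = x * ph, cache = list(x = x, ph = ph))
}

gelu_bwd <- function(dy, cache) {
  list(dx = dy * (cache$ph + cache$x * stats::dnorm(cache$x)))
}

# ---- multi-head channel-wise attention core --------------------------------
# Takes the already-projected Q, K (pooled, Vp x C as matrices) and V (Vf x C);
# per head: S = softmax_rows(alpha_h * Qh^T Kh)  [(C/h) x (C/h)], out = Vh S^T.

chan_attn_fwd <- function(qm, km, vm, alpha, heads, l2norm = FALSE) {
  C <- ncol(qm)
  cp <- C %/% heads
  if (l2norm) {
    qraw <- qm; kraw <- km
    qn <- sqrt(colSums(qm * qm)) + 1e-12
    kn <- sqrt(colSums(km * km)) + 1e-12
    qm <- sweep(qm, 2L, qn, "/")
    km <- sweep(km, 2L, kn, "/")
  }
  out <- matrix(0, nrow(vm), C)
  hc <- vector("list", heads)
  for (i in seq_len(heads)) {
    j <- ((i - 1) * cp + 1):(i * cp)
    logits <- alpha[i] * crossprod(qm[, j, drop = FALSE], km[, j, drop = FALSE])
    mx <- apply(logits, 1L, max)
    e <- exp(logits - mx)
    s <- e / rowSums(e)
    out[, j] <- vm[, j, drop = FALSE] %*% t(s)
    hc[[i]] <- list(j = j, s = s, logits0 = logits / alpha[i])
  }
  cache <- list(hc = hc, qm = qm, km = km, vm = vm, alpha = alpha,
                heads = heads, l2norm = l2norm)
  if (l2norm) cache[c("qn", "kn")] <- list(qn, kn)
  list(y = out, cache = cache)
}

chan_attn_bwd <- function(dout, cache) {
  dq <- matrix(0, nrow(cache$qm), ncol(cache$qm))
  dk <- dq
  dv <- matrix(0, nrow(cache$vm), ncol(cache$vm))
  dalpha <- numeric(cache$heads)
  for (i in seq_len(cache$heads)) {
    hcc <- cache$hc[[i]]
    j <- hcc$j
    s <- hcc$s
    vh <- cache$vm[, j, drop = FALSE]
    doh <- dout[, j, drop = FALSE]
    dv[, j] <- doh %*% s
    ds <- crossprod(doh, vh)          # dL/dS (out_h = Vh %*% t(S))
    # softmax backward per row
    dlog <- s * (ds - rowSums(ds * s))
    dalpha[i] <- sum(dlog * hcc$logits0)
    dlog <- dlog * cache$alpha[i]
    dq[, j] <- cache$km[, j, drop = FALSE] %*% t(dlog)
    dk[, j] <- cache$qm[, j, drop = FALSE] %*% dlog
  }
  if (cache$l2norm) {
    # qm here is the normalized matrix; undo x_hat = x / ||x|| columnwise
    dq <- sweep(dq - sweep(cache$qm, 2L, colSums(dq * cache$qm), "*"),
                2L, cache$qn, "/")
    dk <- sweep(dk - sweep(cache$km, 2L, colSums(dk * cache$km), "*"),
                2L, cache$kn, "/")
  }
  list(dq = dq, dk = dk, dv = dv, dalpha = dalpha)
}
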