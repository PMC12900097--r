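test_that("binary cross-entropy matches closed forms", {
  y <- array(rbinom(4^3 * 2, 1, 0.5), c(4, 4, 4, 2))
  p_half <- array(0.5, dim(y))
  expect_equal(bce_loss(p_half, y), log(2), tolerance = 1e-12)
  # perfect fit
  expect_lt(bce_loss(array(y, dim(y)), y), 1e-10)
  # hand arithmetic: p = (0.8, 0.3), y = (1, 0)
  p <- array(c(0.8, 0.3), c(2, 1, 1, 1))
  yy <- array(c(1, 0), c(2, 1, 1, 1))
  expect_equal(bce_loss(p, yy), mean(c(-log(0.8), -log(0.7))),
               tolerance = 1e-12)
  expect_equal(bce_loss(p, yy), 0.2899092, tolerance = 1e-6)
  expect_error(bce_loss(p_half, array(0, c(2, 2, 2, 2))), "shapes differ")
})

test_that("logit-form BCE agrees with the probability form and its gradient", {
  set.seed(40)
  z <- array(rnorm(4^3 * 2, sd = 3), c(4, 4, 4, 2))
  y <- array(rbinom(length(z), 1, 0.4), dim(z))
  lb <- bce_from_logits(z, y)
  expect_equal(lb$loss, bce_loss(1 / (1 + exp(-z)), y), tolerance = 1e-9)
  eps <- 1e-6
  for (i in sample(length(z), 5)) {
    zp <- z; zp[i] <- zp[i] + eps
    zm <- z; zm[i] <- zm[i] - eps
    num <- (bce_from_logits(zp, y)$loss - bce_from_logits(zm, y)$loss) / (2 * eps)
    expect_equal(lb$dlogits[i], num, tolerance = 1e-5)
  }
})

test_that("cosine annealing hits its endpoints and midpoint", {
  sched <- training_schedule()
  expect_equal(cosine_lr(0, 1000, sched), 3e-4)
  expect_equal(cosine_lr(1000, 1000, sched), 1e-6)
  expect_equal(cosine_lr(500, 1000, sched), (3e-4 + 1e-6) / 2)
  expect_error(cosine_lr(1001, 1000, sched), "step")
})

test_that("patch sampling is the identity crop when the patch fills the volume", {
  ph <- generate_phantom(phantom_spec(dims = c(16, 16, 16), n_tracts = 2,
                                      seed = 2))
  pat <- sample_patch(ph$peaks, ph$labels, 16)
  expect_identical(pat$peaks, ph$peaks$data)
  expect_identical(pat$labels, ph$labels$data)
  expect_error(sample_patch(ph$peaks, ph$labels, 32), "larger than volume")
})

test_that("patch sampling replays against an independent loop oracle", {
  ph <- generate_phantom(phantom_spec(seed = 5))
  lx <- ph$labels$data
  px <- ph$peaks$data
  sdim <- dim(px)[1:3]
  oracle <- function(p, min_fg = 0.001, retries = 10L) {
    chosen <- NULL
    for (i in seq_len(retries + 1L)) {
      corner <- vapply(1:3, function(ax)
        sample.int(sdim[ax] - p + 1L, 1L), integer(1))
      ix <- lapply(1:3, function(ax) corner[ax]:(corner[ax] + p - 1L))
      lp <- lx[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
      chosen <- list(ix = ix, lp = lp)
      if (mean(lp > 0) >= min_fg) break
    }
    list(peaks = px[chosen$ix[[1]], chosen$ix[[2]], chosen$ix[[3]], , drop = FALSE],
         labels = chosen$lp)
  }
  for (rep in 1:50) {
    seed <- 100 + rep
    set.seed(seed); got <- sample_patch(ph$peaks, ph$labels, 8)
    set.seed(seed); want <- oracle(8L)
    expect_identical(got, want)
  }
  # an all-foreground volume accepts the very first draw
  full <- tract_labels(array(1L, c(16, 16, 16, 1)))
  pk <- peak_volume(array(1, c(16, 16, 16, 9)))
  set.seed(1)
  first_corner <- vapply(1:3, function(ax) sample.int(16 - 8 + 1, 1), integer(1))
  set.seed(1)
  pat <- sample_patch(pk, full, 8)
  expect_equal(pat$labels[1, 1, 1, 1], 1L)
  expect_identical(pat$peaks[1, 1, 1, 1],
                   pk$data[first_corner[1], first_corner[2], first_corner[3], 1])
})

test_that("an empty schedule returns the network unchanged", {
  net <- build_network(tiny_config(), seed = 1)
  sched <- training_schedule(stages = list(
    list(patch_size = 8L, batch_size = 1L, epochs = 0L)),
    iterations_per_epoch = 10L)
  res <- run_training(net, list(generate_phantom(phantom_spec(
    dims = c(16, 16, 16), n_tracts = 2, seed = 1))), sched)
  expect_identical(res$net$params, net$params)
})

test_that("initial loss sits at the ln 2 sanity anchor", {
  cfg <- network_config(in_channels = 9L, out_channels = 6L,
                        level_channels = c(4L, 8L, 8L, 8L),
                        blocks_per_level = c(1L, 1L, 1L, 1L),
                        heads_per_level = c(1L, 2L, 2L, 2L),
                        ffn_expansion = 2, nominal_patch = 16L)
  net <- build_network(cfg, seed = 1)
  ph <- generate_phantom(phantom_spec(dims = c(16, 16, 16), n_tracts = 6,
                                      seed = 3))
  prob <- net_forward(net, ph$peaks)
  expect_lt(abs(bce_loss(prob, ph$labels$data) - log(2)), 0.1)
})

test_that("a gradient step with zero learning rate changes nothing", {
  cfg <- tiny_config()
  cfg$in_channels <- 9L; cfg$out_channels <- 2L
  net <- build_network(cfg, seed = 2)
  ph <- generate_phantom(phantom_spec(dims = c(16, 16, 16), n_tracts = 2,
                                      seed = 4))
  sched <- training_schedule(stages = list(
    list(patch_size = 16L, batch_size = 1L, epochs = 1L)),
    iterations_per_epoch = 1L, lr_start = 0, lr_end = 0, seed = 5)
  res <- run_training(net, list(ph), sched)
  expect_identical(res$net$params, net$params)
})

test_that("short runs are reproducible and log the stage curriculum", {
  cfg <- network_config(in_channels = 9L, out_channels = 2L,
                        level_channels = c(4L, 8L, 8L, 8L),
                        blocks_per_level = c(1L, 1L, 1L, 1L),
                        heads_per_level = c(1L, 2L, 2L, 2L),
                        ffn_expansion = 2, nominal_patch = 16L)
  ph <- generate_phantom(phantom_spec(dims = c(32, 32, 32), n_tracts = 2,
                                      seed = 6))
  sched <- training_schedule(stages = list(
    list(patch_size = 16L, batch_size = 1L, epochs = 1L),
    list(patch_size = 32L, batch_size = 2L, epochs = 1L)),
    iterations_per_epoch = 2L, seed = 7)
  r1 <- run_training(build_network(cfg, seed = 3), list(ph), sched)
  r2 <- run_training(build_network(cfg, seed = 3), list(ph), sched)
  expect_identical(r1$history$loss, r2$history$loss)
  expect_identical(r1$net$params, r2$net$params)
  # stage transition exactly as scheduled
  expect_equal(r1$history$patch_size, c(16, 16, 32, 32))
  expect_equal(r1$history$batch_size, c(1, 1, 2, 2))
  expect_equal(r1$history$stage, c(1, 1, 2, 2))
  # learning rate follows the cosine over the global step count
  expect_equal(r1$history$lr,
               sapply(0:3, cosine_lr, total_steps = 4, schedule = sched))
})
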