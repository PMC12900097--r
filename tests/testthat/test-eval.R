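test_that("Dice follows its closed forms and conventions", {
  m <- array(0L, c(5, 5, 5)); m[1:3, 1, 1] <- 1L
  expect_equal(dice_score(m, m), 1)
  # |pred| = 100, |gt| = 80, overlap 60 -> 2*60/180
  pred <- array(0L, c(10, 10, 10)); pred[1:100] <- 1L
  gt <- array(0L, c(10, 10, 10)); gt[41:120] <- 1L
  expect_equal(sum(pred), 100); expect_equal(sum(gt), 80)
  expect_equal(sum(pred & gt), 60)
  expect_equal(dice_score(pred, gt), 2 * 60 / 180)
  expect_equal(round(dice_score(pred, gt), 4), 0.6667)
  # empty-mask conventions
  z <- array(0L, c(4, 4, 4))
  expect_equal(dice_score(z, z), 1)
  expect_equal(dice_score(m[1:4, 1:4, 1:4], z), 0)
  expect_error(dice_score(z, array(0L, c(5, 5, 5))), "shapes differ")
})

test_that("Dice matches a voxel-loop oracle and is symmetric", {
  set.seed(50)
  for (i in 1:5) {
    a <- array(rbinom(216, 1, 0.3), c(6, 6, 6))
    b <- array(rbinom(216, 1, 0.3), c(6, 6, 6))
    inter <- 0; na <- 0; nb <- 0
    for (v in seq_along(a)) {
      inter <- inter + (a[v] == 1 && b[v] == 1)
      na <- na + (a[v] == 1); nb <- nb + (b[v] == 1)
    }
    expect_equal(dice_score(a, b), 2 * inter / (na + nb), tolerance = 1e-12)
    expect_equal(dice_score(a, b), dice_score(b, a))
  }
})

test_that("adding a voxel to both masks never decreases Dice", {
  set.seed(51)
  a <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
  b <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
  for (v in which(a == 0 & b == 0)) {
    a2 <- a; b2 <- b; a2[v] <- 1L; b2[v] <- 1L
    expect_gte(dice_score(a2, b2), dice_score(a, b))
  }
})

test_that("RVD follows its closed forms and is asymmetric", {
  pred <- array(0L, c(10, 10, 1)); pred[1:100] <- 1L
  gt <- array(0L, c(10, 10, 1)); gt[1:80] <- 1L
  expect_equal(rvd_score(gt, gt), 0)
  expect_equal(rvd_score(pred, gt), 20 / 80)
  expect_equal(rvd_score(array(0L, dim(gt)), gt), 1)
  expect_error(rvd_score(pred, array(0L, dim(gt))), "empty ground-truth")
  # asymmetry counterexample: 100 vs 80 -> 0.25, but 80 vs 100 -> 0.2
  expect_false(isTRUE(all.equal(rvd_score(pred, gt), rvd_score(gt, pred))))
})

test_that("signed-rank handles degenerate and textbook cases", {
  expect_warning(res <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(res$n_used, 0L)
  expect_equal(res$p_value, 1)
  # five all-positive differences: W- = 0, exact two-tailed p = 2/32
  res <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(res$n_used, 5L)
  expect_equal(res$p_value, 0.0625)
})

test_that("exact path equals full sign-pattern enumeration for n <= 10", {
  set.seed(52)
  for (n in c(3, 5, 7, 10)) {
    for (i in 1:3) {
      a <- rnorm(n)
      b <- rnorm(n)
      got <- wilcoxon_signed_rank(a, b)
      expect_equal(got$method, "exact")
      expect_equal(got$p_value, enumerate_signed_rank_p(a - b),
                   tolerance = 1e-12)
    }
  }
  # with ties in |d| (mid-ranks) the enumeration must still agree
  a <- c(3, 5, 2, 9, 7); b <- c(1, 3, 4, 2, 3)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value,
               enumerate_signed_rank_p(a - b), tolerance = 1e-12)
})

test_that("tie-free exact p agrees with the classical distribution", {
  set.seed(53)
  a <- runif(12); b <- runif(12)
  got <- wilcoxon_signed_rank(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("the approximation at the n = 26 boundary tracks the exact value", {
  set.seed(54)
  a <- rnorm(26, mean = 0.4)
  b <- rnorm(26)
  got <- wilcoxon_signed_rank(a, b)
  expect_equal(got$method, "normal-approximation")
  # independent exact reference (tie-free continuous data)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
  expect_lt(abs(got$p_value - ref), 0.005)
})

test_that("dataset evaluation aggregates per-pair metrics", {
  set.seed(55)
  gts <- lapply(1:2, function(i)
    tract_labels(array(rbinom(4^3 * 3, 1, 0.4), c(4, 4, 4, 3))))
  # perfect predictions
  ev <- evaluate_dataset(gts, gts)
  expect_equal(unname(ev$aggregates["mean_dsc"]), 1)
  expect_equal(unname(ev$aggregates["mean_rvd"]), 0)
  expect_equal(unname(ev$aggregates["sd_dsc"]), 0)
  expect_equal(nrow(ev$pairs), 6)

  # hand-computed aggregate over 2 subjects x 3 tracts
  preds <- lapply(gts, function(g) {
    d <- g$data
    d[1, 1, 1, ] <- 1L - d[1, 1, 1, ]   # flip one voxel in every tract
    tract_labels(d)
  })
  ev2 <- evaluate_dataset(preds, gts)
  hand <- mapply(function(p, g) sapply(1:3, function(t)
    dice_score(p$data[, , , t], g$data[, , , t])), preds, gts)
  expect_equal(unname(ev2$aggregates["mean_dsc"]), mean(hand))
  expect_equal(unname(ev2$aggregates["sd_dsc"]), sd(hand))
  # size table maps each tract's mean gt volume
  expect_equal(ev2$by_tract$mean_gt_volume,
               sapply(1:3, function(t) mean(sapply(gts, function(g)
                 sum(g$data[, , , t])))))
})

test_that("compare_predictions equals applying the test to the flat table", {
  set.seed(56)
  gts <- lapply(1:3, function(i)
    tract_labels(array(rbinom(4^3 * 2, 1, 0.4), c(4, 4, 4, 2))))
  perturb <- function(g, k) {
    d <- g$data
    idx <- sample(length(d), k)
    d[idx] <- 1L - d[idx]
    tract_labels(d)
  }
  pa <- lapply(gts, perturb, k = 4)
  pb <- lapply(gts, perturb, k = 12)
  ev_a <- evaluate_dataset(pa, gts)
  ev_b <- evaluate_dataset(pb, gts)
  got <- compare_predictions(ev_a, ev_b, "dsc")
  want <- wilcoxon_signed_rank(ev_a$pairs$dsc, ev_b$pairs$dsc)
  expect_equal(got$p_value, want$p_value)
  expect_equal(got$statistic, want$statistic)
})
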