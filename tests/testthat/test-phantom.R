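test_that("curve control points respect the radius margin", {
  spec <- phantom_spec(dims = c(32, 32, 32), radius_range = c(1, 1), seed = 1)
  set.seed(1)
  for (i in 1:20) {
    cv <- sample_tract_curve(spec)
    expect_true(all(cv$control_points >= 1 & cv$control_points <= 30))
  }
})

test_that("curve sampling is deterministic given the seed", {
  spec <- phantom_spec(seed = 7)
  set.seed(11); a <- sample_tract_curve(spec)
  set.seed(11); b <- sample_tract_curve(spec)
  expect_identical(a, b)
})

test_that("tube radii are uniform over the requested range", {
  spec <- phantom_spec(dims = c(64, 64, 64), radius_range = c(2, 4), seed = 1)
  set.seed(2)
  radii <- replicate(1000, sample_tract_curve(spec)$radius)
  expect_gte(min(radii), 2)
  expect_lte(max(radii), 4)
  # mean 3, sd of the mean = (2/sqrt(12))/sqrt(1000) ~ 0.018
  expect_lt(abs(mean(radii) - 3), 0.1)
})

test_that("a straight axis-aligned tube rasterizes as a cylinder", {
  cp <- cbind(seq(4, 24, length.out = 5), rep(8, 5), rep(8, 5))
  ras <- rasterize_tract(list(control_points = cp), 1.5, c(32, 32, 32))
  vox <- which(ras$mask, arr.ind = TRUE)
  expect_gt(nrow(vox), 0)
  # all tangents along +x
  for (i in seq_len(nrow(vox)))
    expect_equal(ras$tangent[vox[i, 1], vox[i, 2], vox[i, 3], ], c(1, 0, 0),
                 tolerance = 1e-6)
  # independent point-to-segment distance oracle over the whole grid
  seg_dist <- function(p) {
    t0 <- min(max((p[1] - 4) / 20, 0), 1)
    sqrt(sum((p - c(4 + 20 * t0, 8, 8))^2))
  }
  for (x in 0:31) for (y in 5:11) for (z in 5:11) {
    expected <- seg_dist(c(x, y, z)) <= 1.5
    expect_identical(ras$mask[x + 1, y + 1, z + 1], expected)
  }
})

test_that("a sub-voxel radius keeps only the traversed voxels", {
  cp <- cbind(seq(4, 24, length.out = 5), rep(8, 5), rep(8, 5))
  ras <- rasterize_tract(list(control_points = cp), 0.4, c(32, 32, 32))
  vox <- which(ras$mask, arr.ind = TRUE)
  # voxels on the line y=8, z=8 (1-based: 9, 9), x within the span
  expect_true(all(vox[, 2] == 9 & vox[, 3] == 9))
  expect_equal(sort(vox[, 1]), 5:25)
})

test_that("tangents on a circular arc are perpendicular to the radius", {
  theta <- seq(0, pi / 2, length.out = 9)
  center <- c(16, 16, 8)
  cp <- cbind(center[1] + 10 * cos(theta), center[2] + 10 * sin(theta),
              rep(8, 9))
  ras <- rasterize_tract(list(control_points = cp), 1.2, c(32, 32, 32))
  vox <- which(ras$mask, arr.ind = TRUE)
  # closed-form oracle applies away from the end caps, where the tube is
  # capped by spheres and the radius vector no longer lies on the arc
  ends <- rbind(cp[1, ], cp[9, ])
  interior <- apply(vox, 1, function(v)
    min(sqrt(rowSums(sweep(ends, 2, v - 1)^2))) > 1.2)
  expect_gt(sum(interior), 50)
  for (i in which(interior)) {
    tg <- ras$tangent[vox[i, 1], vox[i, 2], vox[i, 3], ]
    radial <- c(vox[i, 1] - 1 - center[1], vox[i, 2] - 1 - center[2], 0)
    radial <- radial / sqrt(sum(radial^2))
    expect_lt(abs(sum(tg * radial)), 0.15)
  }
})

test_that("single-tract noiseless phantoms fill only slot 1 at amplitude", {
  spec <- phantom_spec(n_tracts = 1, noise_sigma = 0, amplitude = 1.5, seed = 4)
  ph <- generate_phantom(spec)
  fg <- ph$labels$data[, , , 1] == 1
  expect_gt(sum(fg), 0)
  pk <- ph$peaks$data
  s1 <- sqrt(pk[, , , 1]^2 + pk[, , , 2]^2 + pk[, , , 3]^2)
  expect_true(all(abs(s1[fg] - 1.5) < 1e-6))
  expect_true(all(pk[, , , 4:9] == 0))
  expect_true(all(s1[!fg] == 0))
})

test_that("orthogonal crossing tracts encode orthogonal peak slots", {
  # two straight tubes through the volume center, along x and along y
  spec <- phantom_spec(dims = c(24, 24, 24), n_tracts = 2, noise_sigma = 0,
                       seed = 1)
  curves <- list(
    list(control_points = cbind(seq(3, 21, length.out = 5), rep(12, 5), rep(12, 5)),
         radius = 2),
    list(control_points = cbind(rep(12, 5), seq(3, 21, length.out = 5), rep(12, 5)),
         radius = 2))
  ph <- generate_phantom(spec, curves = curves)
  cross <- which(ph$labels$data[, , , 1] == 1 & ph$labels$data[, , , 2] == 1)
  expect_gt(length(cross), 0)
  pk <- ph$peaks$data
  nvox <- prod(spec$dims)
  for (v in cross) {
    s1 <- sapply(1:3, function(ax) pk[v + (ax - 1) * nvox])
    s2 <- sapply(1:3, function(ax) pk[v + (ax + 2) * nvox])
    s1 <- s1 / sqrt(sum(s1^2)); s2 <- s2 / sqrt(sum(s2^2))
    expect_lt(abs(sum(s1 * s2)), 0.1)
  }
})

test_that("phantom generation is bitwise deterministic given the seed", {
  a <- generate_phantom(phantom_spec(seed = 9))
  b <- generate_phantom(phantom_spec(seed = 9))
  expect_identical(a, b)
})

test_that("noiseless nonzero-slot counts equal min(3, covering tracts)", {
  ph <- generate_phantom(phantom_spec(n_tracts = 8, noise_sigma = 0, seed = 6))
  cover <- apply(ph$labels$data, 1:3, sum)
  pk <- ph$peaks$data
  slotn <- array(0L, dim(cover))
  for (s in 1:3) {
    mag <- sqrt(pk[, , , 3 * s - 2]^2 + pk[, , , 3 * s - 1]^2 + pk[, , , 3 * s]^2)
    slotn <- slotn + (mag > 1e-9)
  }
  expect_true(all(slotn == pmin(3L, cover)))
})

test_that("rasterized tract volume meets the analytic tube lower bound", {
  ph <- generate_phantom(phantom_spec(dims = c(48, 48, 48), n_tracts = 3,
                                      noise_sigma = 0, seed = 12))
  for (t in seq_along(ph$curves)) {
    cv <- ph$curves[[t]]
    len <- sum(sqrt(rowSums(diff(cv$control_points)^2)))   # chord lower bound
    analytic <- pi * cv$radius^2 * len
    expect_gte(sum(ph$labels$data[, , , t]), floor(0.5 * analytic))
  }
})

test_that("peak-major packing survives an unpack/re-pack round trip", {
  ph <- generate_phantom(phantom_spec(seed = 2))
  pk <- ph$peaks$data
  slots <- lapply(1:3, function(s) pk[, , , (3 * s - 2):(3 * s)])
  repacked <- array(0, dim(pk))
  for (s in 1:3) repacked[, , , (3 * s - 2):(3 * s)] <- slots[[s]]
  expect_identical(repacked, pk)
})
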