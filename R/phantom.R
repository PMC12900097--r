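# Synthetic crossing-tract phantoms.
#
# Each tract is a smooth tube: a Catmull-Rom spline (piecewise cubic, passing
# through uniformly sampled control points) swept with a constant radius. The
# voxelwise peak vectors follow the local tube tangent, so the phantom
# reproduces the input regime of peak-based tract segmentation: tubular,
# curving, mutually crossing bundles with up to three encoded directions per
# voxel.

#' Phantom specification
#'
#' Defaults define the package's reference synthetic conditions: a 32-voxel
#' cube with six crossing tracts, tube radii of 1.5-3 voxels, unit peak
#' amplitude and mild additive Gaussian noise on foreground peak components.
#'
#' @param dims three positive integers (voxels).
#' @param n_tracts number of tracts (label channels).
#' @param control_points_per_curve control points per tract curve (>= 4).
#' @param radius_range min/max tube radius in voxels (min >= 1).
#' @param noise_sigma standard deviation of additive Gaussian noise applied to
#'   every peak component of foreground voxels.
#' @param amplitude peak vector magnitude scale.
#' @param seed random seed making generation deterministic.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(32L, 32L, 32L),
                         n_tracts = 6L,
                         control_points_per_curve = 5L,
                         radius_range = c(1.5, 3),
                         noise_sigma = 0.05,
                         amplitude = 1,
                         seed = 1L) {
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  if (n_tracts < 1L) stop("n_tracts must be >= 1", call. = FALSE)
  if (control_points_per_curve < 4L)
    stop("control_points_per_curve must be >= 4", call. = FALSE)
  if (radius_range[1] < 1)
    stop("minimum tube radius must be >= 1 voxel", call. = FALSE)
  if (diff(radius_range) < 0) stop("radius_range must be ordered", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(dims = as.integer(dims), n_tracts = as.integer(n_tracts),
                 control_points_per_curve = as.integer(control_points_per_curve),
                 radius_range = as.numeric(radius_range),
                 noise_sigma = noise_sigma, amplitude = amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Catmull-Rom evaluation at parameter t in [0, n_segments]; control points are
# rows of cp; endpoint tangents use duplicated end points.
catmull_rom <- function(cp, tt) {
  n <- nrow(cp)
  ext <- rbind(cp[1, ], cp, cp[n, ])
  seg <- pmin(floor(tt), n - 2)
  u <- tt - seg
  p0 <- ext[seg + 1, , drop = FALSE]
  p1 <- ext[seg + 2, , drop = FALSE]
  p2 <- ext[seg + 3, , drop = FALSE]
  p3 <- ext[seg + 4, , drop = FALSE]
  u <- matrix(u, length(u), 3)
  pos <- 0.5 * ((2 * p1) + (-p0 + p2) * u +
                  (2 * p0 - 5 * p1 + 4 * p2 - p3) * u^2 +
                  (-p0 + 3 * p1 - 3 * p2 + p3) * u^3)
  der <- 0.5 * ((-p0 + p2) +
                  2 * (2 * p0 - 5 * p1 + 4 * p2 - p3) * u +
                  3 * (-p0 + 3 * p1 - 3 * p2 + p3) * u^2)
  list(pos = pos, der = der)
}

#' Sample a random tract curve
#'
#' Control points are uniform within the volume, inset by the sampled tube
#' radius on every axis so the rasterized tube stays inside; the radius is
#' uniform in `radius_range`.
#'
#' @param spec a [phantom_spec()].
#' @param rng optional function called as `rng(n)` returning n uniforms in
#'   \[0, 1\] (defaults to `runif`; pass a counted wrapper for reproducible
#'   sub-streams).
#' @return list with `control_points` (matrix, 0-based voxel coordinates) and
#'   `radius`.
#' @export
sample_tract_curve <- function(spec, rng = stats::runif) {
  r <- spec$radius_range[1] + diff(spec$radius_range) * rng(1)
  lo <- r
  hi <- spec$dims - 1 - r
  if (any(hi < lo))
    stop("volume dims too small to fit a tube of radius ", signif(r, 3),
         call. = FALSE)
  n <- spec$control_points_per_curve
  cp <- sapply(1:3, function(ax) lo + (hi[ax] - lo) * rng(n))
  # order along the dominant axis so curves sweep the volume instead of
  # zig-zagging
  span <- apply(cp, 2, function(v) diff(range(v)))
  cp <- cp[order(cp[, which.max(span)]), , drop = FALSE]
  list(control_points = cp, radius = r)
}

#' Rasterize a tube around a curve
#'
#' The curve is discretized at quarter-voxel steps; a voxel is set iff its
#' center lies within `radius` of the polyline, and its tangent is the
#' normalized curve derivative at the nearest sample.
#'
#' @param curve list with `control_points` as from [sample_tract_curve()], or
#'   a control-point matrix.
#' @param radius tube radius in voxels.
#' @param dims volume dimensions.
#' @return list with `mask` (logical 3D array) and `tangent` (`[H, W, D, 3]`,
#'   unit vectors on mask voxels, zero elsewhere).
#' @export
rasterize_tract <- function(curve, radius, dims) {
  cp <- if (is.list(curve)) curve$control_points else curve
  nseg <- nrow(cp) - 1
  # arc-length-ish parameter resolution: quarter-voxel steps
  approx_len <- sum(sqrt(rowSums(diff(cp)^2)))
  nsamp <- max(16L, ceiling(approx_len * 4))
  tt <- seq(0, nseg, length.out = nsamp)
  cr <- catmull_rom(cp, tt)
  dn <- sqrt(rowSums(cr$der^2))
  dn[dn < 1e-12] <- 1
  tang <- cr$der / dn
  mask <- array(FALSE, dims)
  best <- array(Inf, dims)
  tangent <- array(0, c(dims, 3))
  rw <- ceiling(radius)
  for (s in seq_len(nsamp)) {
    p <- cr$pos[s, ]
    i0 <- pmax(floor(p - rw), 0)
    i1 <- pmin(ceiling(p + rw), dims - 1)
    if (any(i1 < i0)) next
    gx <- i0[1]:i1[1]; gy <- i0[2]:i1[2]; gz <- i0[3]:i1[3]
    dx2 <- (gx - p[1])^2
    dy2 <- (gy - p[2])^2
    dz2 <- (gz - p[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    hit <- which(d2 <= radius^2 & d2 < best[gx + 1, gy + 1, gz + 1, drop = FALSE],
                 arr.ind = TRUE)
    if (nrow(hit) == 0) next
    vox <- cbind(gx[hit[, 1]] + 1, gy[hit[, 2]] + 1, gz[hit[, 3]] + 1)
    best[vox] <- d2[hit]
    mask[vox] <- TRUE
    for (ax in 1:3) tangent[cbind(vox, ax)] <- tang[s, ax]
  }
  list(mask = mask, tangent = tangent)
}

#' Generate a synthetic crossing-tract phantom
#'
#' Produces a paired peak volume and multi-label ground truth. At every voxel
#' the tangents of the covering tracts are written into peak slots 1..3 in
#' ascending tract-index order and scaled by `amplitude`; crossings beyond
#' three tracts keep their labels but only the three lowest tract indices
#' contribute peaks. Gaussian noise (`noise_sigma`) perturbs every peak
#' component of foreground voxels; background voxels are exactly zero.
#'
#' @param spec a [phantom_spec()].
#' @param curves optional list of `n_tracts` pre-specified curves
#'   (`control_points` + `radius`, as returned by [sample_tract_curve()]);
#'   when supplied they replace random curve sampling, which is useful for
#'   controlled crossing geometries.
#' @return object of class `phantom`: list with `peaks` (`peak_volume`),
#'   `labels` (`tract_labels`) and `curves` (per-tract provenance).
#' @export
generate_phantom <- function(spec, curves = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(curves) && length(curves) != spec$n_tracts)
    stop("curves must have one entry per tract", call. = FALSE)
  set.seed(spec$seed)
  dims <- spec$dims
  nt <- spec$n_tracts
  labels <- array(0L, c(dims, nt))
  peaks <- array(0, c(dims, 9))
  slot_used <- array(0L, dims)
  given <- curves
  curves <- vector("list", nt)
  for (t in seq_len(nt)) {
    cv <- if (is.null(given)) sample_tract_curve(spec) else given[[t]]
    ras <- rasterize_tract(cv, cv$radius, dims)
    curves[[t]] <- list(control_points = cv$control_points, radius = cv$radius)
    labels[, , , t] <- as.integer(ras$mask)
    vox <- which(ras$mask & slot_used < 3L)
    if (length(vox)) {
      slot <- slot_used[vox]            # 0-based slot for this tract
      nvox <- prod(dims)
      for (ax in 1:3) {
        ch <- slot * 3L + ax            # peak-major channel index (1-based)
        peaks[vox + (ch - 1L) * nvox] <-
          spec$amplitude * ras$tangent[vox + (ax - 1L) * nvox]
      }
      slot_used[vox] <- slot_used[vox] + 1L
    }
  }
  if (spec$noise_sigma > 0) {
    fg <- which(apply(labels > 0, c(1, 2, 3), any))
    nvox <- prod(dims)
    for (ch in 1:9) {
      idx <- fg + (ch - 1L) * nvox
      peaks[idx] <- peaks[idx] + stats::rnorm(length(fg), 0, spec$noise_sigma)
    }
  }
  structure(list(peaks = peak_volume(peaks),
                 labels = tract_labels(labels),
                 curves = curves, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("phantom:", paste(x$spec$dims, collapse = "x"), "voxels,",
      x$spec$n_tracts, "tracts, noise sd", x$spec$noise_sigma, "\n")
  invisible(x)
}
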