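# 4D volume containers and NIfTI I/O.
#
# Peak volumes hold 9 channels per voxel: three fiber-orientation peaks in
# peak-major layout (p1x, p1y, p1z, p2x, ..., p3z). Label volumes hold one
# binary channel per tract. All internal geometry is voxel-space (0-based);
# the affine is carried through I/O and crop/pad but never used in
# computation.

PEAK_CHANNELS <- 9L

default_affine <- function(spacing = c(1, 1, 1)) {
  a <- diag(4)
  diag(a)[1:3] <- spacing
  a
}

#' Peak volume container
#'
#' @param data numeric `[H, W, D, 9]` array of peak-vector components
#'   (peak-major channel layout), all finite.
#' @param spacing voxel size in mm per axis.
#' @param affine 4x4 voxel-to-world transform.
#' @return object of class `peak_volume`.
#' @export
peak_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 4L)
    stop("peak volume data must be a 4D array", call. = FALSE)
  if (dim(data)[4] != PEAK_CHANNELS)
    stop(sprintf("peak volume must have %d channels, got %d",
                 PEAK_CHANNELS, dim(data)[4]), call. = FALSE)
  if (!all(is.finite(data)))
    stop("peak volume contains non-finite values", call. = FALSE)
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  if (is.null(affine)) affine <- default_affine(spacing)
  structure(list(data = data, spacing = as.numeric(spacing), affine = affine),
            class = "peak_volume")
}

#' Multi-label tract mask container
#'
#' Channels are independent binary masks, so per-voxel channel sums may exceed
#' one where tracts cross.
#'
#' @param data `[H, W, D, T]` array with values in \{0, 1\}.
#' @param spacing,affine as in [peak_volume()].
#' @return object of class `tract_labels`.
#' @export
tract_labels <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 4L)
    stop("label data must be a 4D array", call. = FALSE)
  if (!all(data %in% c(0, 1)))
    stop("label data must be binary (0/1)", call. = FALSE)
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  if (is.null(affine)) affine <- default_affine(spacing)
  structure(list(data = array(as.integer(data), dim(data)),
                 spacing = as.numeric(spacing), affine = affine),
            class = "tract_labels")
}

#' @export
print.peak_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("peak_volume", paste(d[1:3], collapse = "x"), "voxels,",
      d[4], "channels (3 peaks x xyz),",
      sum(apply(x$data != 0, c(1, 2, 3), any)), "foreground voxels\n")
  invisible(x)
}

#' @export
print.tract_labels <- function(x, ...) {
  d <- dim(x$data)
  cat("tract_labels", paste(d[1:3], collapse = "x"), "voxels,",
      d[4], "tracts,", sum(x$data), "set voxel-labels\n")
  invisible(x)
}

read_nifti_4d <- function(path, allow_3d = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))   # strip image metadata attributes
  if (allow_3d && length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    stop("expected a 4D volume, got ", length(dim(data)), "D: ", path,
         call. = FALSE)
  list(data = data,
       spacing = RNifti::pixdim(img)[1:3],
       affine = unclass(RNifti::xform(img)))
}

write_nifti_4d <- function(data, spacing, affine, path, datatype) {
  attr(data, "pixdim") <- spacing
  img <- RNifti::asNifti(data, datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write fiber-orientation peak volumes
#'
#' Peaks are stored as 4D NIfTI with 9 channels in the 4th dimension
#' (peak-major layout) and 32-bit float data; gzip is handled transparently.
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @param peaks a `peak_volume`.
#' @return `read_peak_volume` returns a `peak_volume`.
#' @export
read_peak_volume <- function(path) {
  v <- read_nifti_4d(path)
  if (dim(v$data)[4] != PEAK_CHANNELS)
    stop(sprintf("peak volume must have %d channels, got %d: %s",
                 PEAK_CHANNELS, dim(v$data)[4], path), call. = FALSE)
  peak_volume(v$data, v$spacing, v$affine)
}

#' @rdname read_peak_volume
#' @export
write_peak_volume <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_volume"))
  write_nifti_4d(peaks$data, peaks$spacing, peaks$affine, path, "float")
}

#' Read / write multi-label tract masks
#'
#' Masks are stored as 4D NIfTI (one binary channel per tract) with 8-bit
#' unsigned integer data, so round-trips are exact.
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @param labels a `tract_labels` (or binary 4D array).
#' @return `read_label_volume` returns a `tract_labels`.
#' @export
read_label_volume <- function(path) {
  v <- read_nifti_4d(path)
  tract_labels(v$data, v$spacing, v$affine)
}

#' @rdname read_label_volume
#' @export
write_label_volume <- function(labels, path) {
  if (!inherits(labels, "tract_labels")) labels <- tract_labels(labels)
  write_nifti_4d(labels$data, labels$spacing, labels$affine, path, "uint8")
}

#' Stack per-tract 3D mask files into one multi-label volume
#'
#' Ground truth for tract segmentation is often shipped as one 3D binary mask
#' per tract; this loader stacks them along the channel axis in
#' filename-sorted order.
#'
#' @param paths character vector of 3D mask files, or a directory containing
#'   them.
#' @param pattern file pattern used when `paths` is a directory.
#' @return a `tract_labels` with one channel per input file.
#' @export
read_label_stack <- function(paths, pattern = "\\.nii(\\.gz)?$") {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = pattern, full.names = TRUE)
  if (length(paths) == 0L) stop("no label files found", call. = FALSE)
  paths <- sort(paths)
  vols <- lapply(paths, function(p) {
    v <- read_nifti_4d(p, allow_3d = TRUE)
    if (dim(v$data)[4] != 1L)
      stop("per-tract masks must be 3D: ", p, call. = FALSE)
    v
  })
  sdim <- dim(vols[[1]]$data)[1:3]
  arr <- array(0L, c(sdim, length(vols)))
  for (i in seq_along(vols)) {
    if (!all(dim(vols[[i]]$data)[1:3] == sdim))
      stop("per-tract masks disagree on spatial dimensions", call. = FALSE)
    arr[, , , i] <- vols[[i]]$data
  }
  tract_labels(arr, vols[[1]]$spacing, vols[[1]]$affine)
}

# centered crop start (0-based) for one axis: window of length t centered on c
crop_start <- function(center, target, n) {
  s <- round(center - (target - 1) / 2)
  min(max(s, 0), n - target)
}

#' Crop or pad a volume to target spatial dimensions
#'
#' Cropping is centered on the bounding box of nonzero voxels when one exists
#' (otherwise the volume center); padding is symmetric zero-fill. The affine
#' translation is updated so world coordinates of retained voxels are
#' preserved. A crop that discards nonzero voxels emits a warning but
#' proceeds.
#'
#' @param volume a `peak_volume` or `tract_labels`.
#' @param target_dims three positive integers.
#' @return a volume of the same class with the requested spatial dimensions.
#' @export
crop_or_pad <- function(volume, target_dims) {
  stopifnot(inherits(volume, "peak_volume") || inherits(volume, "tract_labels"))
  target_dims <- as.integer(target_dims)
  if (length(target_dims) != 3L || any(target_dims < 1L))
    stop("target_dims must be 3 positive integers", call. = FALSE)
  x <- volume$data
  sdim <- dim(x)[1:3]
  fg <- which(apply(x != 0, c(1, 2, 3), any), arr.ind = TRUE)
  centers <- if (nrow(fg) > 0) {
    (apply(fg, 2, min) + apply(fg, 2, max)) / 2 - 1   # 0-based bbox center
  } else {
    (sdim - 1) / 2
  }
  # voxel-space offset of the output origin relative to the input origin
  offset <- numeric(3)
  out <- x
  for (ax in 1:3) {
    n <- dim(out)[ax]
    t <- target_dims[ax]
    if (t < n) {
      s <- crop_start(centers[ax], t, n)
      idx <- (s + 1):(s + t)
      out <- switch(ax,
                    out[idx, , , , drop = FALSE],
                    out[, idx, , , drop = FALSE],
                    out[, , idx, , drop = FALSE])
      offset[ax] <- s
    } else if (t > n) {
      lo <- (t - n) %/% 2
      d2 <- dim(out); d2[ax] <- t
      padded <- array(0, d2)
      idx <- (lo + 1):(lo + n)
      switch(ax,
             padded[idx, , , ] <- out,
             padded[, idx, , ] <- out,
             padded[, , idx, ] <- out)
      out <- padded
      offset[ax] <- -lo
    }
  }
  if (nrow(fg) > 0 && sum(out != 0) < sum(x != 0))
    warning("crop_or_pad discarded nonzero voxels", call. = FALSE)
  affine <- volume$affine
  affine[1:3, 4] <- affine[1:3, 4] + affine[1:3, 1:3] %*% offset
  if (inherits(volume, "peak_volume")) {
    peak_volume(out, volume$spacing, affine)
  } else {
    tract_labels(out, volume$spacing, affine)
  }
}
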