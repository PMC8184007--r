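#' Resample an intensity volume to an isotropic grid
#'
#' Separable cubic-spline interpolation along each axis, reproducing the
#' standard conversion of anisotropic z-stacks (e.g. 200 nm plane spacing)
#' to an isotropically-distributed 3D coordinate grid. The physical extent
#' is preserved to within one voxel per axis.
#'
#' @param vol an [IntensityVolume-class].
#' @param target_pitch desired isotropic pitch in nm.
#' @return an [IntensityVolume-class] with equal spacing on all axes.
#' @export
resampleIsotropic <- function(vol, target_pitch) {
  stopifnot(target_pitch > 0)
  v <- voxelValues(vol)
  sp <- voxelSpacing(vol)
  d <- dim(v)
  for (ax in 1:3)
    if (target_pitch > (d[ax] - 1) * sp[ax] && d[ax] > 1)
      stop(sprintf("target pitch %g nm exceeds volume extent along axis %d",
                   target_pitch, ax))
  for (ax in 1:3) {
    if (abs(sp[ax] - target_pitch) < 1e-12) next
    old <- (seq_len(dim(v)[ax]) - 1) * sp[ax]
    newx <- seq(0, max(old), by = target_pitch)
    v <- .interpAxis(v, ax, old, newx)
  }
  IntensityVolume(v, rep(target_pitch, 3))
}

## cubic natural-spline interpolation of a 3D array along one axis
.interpAxis <- function(v, ax, old, newx) {
  if (length(old) == 1) return(v)   # single plane: nothing to interpolate
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  w <- aperm(v, perm)
  dw <- dim(w)
  m <- matrix(w, nrow = dw[1])
  out <- apply(m, 2, function(col)
    splinefun(old, col, method = "natural")(newx))
  out <- array(out, c(length(newx), dw[2], dw[3]))
  aperm(out, order(perm))
}

#' Threshold an intensity volume into a binary volume
#'
#' Occupancy is `value >= threshold`. Thresholds are caller-supplied on a
#' cell-by-cell, channel-by-channel basis; [otsuThreshold()] provides a
#' default for synthetic data.
#'
#' @param vol an [IntensityVolume-class] with isotropic spacing.
#' @param threshold finite scalar.
#' @return a [BinaryVolume-class].
#' @export
binarizeChannel <- function(vol, threshold) {
  stopifnot(is.finite(threshold))
  sp <- voxelSpacing(vol)
  if (diff(range(sp)) > 1e-9)
    stop("binarizeChannel requires an isotropic volume; resample first")
  BinaryVolume(voxelValues(vol) >= threshold, sp[1])
}

#' Otsu threshold of an intensity volume
#'
#' Maximizes between-class variance over a 256-bin histogram. Intended as a
#' convenience default for synthetic volumes; real channels should be
#' thresholded per cell by the caller.
#'
#' @param vol an [IntensityVolume-class].
#' @return scalar threshold on the intensity scale.
#' @export
otsuThreshold <- function(vol) {
  x <- as.vector(voxelValues(vol))
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(findInterval(x, seq(rng[1], rng[2], length.out = 257),
                             all.inside = TRUE), 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sigma <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma[!is.finite(sigma)] <- 0
  k <- which.max(sigma)
  rng[1] + (k / 256) * diff(rng)
}

#' 3x3x3 neighborhood occupancy filter
#'
#' Reproduces the segmentation clean-up of convolving a binary volume with a
#' uniform 3x3x3 kernel (values 1/27) and re-thresholding at (2/3)^3 = 8/27:
#' an occupied voxel is retained iff at least 8 voxels in its 3x3x3
#' neighborhood are occupied. By default the count includes the center voxel
#' (the literal kernel arithmetic); `include_center = FALSE` selects the
#' alternative reading of "8 occupied nearest neighbors" among the 26
#' neighbors only. Out-of-bounds neighbors count as empty. Output occupancy
#' is always a subset of the input.
#'
#' @param binary a [BinaryVolume-class].
#' @param min_count neighborhood occupancy cutoff (default 8).
#' @param include_center logical; count the center voxel itself?
#' @return a filtered [BinaryVolume-class].
#' @export
neighborFilter <- function(binary, min_count = 8L, include_center = TRUE) {
  occ <- occupancy(binary)
  cnt <- neighbor_count_cpp(as.vector(occ), dim(occ))
  cnt <- array(cnt, dim(occ))
  if (!include_center) cnt <- cnt - (occ * 1L)
  BinaryVolume(occ & (cnt >= min_count), pitch(binary))
}

#' Delete small connected components
#'
#' Removes 26-connected components with fewer than `min_voxels` voxels
#' (binary pixel-noise); components of exactly `min_voxels` are kept.
#'
#' @param binary a [BinaryVolume-class].
#' @param min_voxels minimum surviving component size (default 8, the
#'   neighborhood-filter scale).
#' @return a [BinaryVolume-class].
#' @export
removeSmallNoise <- function(binary, min_voxels = 8L) {
  stopifnot(min_voxels >= 1)
  occ <- occupancy(binary)
  lab <- labelComponents(binary)
  if (attr(lab, "n_labels") == 0) return(binary)
  sizes <- tabulate(lab[lab > 0], attr(lab, "n_labels"))
  keep <- which(sizes >= min_voxels)
  BinaryVolume(array(lab %in% keep, dim(occ)), pitch(binary))
}

#' Label 26-connected components
#'
#' @param binary a [BinaryVolume-class].
#' @return integer array of the same shape with labels dense from 1
#'   (0 = background) and attribute `n_labels`.
#' @export
labelComponents <- function(binary) {
  occ <- occupancy(binary)
  lab <- label3d_cpp(as.vector(occ), dim(occ))
  n <- attr(lab, "n_labels")
  lab <- array(lab, dim(occ))
  attr(lab, "n_labels") <- n
  lab
}

#' Full segmentation pipeline
#'
#' Fixed stage order: resample to isotropic pitch, binarize, neighborhood
#' filter, small-noise removal, component labeling.
#'
#' @param vol an [IntensityVolume-class].
#' @param threshold intensity threshold (scalar) or `NULL` for Otsu.
#' @param target_pitch isotropic pitch in nm.
#' @param min_voxels small-component cutoff.
#' @param include_center neighborhood-filter reading, see [neighborFilter()].
#' @return list with `binary` ([BinaryVolume-class]) and `labels` (integer
#'   array from [labelComponents()]).
#' @export
preprocessChannel <- function(vol, threshold = NULL, target_pitch = 25,
                              min_voxels = 8L, include_center = TRUE) {
  iso <- resampleIsotropic(vol, target_pitch)
  if (is.null(threshold)) threshold <- otsuThreshold(iso)
  bin <- binarizeChannel(iso, threshold)
  bin <- neighborFilter(bin, include_center = include_center)
  bin <- removeSmallNoise(bin, min_voxels)
  list(binary = bin, labels = labelComponents(bin))
}
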