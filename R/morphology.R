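# Grey-scale morphology and mask operations on (ny, nx, nz) arrays.
#
# Footprints follow the acquisition convention (y, x, z); entries are rounded
# up to the next odd integer so windows are centred.

footprint_radii <- function(footprint) {
  if (length(footprint) != 3L || any(footprint < 1))
    stop("'footprint' must be three positive sizes (y, x, z)")
  f <- as.integer(footprint)
  f <- ifelse(f %% 2L == 0L, f + 1L, f)    # round up to odd
  (f - 1L) %/% 2L
}

box_filter3d <- function(x, footprint, do_max) {
  assert_stack3d(x)
  r <- footprint_radii(footprint)
  d <- dim(x)
  if (any(2L * r + 1L > d))
    stop("footprint exceeds image extent on at least one axis")
  out <- x
  storage.mode(out) <- "double"
  for (axis in 0:2) {
    if (r[axis + 1L] == 0L) next
    out <- cpp_minmax_filter_axis(out, d, axis, r[axis + 1L], r[axis + 1L],
                                  do_max)
  }
  out
}

grey_erode3d  <- function(x, footprint) box_filter3d(x, footprint, FALSE)
grey_dilate3d <- function(x, footprint) box_filter3d(x, footprint, TRUE)

#' 3D white top-hat background subtraction
#'
#' Subtracts the grey-scale opening (erosion then dilation with an
#' axis-aligned box) from the image, removing background structure larger
#' than the footprint while preserving compact bright objects. The default
#' footprint is the pipeline's segmentation-channel setting.
#'
#' @param x 3D numeric array `(ny, nx, nz)`, non-negative intensities.
#' @param footprint box size `(y, x, z)` in voxels; even entries are rounded
#'   up to odd. Default `c(50, 50, 3)`.
#' @return array of the same shape; `0 <= out <= x` voxelwise.
#' @examples
#' x <- array(100, c(16, 16, 4))
#' max(abs(white_tophat_3d(x, c(5, 5, 3))))  # opening of a constant: 0
#' @export
white_tophat_3d <- function(x, footprint = c(50, 50, 3)) {
  assert_stack3d(x)
  if (min(x) < 0) stop("intensities must be non-negative")
  x - grey_dilate3d(grey_erode3d(x, footprint), footprint)
}

reflect_index <- function(j, n) {
  # half-sample symmetric reflection: a b c | c b a
  j <- ((j - 1) %% (2L * n))
  ifelse(j >= n, 2L * n - 1L - j, j) + 1L
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

convolve_axis <- function(x, kernel, axis) {
  d <- dim(x)
  n <- d[axis]
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, d)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  for (k in seq_along(kernel)) {
    off <- k - r - 1L
    src <- idx
    src[[axis]] <- reflect_index(idx[[axis]] + off, n)
    out <- out + kernel[k] * x[src[[1]], src[[2]], src[[3]], drop = FALSE]
  }
  out
}

#' Separable 3D Gaussian smoothing
#'
#' Convolves each axis with a normalized discrete Gaussian (radius
#' `ceiling(4 * sigma)`), with reflective boundary handling. A sigma of 0
#' leaves that axis untouched. Default is the pipeline's smoothing setting.
#'
#' @param x 3D numeric array `(ny, nx, nz)`.
#' @param sigma `(y, x, z)` standard deviations in voxels. Default
#'   `c(1, 1, 0.5)`.
#' @return smoothed array of the same shape; constants are preserved exactly.
#' @export
gaussian_smooth <- function(x, sigma = c(1, 1, 0.5)) {
  assert_stack3d(x)
  if (length(sigma) != 3L || any(sigma < 0))
    stop("'sigma' must be three non-negative values (y, x, z)")
  out <- x
  for (axis in 1:3) {
    if (sigma[axis] == 0) next
    out <- convolve_axis(out, gaussian_kernel1d(sigma[axis]), axis)
  }
  out
}

#' Threshold a preprocessed channel into a binary mask
#'
#' Foreground is every voxel with intensity greater than or equal to the
#' threshold (inclusive rule). The default grey value 500 is the pipeline's
#' segmentation setting for 16-bit data.
#'
#' @param x 3D numeric array.
#' @param threshold grey value; voxels `>= threshold` become foreground.
#' @return logical 3D array.
#' @export
binarize <- function(x, threshold = 500) {
  assert_stack3d(x)
  if (threshold < 0) stop("'threshold' must be non-negative")
  x >= threshold
}

#' Shrink a mask by its Euclidean distance transform
#'
#' Computes the exact 3D Euclidean distance of every foreground voxel to the
#' nearest background voxel (in voxel units, ignoring anisotropy; only
#' background voxels inside the volume count, so the array border is not
#' implicit background) and keeps only voxels with distance `>= edt_min`.
#' Slightly narrows each mask component; a 1-voxel-thick structure
#' disappears entirely at the default cutoff of 2.
#'
#' @param mask logical/integer 3D array.
#' @param edt_min minimum retained distance (voxels), default 2.
#' @param mode `"3d"` (default) for a volumetric transform or `"2d"` to
#'   compute the transform per slice.
#' @return logical 3D array, a subset of `mask`.
#' @export
edt_shrink <- function(mask, edt_min = 2, mode = c("3d", "2d")) {
  assert_stack3d(mask)
  mode <- match.arg(mode)
  if (edt_min <= 0) stop("'edt_min' must be positive")
  d <- dim(mask)
  m <- array(as.integer(mask != 0), d)
  if (mode == "3d") {
    dist2 <- cpp_edt3d_sq(m, d)
  } else {
    dist2 <- array(0, d)
    for (z in seq_len(d[3])) {
      sl <- cpp_edt3d_sq(array(m[, , z], c(d[1], d[2], 1L)), c(d[1], d[2], 1L))
      dist2[, , z] <- sl[, , 1L]
    }
  }
  array((dist2 >= edt_min^2) & (m == 1L), d)
}

#' Label 3D connected components
#'
#' Plain volumetric connected-component labelling, used as the baseline the
#' z-tracking segmentation is compared against: components fused through a
#' shared basal structure come out as a single label here.
#'
#' @param mask logical/integer 3D array.
#' @param connectivity 26 (default) or 6.
#' @return integer 3D array of labels, 0 = background.
#' @export
label_components_3d <- function(mask, connectivity = 26) {
  assert_stack3d(mask)
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  d <- dim(mask)
  cpp_label3d(array(as.integer(mask != 0), d), d, as.integer(connectivity))
}

# internal: label one slice in 2D
label_slice_2d <- function(slice, connectivity = 8) {
  cpp_label2d(matrix(as.integer(slice != 0), nrow(slice), ncol(slice)),
              nrow(slice), ncol(slice), as.integer(connectivity))
}
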