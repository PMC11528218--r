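# Synthetic confocal-like stacks with ground truth.
#
# Cells are drawn as flat-top ellipsoids (saturated nuclear reporter) with a
# ~1-voxel Gaussian edge falloff standing in for optical blur at the nominal
# cell boundary. A stack may include a basal structure spanning the last few
# slices — the shared central support-cell body the reporter also labels —
# into which the listed cells fuse. Background is a smooth intensity plane;
# noise is Poisson (scaled) plus Gaussian read noise.

#' Specify one synthetic cell
#'
#' @param center `(y, x, z)` voxel coordinates (1-based).
#' @param radii `(y, x, z)` ellipsoid radii in voxels, each >= 1.
#' @param peak peak intensity per channel (grey values); recycled to the
#'   number of channels in the stack spec.
#' @param edge_sigma Gaussian edge falloff in voxels outside the nominal
#'   boundary (default 1).
#' @return a list of class `CellSpec`.
#' @export
cell_spec <- function(center, radii, peak, edge_sigma = 1) {
  stopifnot(length(center) == 3L, length(radii) == 3L, all(radii >= 1),
            all(peak >= 0), edge_sigma >= 0)
  structure(list(center = as.numeric(center), radii = as.numeric(radii),
                 peak = as.numeric(peak), edge_sigma = edge_sigma),
            class = "CellSpec")
}

#' Specify the fused basal structure
#'
#' An elliptical disc spanning `z_extent` slices at the end of the default
#' traversal (the highest z indices, i.e. the bottom of the stack), with a
#' lateral footprint wide enough that the listed cells merge into it.
#'
#' @param center_yx lateral `(y, x)` centre in voxels.
#' @param radii_yx lateral `(y, x)` radii in voxels.
#' @param z_extent number of slices occupied (default 3).
#' @param intensity intensity per channel (grey values).
#' @param at_end logical; `TRUE` (default) puts the structure at the highest
#'   z indices, `FALSE` at the lowest.
#' @return a list of class `BaseSpec`.
#' @export
base_spec <- function(center_yx, radii_yx, z_extent = 3, intensity = 2000,
                      at_end = TRUE) {
  stopifnot(length(center_yx) == 2L, length(radii_yx) == 2L,
            all(radii_yx >= 1), z_extent >= 1, all(intensity >= 0))
  structure(list(center_yx = as.numeric(center_yx),
                 radii_yx = as.numeric(radii_yx),
                 z_extent = as.integer(z_extent),
                 intensity = as.numeric(intensity),
                 at_end = isTRUE(at_end)),
            class = "BaseSpec")
}

#' Specify the stack noise model
#'
#' Intensity variance follows `poisson_scale * signal + read_sd^2`
#' (shot noise on photon counts plus additive detector read noise).
#'
#' @param poisson_scale grey values per photon equivalent (0 = no shot
#'   noise). Default 60.
#' @param read_sd Gaussian read-noise standard deviation in grey values.
#'   Default 80.
#' @return a list of class `NoiseSpec`.
#' @export
noise_spec <- function(poisson_scale = 60, read_sd = 80) {
  stopifnot(poisson_scale >= 0, read_sd >= 0)
  structure(list(poisson_scale = poisson_scale, read_sd = read_sd),
            class = "NoiseSpec")
}

#' Specify a synthetic stack
#'
#' @param shape `(ny, nx, nz)` voxel counts.
#' @param cells list of [cell_spec()] objects.
#' @param base optional [base_spec()]; when present every cell must overlap
#'   it by at least one voxel (they fuse into it).
#' @param background per-channel plane coefficients
#'   `c(offset, per_y, per_x, per_z)` in grey values (a list with one entry
#'   per channel, or one vector recycled). Default `c(40, 0.3, 0.3, 0)`, a
#'   dim smooth plane well below the segmentation threshold.
#' @param noise a [noise_spec()].
#' @param channels channel names; the first is the segmentation reporter.
#' @param bit_depth intensity ceiling `2^bit_depth - 1` (default 16).
#' @param voxel_size optional `(y, x, z)` micrometre spacing (default
#'   `c(0.3, 0.3, 0.9)`, a typical 3:1 anisotropic confocal sampling).
#' @return a list of class `StackSpec`.
#' @export
stack_spec <- function(shape, cells, base = NULL,
                       background = c(40, 0.3, 0.3, 0),
                       noise = noise_spec(),
                       channels = "reporter",
                       bit_depth = 16L,
                       voxel_size = c(0.3, 0.3, 0.9)) {
  stopifnot(length(shape) == 3L, all(shape >= 1), length(channels) >= 1)
  if (!is.list(cells)) cells <- list(cells)
  if (!all(vapply(cells, inherits, TRUE, "CellSpec")))
    stop("'cells' must be a list of cell_spec() objects")
  if (!is.list(background)) background <- rep(list(background), length(channels))
  if (length(background) != length(channels))
    stop("one background coefficient vector per channel required")
  ceiling_val <- 2^bit_depth - 1
  for (cl in cells) {
    if (any(cl$peak > ceiling_val))
      stop("peak intensity exceeds bit-depth ceiling")
    if (any(cl$center < 1) || any(cl$center > shape))
      stop("cell centre outside the stack")
  }
  structure(list(shape = as.integer(shape), cells = cells, base = base,
                 background = background, noise = noise,
                 channels = channels, bit_depth = as.integer(bit_depth),
                 voxel_size = voxel_size),
            class = "StackSpec")
}

# normalized ellipsoid coordinate e and approximate Euclidean distance to the
# e = 1 surface, evaluated on coordinate arrays
ellipsoid_profile <- function(spec, Y, X, Z) {
  ey <- (Y - spec$center[1]) / spec$radii[1]
  ex <- (X - spec$center[2]) / spec$radii[2]
  ez <- (Z - spec$center[3]) / spec$radii[3]
  e <- sqrt(ey^2 + ex^2 + ez^2)
  prof <- array(0, dim(e))
  inside <- e <= 1
  prof[inside] <- 1
  out <- which(e > 1)
  if (length(out) && spec$edge_sigma > 0) {
    # |grad e| gives the local voxel-per-unit-e scale
    ge <- sqrt((ey[out] / spec$radii[1])^2 + (ex[out] / spec$radii[2])^2 +
                 (ez[out] / spec$radii[3])^2) / pmax(e[out], 1e-12)
    dist_vox <- (e[out] - 1) / pmax(ge, 1e-12)
    prof[out] <- exp(-dist_vox^2 / (2 * spec$edge_sigma^2))
  }
  prof
}

base_support <- function(base, shape) {
  zs <- if (base$at_end) (shape[3] - base$z_extent + 1L):shape[3]
        else seq_len(base$z_extent)
  Y <- array(rep(seq_len(shape[1]), times = shape[2]), shape[1:2])
  X <- array(rep(seq_len(shape[2]), each = shape[1]), shape[1:2])
  disc <- ((Y - base$center_yx[1]) / base$radii_yx[1])^2 +
    ((X - base$center_yx[2]) / base$radii_yx[2])^2 <= 1
  list(zs = zs, disc = disc)
}

coord_arrays <- function(shape) {
  list(Y = array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), shape),
       X = array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
                 shape),
       Z = array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), shape))
}

#' Generate a ground-truthed synthetic stack
#'
#' Draws the noiseless scene (sum of cell profiles, basal structure and
#' background plane per channel), computes the ground truth on the noiseless
#' geometry, then corrupts the scene with scaled-Poisson shot noise and
#' Gaussian read noise and clips to the bit-depth ceiling. Identical
#' `(spec, seed)` give bit-identical output.
#'
#' @param spec a [stack_spec()].
#' @param seed integer RNG seed.
#' @return list with elements
#'   \describe{
#'     \item{stack}{a [multi_channel_stack()]}
#'     \item{truth}{a `GroundTruth` list: `instance_labels` (integer array;
#'       cells 1..n, basal structure n+1), `base_id` (or `NA`), `centroids`
#'       (matrix, one `(y, x, z)` row per cell), `true_means` (cells x
#'       channels matrix of noiseless signal means), `merge_z` (first
#'       traversal slice at which two cells share a 2D connected component;
#'       `NA` without a basal structure), `noiseless` (list of per-channel
#'       signal arrays, background excluded)}
#'   }
#' @export
generate_stack <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "StackSpec"))
  shape <- spec$shape
  nch <- length(spec$channels)
  co <- coord_arrays(shape)
  ncell <- length(spec$cells)

  # truth instance labels: flat-top supports; cells take precedence over base
  labels <- array(0L, shape)
  supports <- vector("list", ncell)
  profiles <- vector("list", ncell)
  for (i in seq_len(ncell)) {
    profiles[[i]] <- ellipsoid_profile(spec$cells[[i]], co$Y, co$X, co$Z)
    supports[[i]] <- profiles[[i]] >= 1
  }
  for (i in seq_len(ncell))
    for (j in seq_len(ncell))
      if (i < j && any(supports[[i]] & supports[[j]]))
        stop(sprintf("cells %d and %d overlap; truth labels would be ambiguous",
                     i, j))
  base_id <- NA_integer_
  if (!is.null(spec$base)) {
    bs <- base_support(spec$base, shape)
    base_mask <- array(FALSE, shape)
    for (z in bs$zs) base_mask[, , z] <- bs$disc
    base_id <- ncell + 1L
    labels[base_mask] <- base_id
    for (i in seq_len(ncell)) {
      if (!any(supports[[i]] & base_mask))
        stop(sprintf("cell %d does not overlap the basal structure", i))
    }
  }
  for (i in seq_len(ncell)) labels[supports[[i]]] <- i

  # noiseless per-channel signal (no background)
  signal <- vector("list", nch)
  for (ch in seq_len(nch)) {
    s <- array(0, shape)
    for (i in seq_len(ncell)) {
      pk <- rep(spec$cells[[i]]$peak, length.out = nch)[ch]
      s <- s + pk * profiles[[i]]
    }
    if (!is.null(spec$base)) {
      bi <- rep(spec$base$intensity, length.out = nch)[ch]
      if (bi > 0) {
        bs <- base_support(spec$base, shape)
        for (z in bs$zs) s[, , z] <- s[, , z] + bi * bs$disc
      }
    }
    signal[[ch]] <- s
  }

  centroids <- t(vapply(seq_len(ncell), function(i) {
    w <- which(supports[[i]], arr.ind = TRUE)
    colMeans(w)
  }, numeric(3)))
  colnames(centroids) <- c("y", "x", "z")
  true_means <- matrix(0, ncell, nch,
                       dimnames = list(NULL, spec$channels))
  for (i in seq_len(ncell))
    for (ch in seq_len(nch))
      true_means[i, ch] <- mean(signal[[ch]][supports[[i]]])

  merge_z <- NA_integer_
  if (!is.null(spec$base) && ncell >= 2) {
    for (z in seq_len(shape[3])) {
      sl <- labels[, , z]
      comp <- label_slice_2d(sl > 0, 8)
      for (ci in seq_len(max(comp))) {
        ids <- unique(sl[comp == ci])
        ids <- ids[ids >= 1 & ids <= ncell]
        if (length(ids) >= 2) { merge_z <- z; break }
      }
      if (!is.na(merge_z)) break
    }
  }

  # corrupt with noise, per channel, under a locally-seeded RNG
  channels <- vector("list", nch)
  names(channels) <- spec$channels
  ceiling_val <- 2^spec$bit_depth - 1
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (ch in seq_len(nch)) {
    bgc <- spec$background[[ch]]
    bg <- bgc[1] + bgc[2] * co$Y + bgc[3] * co$X + bgc[4] * co$Z
    clean <- signal[[ch]] + bg
    ns <- spec$noise
    if (ns$poisson_scale > 0) {
      noisy <- ns$poisson_scale *
        array(rpois(length(clean), clean / ns$poisson_scale), shape)
    } else noisy <- clean
    if (ns$read_sd > 0)
      noisy <- noisy + array(rnorm(length(clean), 0, ns$read_sd), shape)
    channels[[ch]] <- array(pmin(pmax(noisy, 0), ceiling_val), shape)
  }

  stack <- multi_channel_stack(channels,
                               roles = c("segmentation",
                                         rep("measurement", nch - 1L)),
                               voxel_size = spec$voxel_size,
                               bit_depth = spec$bit_depth)
  truth <- structure(list(instance_labels = labels, base_id = base_id,
                          centroids = centroids, true_means = true_means,
                          merge_z = merge_z, noiseless = signal),
                     class = "GroundTruth")
  list(stack = stack, truth = truth)
}

#' Generate a two-cell stack with a known intensity asymmetry
#'
#' Builds a stack containing one sibling-cell pair: a reporter channel with
#' equal peaks (for segmentation) and a `signal` channel whose two cells
#' differ in noiseless mean intensity by exactly `ratio`. Used to validate
#' the raw paired asymmetry measurement.
#'
#' @param ratio true high/low mean-intensity ratio (> 0).
#' @param seed integer RNG seed.
#' @param shape stack shape, default `c(48, 48, 9)`.
#' @param peak_high peak of the brighter cell in the signal channel.
#' @param noise a [noise_spec()]; default moderate confocal noise.
#' @param background per-channel background coefficients as in
#'   [stack_spec()]; default none (paired measurements are taken raw).
#' @return as [generate_stack()]; cell 1 is the brighter one.
#' @export
generate_pair_stack <- function(ratio, seed = 1L, shape = c(48, 48, 9),
                                peak_high = 3000,
                                noise = noise_spec(30, 40),
                                background = c(0, 0, 0, 0)) {
  stopifnot(ratio > 0)
  zc <- ceiling(shape[3] / 2)
  radii <- c(5, 5, 2.5)
  c1 <- c(shape[1] / 2, shape[2] / 3, zc)
  c2 <- c(shape[1] / 2, 2 * shape[2] / 3, zc)
  cells <- list(
    cell_spec(c1, radii, peak = c(3000, peak_high)),
    cell_spec(c2, radii, peak = c(3000, peak_high / ratio))
  )
  spec <- stack_spec(shape, cells, background = background, noise = noise,
                     channels = c("reporter", "signal"))
  generate_stack(spec, seed)
}

#' Generate a random merge-free blob mask
#'
#' Draws well-separated random ellipsoidal blobs, for exercising the
#' z-tracking segmentation in the regime where it must agree with plain 3D
#' connected components (no merges).
#'
#' @param shape `(ny, nx, nz)`.
#' @param n_blobs number of blobs to place.
#' @param radius_range lateral radius range in voxels; the z radius is drawn
#'   from `radius_range / 2` (anisotropic sampling).
#' @param seed integer RNG seed.
#' @param margin minimum gap (voxels) between blob bounding ellipsoids.
#' @return logical 3D array.
#' @export
generate_blob_mask <- function(shape, n_blobs = 3, radius_range = c(3, 6),
                               seed = 1L, margin = 2) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  centers <- matrix(0, 0, 3)
  radii <- matrix(0, 0, 3)
  tries <- 0
  while (nrow(centers) < n_blobs && tries < 2000) {
    tries <- tries + 1
    r_lat <- runif(1, radius_range[1], radius_range[2])
    r <- c(r_lat, runif(1, radius_range[1], radius_range[2]), r_lat / 2)
    ctr <- c(runif(1, r[1] + 1, shape[1] - r[1]),
             runif(1, r[2] + 1, shape[2] - r[2]),
             runif(1, r[3] + 1, shape[3] - r[3]))
    ok <- TRUE
    if (nrow(centers) > 0) {
      for (i in seq_len(nrow(centers))) {
        gap <- sqrt(sum((centers[i, ] - ctr)^2)) -
          max(radii[i, ]) - max(r) - margin
        if (gap < 0) { ok <- FALSE; break }
      }
    }
    if (ok) { centers <- rbind(centers, ctr); radii <- rbind(radii, r) }
  }
  co <- coord_arrays(shape)
  mask <- array(FALSE, shape)
  for (i in seq_len(nrow(centers))) {
    e <- ((co$Y - centers[i, 1]) / radii[i, 1])^2 +
      ((co$X - centers[i, 2]) / radii[i, 2])^2 +
      ((co$Z - centers[i, 3]) / radii[i, 3])^2
    mask <- mask | (e <= 1)
  }
  mask
}

#' Random multi-cell stack specification
#'
#' Places `n_cells` non-overlapping ellipsoidal cells at random positions
#' (no basal structure), for segmentation ground-truth recovery
#' experiments. Cell geometry and intensities follow the generator defaults:
#' lateral radii 5-6.5 voxels and 2.5-3 in z (nuclei just under the
#' measurement top-hat footprint), peaks 2000-2600 grey values — about four
#' to five times the segmentation threshold, so the smoothed-threshold
#' dilation and the EDT trim roughly cancel — over a dim background plane,
#' with shot plus read noise giving a peak SNR above 5.
#'
#' @param shape `(ny, nx, nz)`, default `c(128, 128, 20)`.
#' @param n_cells number of cells.
#' @param seed integer RNG seed (placement only).
#' @param noise a [noise_spec()].
#' @return a [stack_spec()].
#' @export
random_stack_spec <- function(shape = c(128, 128, 20), n_cells = 3,
                              seed = 1L, noise = noise_spec(40, 60)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cells <- list()
  centers <- matrix(0, 0, 3)
  tries <- 0
  while (length(cells) < n_cells && tries < 5000) {
    tries <- tries + 1
    r <- c(runif(1, 5, 6.5), runif(1, 5, 6.5), runif(1, 2.5, 3))
    ctr <- c(runif(1, r[1] + 4, shape[1] - r[1] - 4),
             runif(1, r[2] + 4, shape[2] - r[2] - 4),
             runif(1, r[3] + 2.5, shape[3] - r[3] - 2.5))
    if (nrow(centers) == 0 ||
        all(sqrt(colSums((t(centers) - ctr)^2)) > 2 * max(r) + 6)) {
      centers <- rbind(centers, ctr)
      cells[[length(cells) + 1L]] <-
        cell_spec(ctr, r, peak = runif(1, 2000, 2600))
    }
  }
  if (length(cells) < n_cells)
    stop("could not place ", n_cells, " non-overlapping cells")
  stack_spec(shape, cells, noise = noise)
}

#' Simulate paired sibling-cell intensity measurements
#'
#' A lightweight measurement-level twin of [generate_pair_stack()] plus
#' quantification, for Monte-Carlo power and type-I studies: each pair
#' shares a lognormal image brightness factor, the two cells differ by the
#' true ratio, and each measured mean carries multiplicative lognormal
#' measurement noise of coefficient of variation about `cv`.
#'
#' @param n_pairs number of pairs (one row each).
#' @param ratio true high/low mean-intensity ratio.
#' @param cv per-cell measurement coefficient of variation (default 0.2).
#' @param between_sd lognormal sd of the shared per-image brightness
#'   (default 0.4).
#' @param base_intensity median cell intensity in grey values.
#' @param seed integer RNG seed.
#' @return data frame: `image_id`, `cell_a`, `cell_b` (measured mean
#'   intensities; the truly brighter cell is randomly `a` or `b`) and
#'   `high_is` (`"a"` or `"b"`): which cell the independent reporter marker
#'   designates as the high one. Orienting pairs by `high_is` reproduces the
#'   matched-pairs comparison; under `ratio = 1` the designation is
#'   arbitrary.
#' @export
simulate_pair_measurements <- function(n_pairs, ratio, cv = 0.2,
                                       between_sd = 0.4,
                                       base_intensity = 1000, seed = 1L) {
  stopifnot(n_pairs >= 1, ratio > 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  bright <- base_intensity * rlnorm(n_pairs, 0, between_sd)
  hi <- bright * sqrt(ratio) * rlnorm(n_pairs, 0, sqrt(log(1 + cv^2)))
  lo <- bright / sqrt(ratio) * rlnorm(n_pairs, 0, sqrt(log(1 + cv^2)))
  flip <- runif(n_pairs) < 0.5
  data.frame(image_id = seq_len(n_pairs),
             cell_a = ifelse(flip, lo, hi),
             cell_b = ifelse(flip, hi, lo),
             high_is = ifelse(flip, "b", "a"),
             stringsAsFactors = FALSE)
}
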