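# Per-cell and per-ROI fluorescence quantification. Three measurement
# dialects coexist, mirroring how the imaging data are analysed:
#  * 3D: mean intensity of each segmented cell in top-hat-subtracted
#    measurement channels;
#  * 2D interactive-style: max projection, rolling-ball background
#    subtraction, ROI means;
#  * raw paired: brightest-slice (or up-to-3-slice projection) measurements
#    with NO background subtraction, compared pairwise within an image.
# Quantification always runs on raw or explicitly-subtracted data; no gamma
# parameter exists anywhere in this module (display gamma never reaches
# measurement).

#' Top-hat background subtraction for measurement channels
#'
#' [white_tophat_3d()] with the measurement-channel footprint
#' `(15, 15, 1)`: background is removed per slice laterally with no mixing
#' across z.
#'
#' @param x 3D numeric array.
#' @param footprint `(y, x, z)` box, default `c(15, 15, 1)`.
#' @return background-subtracted array, `0 <= out <= x`.
#' @export
tophat_bg_subtract <- function(x, footprint = c(15, 15, 1)) {
  white_tophat_3d(x, footprint)
}

#' Mean intensity of each segmented cell
#'
#' For every label, the arithmetic mean of each channel over the cell's
#' voxels. Channels are taken as given: apply [tophat_bg_subtract()] first
#' for background-subtracted means, or pass raw channels for raw means.
#'
#' @param labels a `SegmentationResult`, or an integer 3D label array
#'   (0 = background).
#' @param channels a [multi_channel_stack()], a named list of 3D arrays, or
#'   one 3D array.
#' @param cell_ids labels to measure; default all labels present. A
#'   requested label absent from the volume is an error.
#' @return data frame of class `CellMeasurement`: `cell_id`, `channel`,
#'   `mean_intensity`, `n_voxels`, `source`.
#' @export
cell_mean_intensities <- function(labels, channels, cell_ids = NULL) {
  lab <- if (inherits(labels, "SegmentationResult")) labels$labels else labels
  assert_stack3d(lab)
  chans <- if (inherits(channels, "MultiChannelStack")) channels$channels
           else if (is.list(channels)) channels
           else list(signal = channels)
  if (is.null(names(chans)) || any(!nzchar(names(chans))))
    names(chans) <- paste0("ch", seq_along(chans))
  for (ch in chans) {
    assert_stack3d(ch)
    if (!identical(dim(ch), dim(lab)))
      stop("labels and channels must share one shape")
  }
  present <- sort(unique(lab[lab > 0]))
  if (is.null(cell_ids)) cell_ids <- present
  missing_ids <- setdiff(cell_ids, present)
  if (length(missing_ids))
    stop("label(s) absent from volume: ", paste(missing_ids, collapse = ", "))
  rows <- list()
  fl <- as.vector(lab)
  for (chname in names(chans)) {
    v <- as.vector(chans[[chname]])
    means <- vapply(cell_ids, function(id) mean(v[fl == id]), 0)
    ns <- vapply(cell_ids, function(id) sum(fl == id), 0L)
    rows[[chname]] <- data.frame(cell_id = cell_ids, channel = chname,
                                 mean_intensity = means, n_voxels = ns,
                                 source = "label3d", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("CellMeasurement", "data.frame")
  out
}

#' Maximum intensity projection along z
#'
#' @param x 3D numeric array `(ny, nx, nz)` or a [multi_channel_stack()]
#'   channel.
#' @return 2D matrix of voxelwise maxima.
#' @export
max_projection <- function(x) {
  if (inherits(x, "MultiChannelStack")) x <- get_channel(x, "segmentation")
  assert_stack3d(x)
  apply(x, c(1, 2), max)
}

#' Rolling-ball background subtraction
#'
#' Estimates the background of a 2D image as the grey-scale opening with a
#' ball-shaped (spherical-cap) structuring element of the given radius and
#' subtracts it, clipping at zero. Large smooth background is removed;
#' features much smaller than the ball survive nearly unchanged.
#'
#' @param img 2D non-negative numeric matrix.
#' @param radius ball radius in pixels, default 50.
#' @return background-subtracted matrix, everywhere `>= 0`.
#' @export
rolling_ball_subtract <- function(img, radius = 50) {
  if (!is.matrix(img)) stop("'img' must be a 2D matrix")
  if (radius <= 0) stop("'radius' must be positive")
  if (min(img) < 0) stop("intensities must be non-negative")
  bg <- cpp_ball_morph2d(cpp_ball_morph2d(img, radius, FALSE), radius, TRUE)
  pmax(img - bg, 0)
}

#' Mean intensity within a region of interest
#'
#' @param img 2D numeric matrix.
#' @param roi logical matrix of the same shape (the drawn ROI).
#' @return mean intensity over the ROI pixels.
#' @export
roi_mean <- function(img, roi) {
  if (!is.matrix(img) || !identical(dim(img), dim(roi)))
    stop("'img' and 'roi' must be matrices of the same shape")
  if (!any(roi)) stop("empty ROI")
  mean(img[roi])
}

#' Projection of the brightest slice(s)
#'
#' Ranks slices by total intensity (within the ROI when one is given) and
#' returns the maximum projection of the top `k` (k = 1: the brightest
#' slice itself). Used for raw paired measurements; no background
#' subtraction is applied here or downstream.
#'
#' @param x 3D numeric array or [multi_channel_stack()] channel.
#' @param k number of brightest slices, 1 (default), 2 or 3.
#' @param roi optional logical matrix `(ny, nx)` restricting the ranking
#'   criterion (the projection itself covers the full frame).
#' @return 2D matrix.
#' @export
brightest_substack_projection <- function(x, k = 1, roi = NULL) {
  if (inherits(x, "MultiChannelStack")) x <- get_channel(x, "segmentation")
  assert_stack3d(x)
  if (!k %in% 1:3) stop("'k' must be 1, 2 or 3")
  nz <- dim(x)[3]
  if (k > nz) stop("'k' exceeds the number of slices")
  sums <- vapply(seq_len(nz), function(z) {
    sl <- x[, , z]
    if (is.null(roi)) sum(sl) else sum(sl[roi])
  }, 0)
  top <- order(sums, decreasing = TRUE)[seq_len(k)]
  max_projection(x[, , top, drop = FALSE])
}

#' Pairwise intensity asymmetry between two cells of one image
#'
#' Orders two measurements from the same image into high and low, and
#' reports their ratio. Exact ties are flagged and broken deterministically
#' by cell id (ratio 1). This is the within-image comparison used for raw
#' (unsubtracted) sibling-cell measurements.
#'
#' @param measure_a,measure_b the two measurements: either bare intensity
#'   values or lists with elements `cell_id` and `intensity`.
#' @return a list of class `PairMeasurement`: `high_cell`, `low_cell`,
#'   `high_intensity`, `low_intensity`, `ratio`, `tie`.
#' @export
pair_asymmetry <- function(measure_a, measure_b) {
  norm <- function(m, default_id) {
    if (is.list(m)) list(id = m$cell_id, val = as.numeric(m$intensity))
    else list(id = default_id, val = as.numeric(m))
  }
  a <- norm(measure_a, 1L)
  b <- norm(measure_b, 2L)
  if (min(a$val, b$val) <= 0)
    stop("nonpositive low intensity: ratio undefined")
  tie <- a$val == b$val
  if (tie) {
    ord <- order(c(a$id, b$id))
    hi <- list(a, b)[[ord[1]]]; lo <- list(a, b)[[ord[2]]]
  } else if (a$val > b$val) { hi <- a; lo <- b } else { hi <- b; lo <- a }
  structure(list(high_cell = hi$id, low_cell = lo$id,
                 high_intensity = hi$val, low_intensity = lo$val,
                 ratio = hi$val / lo$val, tie = tie),
            class = "PairMeasurement")
}
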