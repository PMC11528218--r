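# Readers/writers: multi-page 16-bit TIFF stacks (one file per channel),
# label volumes with a JSON sidecar carrying trajectories and parameters,
# and the CSV count/measurement schemas. Coordinates in all on-disk schemas
# are 1-based (y, x, z); label 0 is background/unassigned.

#' Read a multichannel stack from TIFF files
#'
#' Each file holds one channel as a (multi-page) grayscale TIFF; pages are
#' z slices. A single-page (2D) image becomes a one-slice stack. Pixel
#' values are read as stored integers.
#'
#' @param paths one TIFF path per channel.
#' @param channels channel names; default file base names.
#' @param roles channel roles as in [multi_channel_stack()]; default first =
#'   segmentation.
#' @return a [multi_channel_stack()].
#' @export
read_stack <- function(paths, channels = NULL, roles = NULL) {
  if (is.null(channels))
    channels <- tools::file_path_sans_ext(basename(paths))
  chans <- lapply(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(pg) {
      if (length(dim(pg)) == 3L) pg[, , 1] else pg   # drop extra samples
    })
    array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  })
  names(chans) <- channels
  multi_channel_stack(chans, roles = roles)
}

#' Write a multichannel stack as 16-bit multi-page TIFFs
#'
#' One file per channel, named `<dir>/<channel>.tif`. Intensities are
#' rounded to integers and clipped to the stack's bit-depth ceiling; a
#' write-then-read round trip reproduces the rounded values exactly.
#'
#' @param stack a [multi_channel_stack()] or 3D array.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_stack <- function(stack, dir) {
  if (is.array(stack)) stack <- multi_channel_stack(list(ch1 = stack))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ceiling_val <- 2^stack$bit_depth - 1
  paths <- character(0)
  for (nm in names(stack$channels)) {
    x <- stack$channels[[nm]]
    x <- pmin(pmax(round(x), 0), ceiling_val)
    pages <- lapply(seq_len(dim(x)[3]), function(z) x[, , z] / 65535)
    p <- file.path(dir, paste0(nm, ".tif"))
    tiff::writeTIFF(pages, p, bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a segmentation result: label TIFF plus JSON sidecar
#'
#' Labels go to a 16-bit multi-page TIFF; trajectories, merge events,
#' parameters and the cell count go to `<path>.json`. [read_labels()]
#' reproduces the label volume exactly.
#'
#' @param result a `SegmentationResult`, or a plain integer label array.
#' @param path output TIFF path.
#' @return invisibly, the TIFF path.
#' @export
write_labels <- function(result, path) {
  lab <- if (inherits(result, "SegmentationResult")) result$labels else result
  assert_stack3d(lab)
  if (max(lab) > 65535) stop("more than 65535 labels cannot be stored in 16-bit")
  pages <- lapply(seq_len(dim(lab)[3]), function(z) lab[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (inherits(result, "SegmentationResult")) {
    side <- list(
      n_cells = result$n_cells,
      merge_events = result$merge_events,
      trajectories = lapply(result$trajectories, function(t)
        list(id = t$id, label = t$label, status = t$status,
             merge_slice = t$merge_slice, slices = t$slices)),
      params = unclass(result$params))
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  }
  invisible(path)
}

#' Read a label volume written by [write_labels()]
#'
#' @param path the TIFF path; the sidecar `<path>.json` is loaded when
#'   present.
#' @return list with `labels` (integer array) and `sidecar` (list or
#'   `NULL`).
#' @export
read_labels <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lab <- array(as.integer(unlist(pages)), c(dim(pages[[1]]), length(pages)))
  side_path <- paste0(path, ".json")
  sidecar <- if (file.exists(side_path))
    jsonlite::read_json(side_path, simplifyVector = TRUE) else NULL
  list(labels = lab, sidecar = sidecar)
}

#' Write / read an ionocyte count table
#'
#' CSV schema: `condition`, `replicate`, `larva_id`, `neuromast_id`,
#' `mature_units`, `progenitor_units`.
#'
#' @param table a `CountTable` data frame.
#' @param path CSV path.
#' @return `write_counts`: invisibly, the path; `read_counts`: the
#'   `CountTable`.
#' @export
write_counts <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "replicate", "larva_id", "neuromast_id",
            "mature_units", "progenitor_units")
  if (!all(need %in% names(out)))
    stop("not a count table: expected columns ", paste(need, collapse = ", "))
  class(out) <- c("CountTable", "data.frame")
  out
}
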