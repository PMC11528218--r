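# Slice-wise z-tracking segmentation: the z-stack is treated as a timelapse,
# 2D components are linked across slices by voxel overlap, and components
# that join two or more tracked cells trigger a merge event. Cells are kept
# only up to (not including) the merge, which is what separates individual
# ionocytes from the shared basal support-cell structure they fuse into.

#' Segmentation parameter set
#'
#' Bundles the parameters of [segment_cells()]. The defaults are the
#' pipeline's reference settings for 16-bit confocal stacks: a 50 x 50 x 3
#' voxel top-hat footprint, Gaussian sigma 1 x 1 x 0.5, a fixed grey-value
#' threshold of 500, and an EDT shrink cutoff of 2 voxels.
#'
#' @param tophat_footprint background-subtraction box `(y, x, z)` in voxels.
#' @param gaussian_sigma smoothing sigma `(y, x, z)` in voxels.
#' @param threshold grey value; voxels `>= threshold` are foreground
#'   (inclusive rule).
#' @param edt_min minimum Euclidean distance (voxels) kept by [edt_shrink()].
#' @param edt_mode `"3d"` volumetric transform (default) or `"2d"` per slice.
#' @param min_object_voxels cells with fewer total voxels are dropped
#'   (speck filter; set 0 to keep everything).
#' @param connectivity_2d in-slice connectivity, 8 (default) or 4.
#' @param traverse_from `"first_slice"` (default) or `"last_slice"`; the
#'   fused basal structure must lie at the *end* of traversal.
#' @return a list of class `SegmentationParams`.
#' @export
segmentation_params <- function(tophat_footprint = c(50, 50, 3),
                                gaussian_sigma = c(1, 1, 0.5),
                                threshold = 500,
                                edt_min = 2,
                                edt_mode = c("3d", "2d"),
                                min_object_voxels = 20,
                                connectivity_2d = 8,
                                traverse_from = c("first_slice", "last_slice")) {
  stopifnot(threshold >= 0, edt_min > 0, min_object_voxels >= 0)
  if (!connectivity_2d %in% c(4, 8)) stop("connectivity_2d must be 4 or 8")
  structure(list(
    tophat_footprint = tophat_footprint,
    gaussian_sigma = gaussian_sigma,
    threshold = threshold,
    edt_min = edt_min,
    edt_mode = match.arg(edt_mode),
    min_object_voxels = as.integer(min_object_voxels),
    connectivity_2d = as.integer(connectivity_2d),
    traverse_from = match.arg(traverse_from)
  ), class = "SegmentationParams")
}

#' Split a binary mask into cells by z-tracking with merge events
#'
#' Traverses the stack slice by slice, labels 2D connected components, and
#' links each component to open trajectories by pixel overlap (>= 1 shared
#' (y, x) position with the trajectory's component in the previous slice).
#' A component touching two or more open trajectories — or a previously
#' merged region — ends those trajectories at the previous slice (a merge
#' event); the merged component and everything it continues into stays
#' unlabelled. A component touching exactly one open trajectory continues
#' it; when several components continue one trajectory (a split), the
#' largest overlap continues it and the rest open new trajectories; a
#' component touching nothing opens a new trajectory.
#'
#' @param mask logical/integer 3D array `(ny, nx, nz)`.
#' @param connectivity_2d 8 (default) or 4.
#' @param traverse_from `"first_slice"` or `"last_slice"`.
#' @param min_object_voxels minimum total voxels for a trajectory to become
#'   a labelled cell.
#' @return an object of class `SegmentationResult`: list with
#'   \describe{
#'     \item{labels}{integer array, cell labels 1..K, 0 = background or
#'       merged/unassigned voxels}
#'     \item{trajectories}{one record per tracked object: id, final label
#'       (0 if filtered), status (`terminated_at_merge` or
#'       `terminated_at_end`), and a per-slice data frame (slice, component,
#'       centroid_y, centroid_x, area)}
#'     \item{merge_events}{data frame: slice, merged_component,
#'       participants (comma-separated trajectory ids)}
#'     \item{params}{parameters used, when called via [segment_cells()]}
#'   }
#' @export
split_by_ztracking <- function(mask, connectivity_2d = 8,
                               traverse_from = c("first_slice", "last_slice"),
                               min_object_voxels = 20) {
  assert_stack3d(mask)
  traverse_from <- match.arg(traverse_from)
  d <- dim(mask)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  zs <- if (traverse_from == "first_slice") seq_len(nz) else rev(seq_len(nz))

  trajs <- list()        # id -> list(slices=df rows list, pixels=list, status)
  open_pix <- list()     # id (char) -> pixel indices in previous slice
  dead_pix <- integer(0) # merged-region pixels in previous slice
  merge_events <- list()
  next_id <- 0L
  prev_z <- NA_integer_

  for (z in zs) {
    lab <- label_slice_2d(mask[, , z], connectivity_2d)
    ncomp <- max(lab)
    prev_map <- integer(ny * nx)           # 0 none, >0 traj id, -1 dead
    for (id in names(open_pix)) prev_map[open_pix[[id]]] <- as.integer(id)
    prev_map[dead_pix] <- -1L

    comp_pix <- if (ncomp > 0) split(which(lab > 0), lab[lab > 0]) else list()
    new_open <- list()
    new_dead <- integer(0)
    continuations <- list()  # traj id -> list(comp = int, overlap = int)

    for (ci in seq_len(ncomp)) {
      pix <- comp_pix[[as.character(ci)]]
      hits <- prev_map[pix]
      traj_hits <- hits[hits > 0L]
      hit_ids <- unique(traj_hits)
      dead_hit <- any(hits == -1L)
      n_links <- length(hit_ids) + as.integer(dead_hit)
      if (n_links >= 2L) {
        # merge event: participating trajectories end at the previous slice
        for (id in hit_ids) {
          trajs[[id]]$status <- "terminated_at_merge"
          trajs[[id]]$merge_slice <- z
        }
        merge_events[[length(merge_events) + 1L]] <-
          data.frame(slice = z, merged_component = ci,
                     participants = paste(sort(hit_ids), collapse = ","),
                     stringsAsFactors = FALSE)
        new_dead <- c(new_dead, pix)
      } else if (length(hit_ids) == 1L) {
        id <- hit_ids[1]
        continuations[[as.character(id)]] <-
          c(continuations[[as.character(id)]],
            list(list(comp = ci, overlap = length(traj_hits))))
      } else if (dead_hit) {
        new_dead <- c(new_dead, pix)
      } else {
        # opens a new trajectory
        next_id <- next_id + 1L
        trajs[[next_id]] <- list(id = next_id, slices = list(), pixels = list(),
                                 status = "open", merge_slice = NA_integer_)
        continuations[[as.character(next_id)]] <-
          list(list(comp = ci, overlap = 0L))
      }
    }

    # resolve continuations (splits: best overlap continues, rest are new)
    for (id_chr in names(continuations)) {
      id <- as.integer(id_chr)
      cands <- continuations[[id_chr]]
      still_open <- !is.null(trajs[[id]]) && trajs[[id]]$status == "open"
      ord <- order(vapply(cands, function(c) -c$overlap, 0),
                   vapply(cands, function(c) c$comp, 0L))
      for (k in seq_along(ord)) {
        ci <- cands[[ord[k]]]$comp
        pix <- comp_pix[[as.character(ci)]]
        if (k == 1L && still_open) {
          tid <- id
        } else {
          next_id <- next_id + 1L
          trajs[[next_id]] <- list(id = next_id, slices = list(),
                                   pixels = list(), status = "open",
                                   merge_slice = NA_integer_)
          tid <- next_id
        }
        yy <- ((pix - 1L) %% ny) + 1L
        xx <- ((pix - 1L) %/% ny) + 1L
        trajs[[tid]]$slices[[length(trajs[[tid]]$slices) + 1L]] <-
          data.frame(slice = z, component = ci,
                     centroid_y = mean(yy), centroid_x = mean(xx),
                     area = length(pix))
        trajs[[tid]]$pixels[[length(trajs[[tid]]$pixels) + 1L]] <-
          list(slice = z, pix = pix)
        new_open[[as.character(tid)]] <- pix
      }
    }

    # trajectories with no continuation this slice end here
    for (id in names(open_pix)) {
      if (is.null(new_open[[id]]) && trajs[[as.integer(id)]]$status == "open")
        trajs[[as.integer(id)]]$status <- "terminated_at_end"
    }
    open_pix <- new_open
    dead_pix <- new_dead
    prev_z <- z
  }
  for (i in seq_along(trajs))
    if (trajs[[i]]$status == "open") trajs[[i]]$status <- "terminated_at_end"

  # assemble labels: trajectories above the size filter, ordered by first
  # traversal slice then centroid
  totals <- vapply(trajs, function(t)
    sum(vapply(t$pixels, function(p) length(p$pix), 0L)), 0L)
  keep <- which(totals >= min_object_voxels & totals > 0L)
  if (length(keep)) {
    firsts <- vapply(trajs[keep], function(t) t$slices[[1]]$slice, 0)
    tpos <- if (traverse_from == "first_slice") firsts else -firsts
    cy <- vapply(trajs[keep], function(t) t$slices[[1]]$centroid_y, 0)
    cx <- vapply(trajs[keep], function(t) t$slices[[1]]$centroid_x, 0)
    keep <- keep[order(tpos, cy, cx)]
  }
  labels <- array(0L, d)
  for (k in seq_along(keep)) {
    t <- trajs[[keep[k]]]
    for (p in t$pixels)
      labels[p$pix + (p$slice - 1L) * ny * nx] <- k
  }
  traj_out <- lapply(seq_along(trajs), function(i) {
    t <- trajs[[i]]
    list(id = t$id,
         label = if (i %in% keep) match(i, keep) else 0L,
         status = t$status,
         merge_slice = t$merge_slice,
         slices = do.call(rbind, t$slices))
  })
  structure(list(labels = labels,
                 n_cells = length(keep),
                 trajectories = traj_out,
                 merge_events = if (length(merge_events))
                   do.call(rbind, merge_events)
                 else data.frame(slice = integer(0),
                                 merged_component = integer(0),
                                 participants = character(0)),
                 params = NULL),
            class = "SegmentationResult")
}

#' @export
print.SegmentationResult <- function(x, ...) {
  cat(sprintf("SegmentationResult: %d cell(s), %d merge event(s), %d trajectorie(s)\n",
              x$n_cells, nrow(x$merge_events), length(x$trajectories)))
  invisible(x)
}

#' Segment ionocytes in a 3D stack
#'
#' Runs the full segmentation chain on the reporter channel: white top-hat
#' background subtraction, Gaussian smoothing, fixed-threshold binarization,
#' Euclidean-distance-transform mask shrinking, then slice-wise z-tracking
#' with merge-event splitting ([split_by_ztracking()]). Cells fused into a
#' shared basal structure are recovered individually because each trajectory
#' is kept only up to its merge event.
#'
#' @param stack a [multi_channel_stack()] or a plain 3D array (treated as
#'   the segmentation channel).
#' @param params a [segmentation_params()] object.
#' @return a `SegmentationResult` (see [split_by_ztracking()]) with `params`
#'   recorded.
#' @examples
#' spec <- stack_spec(shape = c(64, 64, 12),
#'                    cells = list(cell_spec(c(24, 24, 5), c(6, 6, 3), 3000)),
#'                    noise = noise_spec(0, 0))
#' sim <- generate_stack(spec, seed = 1)
#' seg <- segment_cells(sim$stack)
#' seg$n_cells
#' @export
segment_cells <- function(stack, params = segmentation_params()) {
  channel <- get_channel(stack, "segmentation")
  x <- white_tophat_3d(channel, params$tophat_footprint)
  x <- gaussian_smooth(x, params$gaussian_sigma)
  mask <- binarize(x, params$threshold)
  mask <- edt_shrink(mask, params$edt_min, mode = params$edt_mode)
  res <- split_by_ztracking(mask,
                            connectivity_2d = params$connectivity_2d,
                            traverse_from = params$traverse_from,
                            min_object_voxels = params$min_object_voxels)
  res$params <- params
  res
}
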