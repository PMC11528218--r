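#' Multichannel 3D fluorescence stack
#'
#' A light container for a multichannel confocal z-stack. Each channel is a
#' numeric array with `dim = c(ny, nx, nz)` (rows, columns, slices); all
#' channels share one shape. One channel carries the segmentation reporter,
#' the remaining channels carry measurement signals (e.g. HCR probes).
#'
#' @param channels named list of 3D numeric arrays, all with identical `dim`.
#' @param roles character vector, same length as `channels`; each entry
#'   `"segmentation"` or `"measurement"`.
#' @param voxel_size optional numeric `(y, x, z)` voxel spacing in micrometres.
#' @param bit_depth intensity bit depth (ceiling `2^bit_depth - 1`).
#'
#' @return an object of class `MultiChannelStack`: a list with elements
#'   `channels`, `roles`, `voxel_size`, `bit_depth`.
#' @examples
#' a <- array(0, c(8, 8, 4))
#' s <- multi_channel_stack(list(gfp = a), roles = "segmentation")
#' dim(get_channel(s, "gfp"))
#' @export
multi_channel_stack <- function(channels, roles = NULL, voxel_size = NULL,
                                bit_depth = 16L) {
  if (!is.list(channels) || length(channels) == 0)
    stop("'channels' must be a non-empty list of 3D arrays")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    names(channels) <- paste0("ch", seq_along(channels))
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("every channel must be a 3D array (ny, nx, nz)")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all channels must share one shape")
  if (is.null(roles)) {
    roles <- c("segmentation", rep("measurement", length(channels) - 1L))
  }
  roles <- match.arg(roles, c("segmentation", "measurement"),
                     several.ok = TRUE)
  if (length(roles) != length(channels))
    stop("'roles' must match the number of channels")
  if (!is.null(voxel_size) && (length(voxel_size) != 3L || any(voxel_size <= 0)))
    stop("'voxel_size' must be positive (y, x, z) spacing")
  structure(list(channels = channels, roles = roles,
                 voxel_size = voxel_size, bit_depth = as.integer(bit_depth)),
            class = "MultiChannelStack")
}

#' Extract one channel from a stack
#'
#' @param stack a [multi_channel_stack()], a plain 3D array (returned as is),
#'   or a list of arrays.
#' @param which channel name, index, or `"segmentation"` to pick the first
#'   channel with the segmentation role.
#' @return a 3D numeric array.
#' @export
get_channel <- function(stack, which = "segmentation") {
  if (is.array(stack) && length(dim(stack)) == 3L) return(stack)
  if (inherits(stack, "MultiChannelStack")) {
    if (identical(which, "segmentation")) {
      i <- match("segmentation", stack$roles)
      if (is.na(i)) i <- 1L
      return(stack$channels[[i]])
    }
    return(stack$channels[[which]])
  }
  if (is.list(stack)) return(stack[[if (identical(which, "segmentation")) 1L else which]])
  stop("cannot extract a channel from this object")
}

#' @export
print.MultiChannelStack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("MultiChannelStack: %d channel(s), %d x %d x %d (y, x, z)\n",
              length(x$channels), d[1], d[2], d[3]))
  for (i in seq_along(x$channels))
    cat(sprintf("  [%d] %-12s %s  range [%.6g, %.6g]\n", i,
                names(x$channels)[i], x$roles[i],
                min(x$channels[[i]]), max(x$channels[[i]])))
  if (!is.null(x$voxel_size))
    cat(sprintf("  voxel size (um): %.3g x %.3g x %.3g\n",
                x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

# internal: check a 3D array argument
assert_stack3d <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("'%s' must be a 3D array (ny, nx, nz)", name))
  invisible(x)
}
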