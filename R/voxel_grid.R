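#' Multi-channel 3D intensity grid
#'
#' The in-memory container for a confocal stack: a 4D numeric array indexed
#' `[y, x, z, channel]` plus the physical voxel size and channel names.
#' Slice `z = 1` is the outermost (objective-side) slice; structures above
#' the epidermis, such as trichomes, therefore sit at *smaller* z.  Readers
#' of stacks acquired in the opposite order should pass `flip_z = TRUE` to
#' [read_stack()].
#'
#' @param data numeric array.  Accepted shapes: `[y, x]` (one slice, one
#'   channel), `[y, x, z]` (one channel) or `[y, x, z, channel]`.
#' @param voxel_size numeric length-3 vector `c(dz, dy, dx)` in micrometres.
#' @param channel_names character vector naming the channels; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(runif(16 * 16 * 8 * 2), c(16, 16, 8, 2)),
#'                 voxel_size = c(1, 0.5, 0.5),
#'                 channel_names = c("wall", "nucleus"))
#' dim(g)
#' @export
voxel_grid <- function(data, voxel_size = c(1, 1, 1), channel_names = NULL) {
  if (!is.numeric(data)) stop("`data` must be a numeric array")
  d <- dim(data)
  if (is.null(d)) stop("`data` must have dimensions")
  if (length(d) == 2L) dim(data) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(data) <- c(d, 1L)
  else if (length(d) != 4L) stop("`data` must be a 2D, 3D or 4D array")
  d <- dim(data)
  if (any(d < 1L)) stop("all dimensions must be >= 1")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("`voxel_size` must be three positive values c(dz, dy, dx)")
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("intensities must be finite")
  }
  if (any(data < 0)) stop("intensities must be non-negative")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d[4]))
  if (length(channel_names) != d[4]) {
    stop("`channel_names` length must equal the number of channels (", d[4], ")")
  }
  structure(
    list(data = data,
         voxel_size = stats::setNames(as.numeric(voxel_size),
                                      c("dz", "dy", "dx")),
         channel_names = as.character(channel_names)),
    class = "voxel_grid")
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d px, %d slices, %d channel(s) [%s]\n",
              d[1], d[2], d[3], d[4], paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  voxel size (dz, dy, dx): %g x %g x %g um\n",
              x$voxel_size[["dz"]], x$voxel_size[["dy"]], x$voxel_size[["dx"]]))
  invisible(x)
}

#' Extract one channel of a grid as a 3D array
#'
#' @param grid a [voxel_grid()].
#' @param channel channel name or integer index.
#' @return numeric array `[y, x, z]`.
#' @export
grid_channel <- function(grid, channel) {
  stopifnot(inherits(grid, "voxel_grid"))
  ci <- resolve_channel(grid, channel)
  arr <- grid$data[, , , ci, drop = FALSE]
  dim(arr) <- dim(grid$data)[1:3]
  arr
}

resolve_channel <- function(grid, channel) {
  if (is.character(channel)) {
    ci <- match(channel, grid$channel_names)
    if (is.na(ci)) {
      stop("channel '", channel, "' not found; available: ",
           paste(grid$channel_names, collapse = ", "))
    }
  } else {
    ci <- as.integer(channel)
    if (ci < 1L || ci > dim(grid$data)[4]) stop("channel index out of range")
  }
  ci
}

#' Linear combination of channels
#'
#' Computes `sum_c coefficients[c] * I_c + offset` voxelwise and clips the
#' result to the non-negative intensity range (negative values to 0).
#' Useful before segmentation when one channel bleeds into another.
#'
#' @param grid a [voxel_grid()].
#' @param coefficients numeric weights, one per channel.
#' @param offset scalar added after the weighted sum.
#' @param clip_max optional upper clip (default: no upper clipping).
#' @return single-channel [voxel_grid()] with the same voxel size.
#' @examples
#' g <- voxel_grid(array(10, c(4, 4, 2, 2)))
#' combine_channels(g, c(0.5, 0.5))
#' @export
combine_channels <- function(grid, coefficients, offset = 0, clip_max = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  nch <- dim(grid$data)[4]
  if (length(coefficients) != nch) {
    stop("`coefficients` must have one entry per channel (", nch, ")")
  }
  d <- dim(grid$data)[1:3]
  out <- array(0, d)
  for (c in seq_len(nch)) {
    out <- out + coefficients[c] * grid$data[, , , c]
  }
  out <- out + offset
  out[out < 0] <- 0
  if (!is.null(clip_max)) out[out > clip_max] <- clip_max
  voxel_grid(out, voxel_size = grid$voxel_size,
             channel_names = "combined")
}
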