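#' Leaf surface mask
#'
#' Per-(x, y) z-coordinate of the detected leaf surface.  `z` holds
#' fractional slice indices on the 1..Z scale used throughout the package
#' (slice 1 = outermost); `valid` flags punctures whose intensity maximum
#' reached the detection threshold before any filling.
#'
#' @param z numeric matrix `[y, x]` of slice coordinates.
#' @param valid logical matrix of the same shape.
#' @param n_slices total number of slices Z of the source grid.
#' @param channel name of the source channel.
#' @return object of class `surface_mask`.
#' @export
surface_mask <- function(z, valid = NULL, n_slices = max(z), channel = NA) {
  stopifnot(is.matrix(z))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(z), ncol(z))
  stopifnot(identical(dim(z), dim(valid)))
  ok <- valid & !is.na(z)
  tol <- 1e-5 * max(1, n_slices)
  if (any(z[ok] < 1 - tol) || any(z[ok] > n_slices + tol)) {
    stop("surface z-coordinates must lie within [1, n_slices]")
  }
  structure(list(z = z, valid = valid, n_slices = as.integer(n_slices),
                 channel = channel),
            class = "surface_mask")
}

#' @export
print.surface_mask <- function(x, ...) {
  cat(sprintf("<surface_mask> %d x %d px over %d slices (%.1f%% valid punctures)\n",
              nrow(x$z), ncol(x$z), x$n_slices, 100 * mean(x$valid)))
  invisible(x)
}

#' Build the leaf surface mask from intensity punctures
#'
#' For every (x, y) position a virtual puncture runs along z and the slice
#' of maximal intensity is recorded; the premise is that the outer
#' periclinal cell wall carries the brightest fluorescence, so these maxima
#' trace the leaf surface.  Ties take the smallest z (the outermost slice).
#' Punctures whose maximum stays below `min_intensity` are flagged invalid
#' and filled with the value of the nearest valid puncture (Euclidean
#' distance), and the raw surface is then smoothed ("leaf surface
#' approximation") with a median filter (default) or mean filter.
#'
#' @param grid a [voxel_grid()].
#' @param channel wall channel name or index.
#' @param min_intensity detection threshold for a puncture maximum.
#' @param smooth_radius half-width in px of the smoothing window
#'   (0 disables smoothing).
#' @param smooth `"median"` (robust to isolated argmax outliers, the
#'   default) or `"mean"`.
#' @return a [surface_mask()] with all punctures valid after filling.
#' @export
build_surface_mask <- function(grid, channel = 1L, min_intensity = 0,
                               smooth_radius = 2L,
                               smooth = c("median", "mean")) {
  stopifnot(inherits(grid, "voxel_grid"))
  smooth <- match.arg(smooth)
  arr <- grid_channel(grid, channel)
  d <- dim(arr)
  if (d[3] < 2L) stop("need at least 2 z-slices to detect a surface")
  best <- arr[, , 1]
  zidx <- matrix(1, d[1], d[2])
  for (z in seq_len(d[3])[-1]) {
    sl <- arr[, , z]
    upd <- sl > best            # strict: ties keep the smaller z
    best[upd] <- sl[upd]
    zidx[upd] <- z
  }
  valid <- best >= min_intensity
  if (!any(valid)) {
    stop("empty surface: no puncture maximum reaches min_intensity = ",
         min_intensity)
  }
  raw_valid <- valid
  if (!all(valid)) {
    zidx <- fill_nearest_2d(zidx, valid)
  }
  if (smooth_radius > 0L) {
    zidx <- if (smooth == "median") {
      median_filter_2d(zidx, as.integer(smooth_radius))
    } else {
      mean_filter_2d(zidx, as.integer(smooth_radius))
    }
  }
  m <- surface_mask(zidx, valid = matrix(TRUE, d[1], d[2]),
                    n_slices = d[3],
                    channel = if (is.character(channel)) channel else
                      grid$channel_names[resolve_channel(grid, channel)])
  m$raw_valid <- raw_valid
  m
}

#' Remove trichome protrusions from a surface mask
#'
#' Trichomes rise above the epidermis; under the convention that z
#' increases into the leaf they are local *minima* of the surface z-map and
#' are removed by grayscale closing with a disk structuring element.
#' Protrusions whose base radius is smaller than `radius` are flattened to
#' the surrounding surface level; the operation is idempotent.
#'
#' @param mask a [surface_mask()].
#' @param radius disk radius in px of the structuring element (>= 1).
#' @param op `"closing"` (removes upward protrusions, i.e. trichomes) or
#'   `"opening"` (removes downward pits).
#' @return a [surface_mask()] with the edited z-map.
#' @export
remove_trichomes <- function(mask, radius = 5L, op = c("closing", "opening")) {
  stopifnot(inherits(mask, "surface_mask"))
  op <- match.arg(op)
  if (radius < 1) stop("`radius` must be >= 1")
  # EBImage grayscale morphology operates on [0, 1]; normalise by Z
  zn <- mask$z / mask$n_slices
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  zn <- if (op == "closing") EBImage::closing(zn, brush)
        else EBImage::opening(zn, brush)
  out <- mask
  out$z <- zn * mask$n_slices
  out
}

#' Sample a virtual cut at a fixed depth below the surface
#'
#' Produces the 2D image whose pixel (x, y) is the stack intensity at
#' `z_surface(x, y) + depth`, linearly interpolated along z for fractional
#' coordinates and clamped to the deepest slice.  At the generator's wall
#' depth this flattens the curved epidermis into a single plane showing the
#' cell-wall network.
#'
#' @param grid a [voxel_grid()].
#' @param mask a fully valid [surface_mask()].
#' @param channel channel to sample.
#' @param depth non-negative distance below the surface in slices
#'   (fractional allowed); use `depth_um / voxel dz` to specify micrometres.
#' @return object of class `virtual_cut`: list with `intensity` (matrix),
#'   `depth`, and the mask used.
#' @export
extract_virtual_cut <- function(grid, mask, channel = 1L, depth = 2) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(mask, "surface_mask"))
  if (depth < 0) stop("`depth` must be >= 0")
  arr <- grid_channel(grid, channel)
  d <- dim(arr)
  if (!identical(dim(mask$z), d[1:2])) {
    stop("mask shape ", paste(dim(mask$z), collapse = "x"),
         " does not match grid XY shape ", paste(d[1:2], collapse = "x"))
  }
  zq <- mask$z + depth
  zq[zq < 1] <- 1
  zq[zq > d[3]] <- d[3]
  z0 <- floor(zq)
  z1 <- pmin(z0 + 1, d[3])
  w <- zq - z0
  npx <- d[1] * d[2]
  flat <- matrix(arr, nrow = npx)   # columns are z-slices
  px <- seq_len(npx)
  lo <- flat[cbind(px, as.integer(z0))]
  hi <- flat[cbind(px, as.integer(z1))]
  intensity <- matrix((1 - w) * lo + w * hi, d[1], d[2])
  structure(list(intensity = intensity, depth = depth, mask = mask,
                 channel = channel),
            class = "virtual_cut")
}

#' @export
print.virtual_cut <- function(x, ...) {
  cat(sprintf("<virtual_cut> %d x %d px at depth %.2f slices below the surface\n",
              nrow(x$intensity), ncol(x$intensity), x$depth))
  invisible(x)
}

#' Write a surface mask as a 32-bit TIFF (z-map scaled to the unit range)
#'
#' The z-map is stored divided by `n_slices`; the sidecar records the
#' divisor so [read_surface_mask()] restores slice units.
#' @param mask a [surface_mask()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_surface_mask <- function(mask, path) {
  stopifnot(inherits(mask, "surface_mask"))
  tiff::writeTIFF(mask$z / mask$n_slices, path, bits.per.sample = 32L,
                  reduce = FALSE)
  write_stack_sidecar(path, list(n_slices = mask$n_slices,
                                 storage = "surface"))
  invisible(path)
}

#' Read a surface mask written by [write_surface_mask()]
#' @param path TIFF path.
#' @return a [surface_mask()].
#' @export
read_surface_mask <- function(path) {
  z <- tiff::readTIFF(path)
  meta <- read_stack_sidecar(path)
  ns <- if (!is.null(meta$n_slices)) meta$n_slices else 1L
  surface_mask(z * ns, n_slices = ns)
}
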