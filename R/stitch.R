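#' Tile set for mosaic stitching
#'
#' Bundles the frames of a tile scan with their mosaic offsets.  All tiles
#' must share voxel size, channel count and z-depth, and the offsets must
#' describe a connected mosaic (every tile overlaps or abuts another).
#'
#' @param tiles list of [voxel_grid()]s.
#' @param offsets numeric matrix with columns `(y, x)`: pixel position of
#'   each tile's (1, 1) pixel in mosaic coordinates (from acquisition
#'   metadata; any origin, integers).
#' @return object of class `tile_set`.
#' @export
tile_set <- function(tiles, offsets) {
  stopifnot(is.list(tiles), length(tiles) >= 1L)
  lapply(tiles, function(t) stopifnot(inherits(t, "voxel_grid")))
  offsets <- matrix(as.numeric(offsets), ncol = 2)
  if (nrow(offsets) != length(tiles)) {
    stop("need one (y, x) offset per tile")
  }
  vs <- tiles[[1]]$voxel_size
  nch <- dim(tiles[[1]]$data)[4]
  nz <- dim(tiles[[1]]$data)[3]
  for (t in tiles[-1]) {
    if (!isTRUE(all.equal(t$voxel_size, vs))) {
      stop("all tiles must share the voxel size")
    }
    if (dim(t$data)[4] != nch) stop("all tiles must share the channel count")
    if (dim(t$data)[3] != nz) {
      stop("tiles with unequal z-depth cannot be stitched (",
           dim(t$data)[3], " vs ", nz, ")")
    }
  }
  # connectivity: union of tiles must form one mosaic component
  n <- length(tiles)
  if (n > 1L) {
    boxes <- t(vapply(seq_len(n), function(k) {
      d <- dim(tiles[[k]]$data)
      c(offsets[k, 1], offsets[k, 1] + d[1] - 1,
        offsets[k, 2], offsets[k, 2] + d[2] - 1)
    }, numeric(4)))
    comp <- seq_len(n)
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      touch <- boxes[a, 1] <= boxes[b, 2] + 1 && boxes[b, 1] <= boxes[a, 2] + 1 &&
        boxes[a, 3] <= boxes[b, 4] + 1 && boxes[b, 3] <= boxes[a, 4] + 1
      if (touch) comp[comp == comp[b]] <- comp[a]
    }
    if (length(unique(comp)) > 1L) {
      stop("tile offsets do not form a connected mosaic")
    }
  }
  structure(list(tiles = tiles, offsets = offsets), class = "tile_set")
}

#' Stitch a tile scan into one mosaic grid
#'
#' Places every tile at its offset (optionally refined) and resolves
#' overlap regions by linear feather blending: each tile contributes with
#' a weight that ramps down towards its own border, removing seams without
#' displacing structures.  With `refine = TRUE` each offset is adjusted by
#' the integer XY translation (within `search_radius`) that maximises the
#' normalised cross-correlation of the overlap on a z-maximum projection
#' of `channel`; tiles whose stated overlap is empty keep the metadata
#' offset with a warning.
#'
#' @param tiles a [tile_set()].
#' @param refine refine offsets by cross-correlation.
#' @param search_radius maximum offset correction in px.
#' @param channel channel used for the correlation (default first).
#' @return a [voxel_grid()] covering the offsets' bounding box.
#' @export
stitch_frames <- function(tiles, refine = FALSE, search_radius = 10L,
                          channel = 1L) {
  stopifnot(inherits(tiles, "tile_set"))
  ts <- tiles$tiles
  off <- round(tiles$offsets)
  n <- length(ts)
  if (refine && n > 1L) {
    proj <- lapply(ts, function(t) {
      a <- grid_channel(t, channel)
      apply(a, c(1, 2), max)
    })
    for (k in 2:n) {
      anchor <- best_overlap_partner(off, ts, k)
      if (is.na(anchor)) {
        warning("tile ", k, " has no stated overlap; keeping metadata offset")
        next
      }
      adj <- refine_offset_ncc(proj[[anchor]], off[anchor, ],
                               proj[[k]], off[k, ], search_radius)
      if (is.null(adj)) {
        warning("tile ", k, " overlap with tile ", anchor,
                " is empty; keeping metadata offset")
      } else {
        off[k, ] <- adj
      }
    }
  }
  # normalise offsets to a 1-based canvas
  off[, 1] <- off[, 1] - min(off[, 1]) + 1
  off[, 2] <- off[, 2] - min(off[, 2]) + 1
  dims <- vapply(ts, function(t) dim(t$data), integer(4))
  H <- max(off[, 1] + dims[1, ] - 1)
  W <- max(off[, 2] + dims[2, ] - 1)
  nz <- dims[3, 1]; nch <- dims[4, 1]
  acc <- array(0, c(H, W, nz, nch))
  wacc <- matrix(0, H, W)
  for (k in seq_len(n)) {
    d <- dims[, k]
    ry <- off[k, 1]:(off[k, 1] + d[1] - 1)
    rx <- off[k, 2]:(off[k, 2] + d[2] - 1)
    wy <- pmin(seq_len(d[1]), rev(seq_len(d[1])))
    wx <- pmin(seq_len(d[2]), rev(seq_len(d[2])))
    w <- outer(wy, wx, pmin)           # distance-to-border ramp
    for (z in seq_len(nz)) for (c in seq_len(nch)) {
      acc[ry, rx, z, c] <- acc[ry, rx, z, c] + w * ts[[k]]$data[, , z, c]
    }
    wacc[ry, rx] <- wacc[ry, rx] + w
  }
  wacc[wacc == 0] <- 1
  for (z in seq_len(nz)) for (c in seq_len(nch)) {
    acc[, , z, c] <- acc[, , z, c] / wacc
  }
  voxel_grid(acc, voxel_size = ts[[1]]$voxel_size,
             channel_names = ts[[1]]$channel_names)
}

best_overlap_partner <- function(off, ts, k) {
  dk <- dim(ts[[k]]$data)
  best <- NA_integer_; barea <- 0
  for (a in seq_len(k - 1)) {
    da <- dim(ts[[a]]$data)
    oy <- min(off[a, 1] + da[1], off[k, 1] + dk[1]) - max(off[a, 1], off[k, 1])
    ox <- min(off[a, 2] + da[2], off[k, 2] + dk[2]) - max(off[a, 2], off[k, 2])
    if (oy > 0 && ox > 0 && oy * ox > barea) {
      barea <- oy * ox
      best <- a
    }
  }
  best
}

refine_offset_ncc <- function(img_a, off_a, img_b, off_b, radius) {
  best <- NULL; bncc <- -Inf
  for (dy in -radius:radius) for (dx in -radius:radius) {
    ob <- c(off_b[1] + dy, off_b[2] + dx)
    ya <- max(off_a[1], ob[1]); yb <- min(off_a[1] + nrow(img_a),
                                          ob[1] + nrow(img_b)) - 1
    xa <- max(off_a[2], ob[2]); xb <- min(off_a[2] + ncol(img_a),
                                          ob[2] + ncol(img_b)) - 1
    if (yb - ya < 3 || xb - xa < 3) next
    a <- img_a[(ya - off_a[1] + 1):(yb - off_a[1] + 1),
               (xa - off_a[2] + 1):(xb - off_a[2] + 1)]
    b <- img_b[(ya - ob[1] + 1):(yb - ob[1] + 1),
               (xa - ob[2] + 1):(xb - ob[2] + 1)]
    sa <- stats::sd(a); sb <- stats::sd(b)
    if (sa == 0 || sb == 0) next
    ncc <- mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
    # prefer the smallest correction on ties
    score <- ncc - 1e-9 * (abs(dy) + abs(dx))
    if (score > bncc) {
      bncc <- score
      best <- ob
    }
  }
  best
}
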