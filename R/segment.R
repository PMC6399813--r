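#' Watershed segmentation parameters
#'
#' @param mode `"border"` for bright-ridge images (cell walls: the image
#'   itself is the flooding relief) or `"object"` for bright-blob images
#'   (nuclei: the inverted image is flooded and pixels below
#'   `background_threshold` become background).
#' @param dynamic_tolerance h-minima depth used to generate markers: the
#'   relief's minima are filled up to this depth before extracting regional
#'   minima, so shallow minima (noise) do not seed regions.  Same role as
#'   the "tolerance" of interactive morphological-segmentation tools.
#' @param connectivity region connectivity: 4 or 8 in 2D, 6 or 26 in 3D.
#'   Defaults (4 / 6) let the 8-/26-connected thin watershed lines separate
#'   regions.
#' @param background_threshold intensity below which pixels are background
#'   (object mode only).
#' @param min_size minimum region size in pixels/voxels (object mode only):
#'   regions smaller than this are dropped as sub-resolution debris.  The
#'   imaging protocol requires nuclei to span at least 3 px in diameter, so
#'   smaller blobs cannot be real objects.  0 disables the filter.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(mode = c("border", "object"),
                                dynamic_tolerance = 10,
                                connectivity = NULL,
                                background_threshold = 0,
                                min_size = 0) {
  mode <- match.arg(mode)
  if (dynamic_tolerance < 0) stop("`dynamic_tolerance` must be >= 0")
  if (min_size < 0) stop("`min_size` must be >= 0")
  structure(list(mode = mode, dynamic_tolerance = dynamic_tolerance,
                 connectivity = connectivity,
                 background_threshold = background_threshold,
                 min_size = min_size),
            class = "segmentation_params")
}

#' Marker-controlled watershed segmentation
#'
#' Generates markers as the regional minima of the h-minima transform of
#' the relief (minima shallower than `dynamic_tolerance` are suppressed),
#' then floods the relief from the markers.  Watershed lines get the
#' reserved value 1; catchment basins get indices 2..K+1, ordered by the
#' row-major position of each marker's first pixel so outputs are
#' reproducible.  In object mode the image is inverted first and pixels
#' below `background_threshold` are excluded as background (0).
#'
#' @param image numeric 2D matrix or 3D array `[y, x, z]`, or a
#'   [virtual_cut()] (its intensity image is used).
#' @param params a [segmentation_params()].
#' @param markers optional precomputed marker label image (integers >= 1,
#'   0 elsewhere) overriding h-minima marker generation.
#' @param voxel_size optional `c(dz, dy, dx)` attached to the result.
#' @return a [label_image()].
#' @export
segment_watershed <- function(image, params = segmentation_params(),
                              markers = NULL, voxel_size = NULL) {
  if (inherits(image, "virtual_cut")) image <- image$intensity
  stopifnot(inherits(params, "segmentation_params"))
  if (anyNA(image) || any(!is.finite(image))) {
    stop("intensities must be finite")
  }
  d <- dim(image)
  if (is.null(d) || !(length(d) %in% c(2L, 3L))) stop("`image` must be 2D or 3D")
  is3d <- length(d) == 3L
  conn <- params$connectivity
  if (is.null(conn)) conn <- if (is3d) 6L else 4L
  if (is3d && !conn %in% c(6L, 26L)) stop("3D connectivity must be 6 or 26")
  if (!is3d && !conn %in% c(4L, 8L)) stop("2D connectivity must be 4 or 8")

  img <- image
  if (!is3d) dim(img) <- c(d, 1L)
  if (params$mode == "border") {
    relief <- img
    floodable <- array(1L, dim(img))
  } else {
    floodable <- array(0L, dim(img))
    floodable[img >= params$background_threshold] <- 1L
    relief <- max(img) - img
  }

  if (is.null(markers)) {
    hm <- hminima_transform(relief, params$dynamic_tolerance, conn)
    # restrict minima to the floodable domain: push masked-out pixels high
    if (any(floodable == 0L)) {
      hm[floodable == 0L] <- max(hm) + 1 + params$dynamic_tolerance
    }
    mk <- regional_minima_labels(hm, conn)
    mk[floodable == 0L] <- 0L
  } else {
    mk <- markers
    if (!is3d && length(dim(mk)) == 2L) dim(mk) <- c(dim(mk), 1L)
    storage.mode(mk) <- "integer"
    if (!identical(dim(mk), dim(img))) stop("marker shape mismatch")
  }
  mk <- renumber_markers_rowmajor(mk)
  k <- max(mk)
  if (k == 0L) {
    stop("empty segmentation: no markers found; lower `dynamic_tolerance` ",
         "or check the background threshold")
  }
  out <- watershed_flood(relief, mk, floodable, conn)
  if (params$mode == "object" && params$min_size > 0) {
    out <- drop_small_regions(out, params$min_size)
  }
  if (!is3d) dim(out) <- d
  label_image(out, voxel_size = voxel_size)
}

# remove regions below a size threshold, clean orphaned boundary pixels and
# renumber the survivors 2..K+1 preserving their order
drop_small_regions <- function(lab, min_size) {
  sz <- table(lab[lab >= 2L])
  small <- as.integer(names(sz)[sz < min_size])
  if (length(small)) {
    lab[lab %in% small] <- 0L
    bidx <- which(lab == 1L)
    if (length(bidx)) {
      nb <- neighbour_label_sets(lab, bidx)
      orphan <- vapply(nb, function(s) length(s) == 0L, logical(1))
      lab[bidx[orphan]] <- 0L
    }
  }
  keep <- sort(unique(lab[lab >= 2L]))
  if (length(keep)) {
    remap <- integer(max(keep))
    remap[keep] <- seq_along(keep) + 1L
    sel <- lab >= 2L
    lab[sel] <- remap[lab[sel]]
  }
  lab
}

#' h-minima transform (fills minima shallower than depth h)
#'
#' Morphological reconstruction by erosion of `img + h` above `img`;
#' regional minima of the result are the watershed markers.
#' @param img numeric 2D/3D array.
#' @param h fill depth (>= 0).
#' @param connectivity neighbourhood connectivity.
#' @return array of the same shape.
#' @export
hminima_transform <- function(img, h, connectivity = 4L) {
  if (h < 0) stop("`h` must be >= 0")
  d <- dim(img)
  if (length(d) == 2L) dim(img) <- c(d, 1L)
  if (h == 0) {
    out <- img
  } else {
    # reconstruction by erosion via the dilation dual
    out <- -morpho_reconstruct_dilate(-(img + h), -img, as.integer(connectivity))
  }
  dim(out) <- d
  out
}

renumber_markers_rowmajor <- function(mk) {
  d <- dim(mk)
  k <- max(mk)
  if (k == 0L) return(mk)
  # row-major linear index (x fastest within a row? row-major = scan rows:
  # index = ((z-1)*Y + y-1)*X + x) -- first pixel per marker in that order
  idx <- which(mk > 0L)
  lab <- mk[idx]
  ii <- arrayInd(idx, .dim = d)
  rm_index <- (if (ncol(ii) == 3L) (ii[, 3] - 1) * d[1] * d[2] else 0) +
    (ii[, 1] - 1) * d[2] + ii[, 2]
  firsts <- tapply(rm_index, lab, min)
  ord <- order(as.numeric(firsts))
  remap <- integer(k)
  remap[as.integer(names(firsts))[ord]] <- seq_along(ord)
  out <- mk
  out[idx] <- remap[lab]
  out
}

#' Merge regions of a label image
#'
#' Fuses the given regions into the smallest id.  The regions must form a
#' connected group under adjacency (two regions are adjacent when they are
#' in direct contact or separated only by boundary pixels); boundary pixels
#' that separated only merged regions are reassigned to the merged region.
#'
#' @param labels a [label_image()].
#' @param ids integer region indices to merge.
#' @return a [label_image()].
#' @export
merge_labels <- function(labels, ids) {
  lab <- as_label_array(labels)
  ids <- sort(unique(as.integer(ids)))
  present <- label_ids(labels)
  if (!all(ids %in% present)) {
    stop("unknown region id(s): ", paste(setdiff(ids, present), collapse = ", "))
  }
  if (length(ids) == 1L) return(labels)
  adj <- region_adjacency_pairs(lab)
  sub <- adj[adj[, 1] %in% ids & adj[, 2] %in% ids, , drop = FALSE]
  if (!connected_ids(ids, sub)) {
    stop("regions ", paste(ids, collapse = ", "),
         " are not mutually adjacent; merge adjacent groups only")
  }
  lab <- merge_id_set(lab, ids)
  label_image(lab, voxel_size = attr(labels, "voxel_size"))
}

# fuse a set of region ids into min(ids); boundary pixels that separated
# only members of the set are reassigned to the merged region
merge_id_set <- function(lab, ids) {
  target <- min(ids)
  bidx <- which(lab == 1L)
  if (length(bidx)) {
    nb <- neighbour_label_sets(lab, bidx)
    sep <- vapply(nb, function(s) length(s) >= 2L && all(s %in% ids),
                  logical(1))
    lab[bidx[sep]] <- target
  }
  lab[lab %in% ids] <- target
  lab
}

connected_ids <- function(ids, pairs) {
  if (length(ids) <= 1L) return(TRUE)
  seen <- ids[1]
  repeat {
    nxt <- unique(c(pairs[pairs[, 1] %in% seen, 2],
                    pairs[pairs[, 2] %in% seen, 1]))
    grow <- setdiff(intersect(nxt, ids), seen)
    if (!length(grow)) break
    seen <- c(seen, grow)
  }
  length(seen) == length(ids)
}

#' Remove a region from a label image
#'
#' The region's pixels and the boundary pixels exclusive to it become
#' background; boundary pixels shared with surviving neighbours are kept.
#'
#' @param labels a [label_image()].
#' @param id region index to remove.
#' @return a [label_image()].
#' @export
remove_label <- function(labels, id) {
  lab <- as_label_array(labels)
  id <- as.integer(id)
  if (!id %in% label_ids(labels)) stop("region id ", id, " not present")
  lab[lab == id] <- 0L
  # boundary pixels neighbouring no remaining region become background
  bidx <- which(lab == 1L)
  if (length(bidx)) {
    nb <- neighbour_label_sets(lab, bidx)
    drop <- vapply(nb, function(s) length(s) == 0L, logical(1))
    lab[bidx[drop]] <- 0L
  }
  label_image(lab, voxel_size = attr(labels, "voxel_size"))
}

#' Heal nuclei fragmented by 1-px boundaries
#'
#' Automatic correction for fragmented segments: wherever a boundary of
#' width exactly one pixel separates exactly two regions, the two regions
#' are merged and the separating pixels absorbed; the rule is iterated to a
#' fixpoint.  Wider separations (including background gaps) are never
#' merged.
#'
#' @param labels a [label_image()].
#' @return a [label_image()].
#' @export
heal_fragmented_labels <- function(labels) {
  lab <- as_label_array(labels)
  repeat {
    bidx <- which(lab == 1L)
    if (!length(bidx)) break
    nb <- neighbour_label_sets(lab, bidx)
    # a 1-px-wide separation: a boundary pixel directly touching exactly
    # two distinct regions (wider boundaries touch at most one each)
    pair_of <- vapply(nb, function(s) {
      if (length(s) == 2L) paste(s, collapse = "-") else NA_character_
    }, character(1))
    pairs <- unique(pair_of[!is.na(pair_of)])
    if (!length(pairs)) break
    ab <- as.integer(strsplit(pairs[1], "-", fixed = TRUE)[[1]])
    lab <- merge_id_set(lab, ab)    # recompute pairs after every merge
  }
  label_image(lab, voxel_size = attr(labels, "voxel_size"))
}

# labels >= 2 in the full neighbourhood (8 in 2D / 26 in 3D) of given pixels
neighbour_label_sets <- function(lab, idx) {
  d <- dim(lab)
  is3d <- length(d) == 3L
  co <- arrayInd(idx, .dim = d)
  offs <- if (is3d) {
    as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  } else {
    as.matrix(expand.grid(di = -1:1, dj = -1:1))
  }
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  sets <- vector("list", length(idx))
  for (r in seq_len(nrow(offs))) {
    ni <- co[, 1] + offs[r, 1]
    nj <- co[, 2] + offs[r, 2]
    ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2]
    if (is3d) {
      nk <- co[, 3] + offs[r, 3]
      ok <- ok & nk >= 1 & nk <= d[3]
      lin <- (nk - 1) * d[1] * d[2] + (nj - 1) * d[1] + ni
    } else {
      lin <- (nj - 1) * d[1] + ni
    }
    v <- rep(0L, length(idx))
    v[ok] <- lab[lin[ok]]
    keep <- which(v >= 2L)
    for (q in keep) sets[[q]] <- c(sets[[q]], v[q])
  }
  lapply(sets, function(s) if (is.null(s)) integer(0) else sort(unique(s)))
}

# unique adjacent region pairs (direct contact or via boundary pixels)
region_adjacency_pairs <- function(lab) {
  d <- dim(lab)
  pairs <- matrix(integer(0), 0, 2)
  # via boundary pixels
  bidx <- which(lab == 1L)
  if (length(bidx)) {
    nb <- neighbour_label_sets(lab, bidx)
    for (s in nb) {
      if (length(s) >= 2L) {
        cmb <- t(utils::combn(s, 2L))
        pairs <- rbind(pairs, cmb)
      }
    }
  }
  # direct contact (shifted comparison, 8-neighbourhood in 2D, 26 in 3D)
  pairs <- rbind(pairs, direct_contact_pairs(lab))
  unique(pairs)
}

direct_contact_pairs <- function(lab) {
  d <- dim(lab)
  is3d <- length(d) == 3L
  offs <- if (is3d) {
    as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = 0:1))
  } else {
    as.matrix(expand.grid(di = -1:1, dj = 0:1))
  }
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  res <- list()
  for (r in seq_len(nrow(offs))) {
    a <- shift_crop(lab, offs[r, ])
    if (is.null(a)) next
    sel <- a$a >= 2L & a$b >= 2L & a$a != a$b
    if (any(sel)) {
      res[[length(res) + 1]] <- cbind(pmin(a$a[sel], a$b[sel]),
                                      pmax(a$a[sel], a$b[sel]))
    }
  }
  if (!length(res)) return(matrix(integer(0), 0, 2))
  unique(do.call(rbind, res))
}

shift_crop <- function(lab, off) {
  d <- dim(lab)
  is3d <- length(d) == 3L
  ri <- seq_len(d[1]); rj <- seq_len(d[2])
  si <- ri + off[1]; sj <- rj + off[2]
  keep_i <- si >= 1 & si <= d[1]
  keep_j <- sj >= 1 & sj <= d[2]
  if (!any(keep_i) || !any(keep_j)) return(NULL)
  if (is3d) {
    rk <- seq_len(d[3]); sk <- rk + off[3]
    keep_k <- sk >= 1 & sk <= d[3]
    if (!any(keep_k)) return(NULL)
    list(a = lab[ri[keep_i], rj[keep_j], rk[keep_k], drop = FALSE],
         b = lab[si[keep_i], sj[keep_j], sk[keep_k], drop = FALSE])
  } else {
    list(a = lab[ri[keep_i], rj[keep_j], drop = FALSE],
         b = lab[si[keep_i], sj[keep_j], drop = FALSE])
  }
}

#' Attach group names to region indices
#'
#' Records an id-to-group assignment (for instance cells of the same type
#' or the same longitudinal cell row) that downstream feature tables attach
#' as a `group` column.  The label array itself is unchanged.  Duplicate
#' assignments of one id keep the last and emit a warning.
#'
#' @param labels a [label_image()].
#' @param assignment named vector or list: names are region indices,
#'   values are group names.
#' @return `labels` with a `groups` attribute (named character vector).
#' @export
group_labels <- function(labels, assignment) {
  ids <- as.integer(names(assignment))
  if (anyNA(ids)) stop("assignment names must be region indices")
  present <- label_ids(labels)
  if (!all(ids %in% present)) {
    stop("unknown region id(s): ", paste(setdiff(ids, present), collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    warning("duplicate group assignment; last one wins")
  }
  vals <- as.character(unlist(assignment))
  groups <- attr(labels, "groups")
  if (is.null(groups)) groups <- character(0)
  for (k in seq_along(ids)) groups[[as.character(ids[k])]] <- vals[k]
  attr(labels, "groups") <- groups
  labels
}

#' Check the thin-line partition property of a segmentation
#'
#' Removing the watershed lines and relabelling by connectivity must
#' reproduce the same region partition if lines are thin.
#' @param labels a [label_image()].
#' @param connectivity region connectivity (4/8 in 2D, 6/26 in 3D).
#' @return TRUE if the partition is reproduced.
#' @export
watershed_lines_are_thin <- function(labels, connectivity = NULL) {
  lab <- as_label_array(labels)
  d <- dim(lab)
  is3d <- length(d) == 3L
  if (is.null(connectivity)) connectivity <- if (is3d) 6L else 4L
  fg <- array(0L, d)
  fg[lab >= 2L] <- 1L
  if (!is3d) dim(fg) <- c(d, 1L)
  cc <- label_components(fg, as.integer(connectivity))
  dim(cc) <- d
  ids <- label_ids(labels)
  if (max(cc) != length(ids)) return(FALSE)
  for (id in ids) {
    if (length(unique(cc[lab == id])) != 1L) return(FALSE)
  }
  TRUE
}
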