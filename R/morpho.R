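#' Per-cell shape features from a 2D label image
#'
#' Measures every region of a segmented virtual cut, in physical units:
#'
#' * `area_um2` - pixel count times `dy * dx`;
#' * `perimeter_um` - length of the simplified crack-boundary polygon
#'   (see [trace_region_polygon()]);
#' * `length_um`, `width_um` - major/minor axis lengths of the ellipse with
#'   matching second central moments;
#' * `elongation` - `1 - width / length`;
#' * `circularity` - equivalent-disk perimeter over the region perimeter,
#'   `2 * sqrt(pi * area) / perimeter` (1 for a disk);
#' * `rectangularity` - area over the area of the minimal-area oriented
#'   bounding rectangle of the outline;
#' * `lobeyness` - convex-hull perimeter over the region perimeter (1 for
#'   convex cells, ~0.6 for wavy pavement cells), see [lobeyness()];
#' * `neighbor_count`, `is_marginal` - see [neighbor_counts()];
#' * `centroid_y_um`, `centroid_x_um` - physical centroid.
#'
#' @param labels a 2D [label_image()].
#' @param voxel_size `c(dz, dy, dx)` in micrometres (dz unused here);
#'   defaults to the label image's own voxel size.
#' @param simplify_tol outline simplification tolerance in px.
#' @return data.frame with one row per region, sorted by index; region
#'   groups attached by [group_labels()] appear in a `group` column.
#' @export
compute_shape_features <- function(labels, voxel_size = NULL,
                                   simplify_tol = 1) {
  lab <- as_label_array(labels)
  if (length(dim(lab)) != 2L) {
    stop("expected 2D labels; use compute_volumes() for 3D label stacks")
  }
  if (is.null(voxel_size)) voxel_size <- label_voxel_size(labels)
  dy <- voxel_size[2]; dx <- voxel_size[3]
  ids <- label_ids(labels)
  nbr <- neighbor_counts(labels)
  groups <- attr(labels, "groups")
  rows <- lapply(ids, function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    n <- nrow(px)
    area <- n * dy * dx
    # crop to the bounding box for the outline trace
    i0 <- min(px[, 1]); j0 <- min(px[, 2])
    sub <- matrix(0L, max(px[, 1]) - i0 + 1L, max(px[, 2]) - j0 + 1L)
    sub[cbind(px[, 1] - i0 + 1L, px[, 2] - j0 + 1L)] <- 1L
    poly <- trace_region_polygon(sub, simplify_tol = simplify_tol)
    polyu <- cbind(poly[, 1] * dy, poly[, 2] * dx)   # physical units
    per <- polygon_perimeter(polyu)
    hull <- convex_hull_polygon(polyu)
    lob <- polygon_perimeter(hull) / per
    rect <- min_area_rect(polyu)
    rectangularity <- if (rect$area > 0) min(area / rect$area, 1.5) else NA_real_
    # moment ellipse (pixel-extent corrected covariance)
    yy <- px[, 1] * dy; xx <- px[, 2] * dx
    vy <- sum((yy - mean(yy))^2) / n + dy^2 / 12
    vx <- sum((xx - mean(xx))^2) / n + dx^2 / 12
    vxy <- sum((yy - mean(yy)) * (xx - mean(xx))) / n
    ev <- eigen(matrix(c(vy, vxy, vxy, vx), 2), symmetric = TRUE)$values
    ev[ev < 0] <- 0
    len <- 4 * sqrt(ev[1]); wid <- 4 * sqrt(ev[2])
    data.frame(
      index = id,
      area_um2 = area,
      perimeter_um = per,
      length_um = len,
      width_um = wid,
      elongation = 1 - wid / len,
      circularity = 2 * sqrt(pi * area) / per,
      rectangularity = rectangularity,
      lobeyness = lob,
      neighbor_count = nbr$neighbor_count[match(id, nbr$index)],
      is_marginal = nbr$is_marginal[match(id, nbr$index)],
      centroid_y_um = (mean(px[, 1]) - 0.5) * dy,
      centroid_x_um = (mean(px[, 2]) - 0.5) * dx)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(index = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), length_um = numeric(0),
                      width_um = numeric(0), elongation = numeric(0),
                      circularity = numeric(0), rectangularity = numeric(0),
                      lobeyness = numeric(0), neighbor_count = integer(0),
                      is_marginal = logical(0), centroid_y_um = numeric(0),
                      centroid_x_um = numeric(0))
  }
  if (!is.null(groups)) {
    out$group <- ifelse(as.character(out$index) %in% names(groups),
                        unname(groups[as.character(out$index)]), "")
  }
  rownames(out) <- NULL
  out
}

#' Lobeyness of a cell outline
#'
#' Ratio of the convex-hull perimeter of the outline to the outline
#' perimeter itself.  Always <= 1, with equality exactly for convex
#' outlines; wavy jigsaw-puzzle pavement cells score markedly lower.
#'
#' @param polygon two-column matrix of outline vertices (`y`, `x` or any
#'   planar coordinates; closed implicitly), at least 3 vertices.
#' @return dimensionless ratio in (0, 1].
#' @export
lobeyness <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
  if (polygon_area(polygon) <= 0) stop("degenerate (zero-area) polygon")
  hull <- convex_hull_polygon(polygon)
  polygon_perimeter(hull) / polygon_perimeter(polygon)
}

#' Volumes and centroids from a 3D label stack
#'
#' Volume is the voxel count times `dz * dy * dx`; centroids are physical
#' (z, y, x) micrometre coordinates.
#'
#' @param labels a 3D [label_image()].
#' @param voxel_size `c(dz, dy, dx)` in micrometres.
#' @return data.frame with columns `index`, `volume_um3`, `centroid_z_um`,
#'   `centroid_y_um`, `centroid_x_um`, `voxel_count`.
#' @export
compute_volumes <- function(labels, voxel_size = NULL) {
  lab <- as_label_array(labels)
  if (length(dim(lab)) != 3L) {
    stop("expected 3D labels; use compute_shape_features() for 2D labels")
  }
  if (is.null(voxel_size)) voxel_size <- label_voxel_size(labels)
  vv <- prod(voxel_size)
  ids <- label_ids(labels)
  if (!length(ids)) {
    return(data.frame(index = integer(0), volume_um3 = numeric(0),
                      centroid_z_um = numeric(0), centroid_y_um = numeric(0),
                      centroid_x_um = numeric(0), voxel_count = integer(0)))
  }
  idx <- which(lab >= 2L)
  co <- arrayInd(idx, .dim = dim(lab))
  v <- lab[idx]
  cnt <- tapply(rep(1L, length(v)), v, sum)
  cz <- tapply(co[, 3], v, mean); cy <- tapply(co[, 1], v, mean)
  cx <- tapply(co[, 2], v, mean)
  ord <- order(as.integer(names(cnt)))
  data.frame(index = as.integer(names(cnt))[ord],
             volume_um3 = as.numeric(cnt)[ord] * vv,
             centroid_z_um = (as.numeric(cz)[ord] - 0.5) * voxel_size[1],
             centroid_y_um = (as.numeric(cy)[ord] - 0.5) * voxel_size[2],
             centroid_x_um = (as.numeric(cx)[ord] - 0.5) * voxel_size[3],
             voxel_count = as.integer(cnt)[ord])
}

#' Cylinder approximation of a cell volume
#'
#' For 2D-segmented cells each cell is approximated by a cylinder whose
#' base is the 2D projection of the cell and whose height is the epidermal
#' layer depth, so `volume = area * depth`.
#'
#' @param area cell projection area(s), um^2.
#' @param depth epidermal layer depth, um (> 0).
#' @return volume(s) in um^3.
#' @export
cylinder_cell_volume <- function(area, depth) {
  if (any(depth <= 0)) stop("`depth` must be positive")
  area * depth
}

#' Region adjacency counts and marginal flags
#'
#' Two regions are neighbours when some pixel (a boundary pixel or a pixel
#' of direct contact) holds both within its 8-neighbourhood.  Counts
#' include marginal neighbours; regions touching the image border are
#' flagged `is_marginal` (the convention for downstream analyses: marginal
#' cells count as neighbours but are excluded as subjects).
#'
#' @param labels a 2D [label_image()].
#' @return data.frame with `index`, `neighbor_count`, `is_marginal`.
#' @export
neighbor_counts <- function(labels) {
  lab <- as_label_array(labels)
  if (length(dim(lab)) != 2L) stop("expected 2D labels")
  ids <- label_ids(labels)
  pairs <- region_adjacency_pairs(lab)
  cnt <- stats::setNames(integer(length(ids)), ids)
  if (nrow(pairs)) {
    tb <- table(factor(c(pairs[, 1], pairs[, 2]), levels = ids))
    cnt[names(tb)] <- as.integer(tb)
  }
  d <- dim(lab)
  border <- c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]])
  marg <- unique(border[border >= 2L])
  # boundary pixels on the border make their adjacent regions marginal too
  bidx <- which(lab == 1L)
  if (length(bidx)) {
    co <- arrayInd(bidx, .dim = d)
    onb <- co[, 1] == 1L | co[, 1] == d[1] | co[, 2] == 1L | co[, 2] == d[2]
    if (any(onb)) {
      nb <- neighbour_label_sets(lab, bidx[onb])
      marg <- unique(c(marg, unlist(nb)))
    }
  }
  data.frame(index = ids, neighbor_count = as.integer(cnt),
             is_marginal = ids %in% marg)
}

#' Cell size index
#'
#' `M / (M + S)` where `M` is the area of the candidate guard mother cell
#' and `S` the area of its sister cell from the same asymmetric division.
#' Values near 0 mark strongly asymmetric divisions (small stomatal
#' initials); values above 0.5 suggest a trichome precursor instead.
#'
#' @param area_m candidate (guard-mother-cell) area, um^2.
#' @param area_s sister-cell area, um^2.
#' @return dimensionless index in (0, 1).
#' @export
cell_size_index <- function(area_m, area_s) {
  if (any(area_m <= 0) || any(area_s <= 0)) stop("areas must be positive")
  area_m / (area_m + area_s)
}

#' Flag guard-mother-cell candidates
#'
#' Guard mother cells sit in stomatal rows between two in-row sisters and
#' two cross-row cells, so they typically have exactly four neighbours.
#' Candidates are the non-marginal cells with `neighbor_count == 4`; each
#' is annotated with the cell size index against its left in-row sister
#' (the adjacent cell of the same longitudinal row on the smaller-
#' coordinate side of the growth axis).  Candidates with index > 0.5 carry
#' a trichome-precursor flag; candidates without a left in-row sister are
#' excluded with a warning.
#'
#' @param table feature table from [compute_shape_features()].
#' @param labels the 2D [label_image()] the table was measured on.
#' @param axis leaf growth axis, `"x"` (default) or `"y"`.
#' @return data.frame with `cell_index`, `neighbor_count`,
#'   `left_sister_index`, `cell_size_index`, `trichome_precursor`.
#' @export
flag_gmc_candidates <- function(table, labels, axis = c("x", "y")) {
  axis <- match.arg(axis)
  stopifnot(all(c("index", "area_um2", "neighbor_count", "is_marginal",
                  "centroid_y_um", "centroid_x_um") %in% names(table)))
  lab <- as_label_array(labels)
  pairs <- region_adjacency_pairs(lab)
  along <- if (axis == "x") table$centroid_x_um else table$centroid_y_um
  across <- if (axis == "x") table$centroid_y_um else table$centroid_x_um
  names(along) <- names(across) <- table$index
  cand_ids <- table$index[table$neighbor_count == 4L & !table$is_marginal]
  out <- list()
  for (id in cand_ids) {
    nbrs <- c(pairs[pairs[, 1] == id, 2], pairs[pairs[, 2] == id, 1])
    key <- as.character(id)
    da <- along[as.character(nbrs)] - along[key]
    dc <- across[as.character(nbrs)] - across[key]
    in_row <- abs(dc) < abs(da)          # same longitudinal row
    left <- nbrs[in_row & da < 0]
    if (!length(left)) {
      warning("cell ", id, " has no left in-row sister; excluded")
      next
    }
    sister <- left[which.max(along[as.character(left)])]
    m <- table$area_um2[table$index == id]
    s <- table$area_um2[table$index == sister]
    csi <- cell_size_index(m, s)
    out[[length(out) + 1L]] <- data.frame(
      cell_index = id, neighbor_count = 4L,
      left_sister_index = sister, cell_size_index = csi,
      trichome_precursor = csi > 0.5)
  }
  if (!length(out)) {
    return(data.frame(cell_index = integer(0), neighbor_count = integer(0),
                      left_sister_index = integer(0),
                      cell_size_index = numeric(0),
                      trichome_precursor = logical(0)))
  }
  do.call(rbind, out)
}

#' Match segmented cells to segmented nuclei
#'
#' Each cell of the 2D segmentation is approximated by a cylinder: its 2D
#' region extruded from the leaf surface down to `depth` slices below it.
#' A nucleus matches a cell when the cell label at the nucleus XY centroid
#' is that cell and the nucleus z-centroid lies within the cell's cylinder
#' window `[z_surface, z_surface + depth]`.  If several nuclei fall into
#' one cylinder, the one with the most voxels inside the cylinder is kept
#' and the others are reported unmatched.
#'
#' @param cells a 2D [label_image()] of cells.
#' @param nuclei a 3D [label_image()] of nuclei (same XY shape).
#' @param mask the [surface_mask()] used for the virtual cut.
#' @param depth epidermal layer depth in slices.
#' @param voxel_size `c(dz, dy, dx)` um, for the reported nucleus volumes.
#' @return data.frame with one row per cell (`cell_index`,
#'   `nucleus_index`, `nucleus_volume_um3`; NA when no nucleus matched).
#'   Attribute `unmatched_nuclei` lists nucleus indices without a cell.
#' @export
match_cells_to_nuclei <- function(cells, nuclei, mask, depth,
                                  voxel_size = NULL) {
  cl <- as_label_array(cells)
  nl <- as_label_array(nuclei)
  if (length(dim(cl)) != 2L || length(dim(nl)) != 3L) {
    stop("`cells` must be 2D and `nuclei` 3D")
  }
  if (!identical(dim(cl), dim(nl)[1:2])) {
    stop("XY shape mismatch: cells ", paste(dim(cl), collapse = "x"),
         " vs nuclei ", paste(dim(nl)[1:2], collapse = "x"))
  }
  stopifnot(inherits(mask, "surface_mask"))
  if (is.null(voxel_size)) voxel_size <- label_voxel_size(nuclei)
  nvol <- compute_volumes(nuclei, voxel_size)
  cell_ids <- label_ids(cells)
  # candidate assignment per nucleus
  idx <- which(nl >= 2L)
  co <- arrayInd(idx, .dim = dim(nl))
  v <- nl[idx]
  cyz <- tapply(co[, 3], v, mean)
  cyy <- tapply(co[, 1], v, mean)
  cyx <- tapply(co[, 2], v, mean)
  nuc_ids <- as.integer(names(cyz))
  cand <- data.frame(nucleus = nuc_ids, cell = NA_integer_,
                     inside = 0L)
  # voxels of each nucleus inside each cell cylinder
  zsurf_at <- mask$z[cbind(co[, 1], co[, 2])]
  in_window <- co[, 3] >= zsurf_at - 1e-9 & co[, 3] <= zsurf_at + depth + 1e-9
  cell_at <- cl[cbind(co[, 1], co[, 2])]
  for (k in seq_along(nuc_ids)) {
    id <- nuc_ids[k]
    yi <- as.integer(round(cyy[k])); xi <- as.integer(round(cyx[k]))
    yi <- max(1L, min(nrow(cl), yi)); xi <- max(1L, min(ncol(cl), xi))
    ccell <- cl[yi, xi]
    if (ccell < 2L) next
    zs <- mask$z[yi, xi]
    zc <- cyz[k]
    if (zc < zs - 1e-9 || zc > zs + depth + 1e-9) next
    cand$cell[k] <- ccell
    sel <- v == id & in_window & cell_at == ccell
    cand$inside[k] <- sum(sel)
  }
  # resolve multiple nuclei per cell: keep the largest inside-count
  matched <- rep(NA_integer_, length(cell_ids))
  names(matched) <- cell_ids
  ok <- !is.na(cand$cell)
  if (any(ok)) {
    sp <- split(cand[ok, ], cand$cell[ok])
    for (cc in names(sp)) {
      grp <- sp[[cc]]
      win <- grp$nucleus[order(-grp$inside, grp$nucleus)][1]
      matched[cc] <- win
    }
  }
  res <- data.frame(cell_index = cell_ids,
                    nucleus_index = as.integer(matched),
                    nucleus_volume_um3 =
                      nvol$volume_um3[match(matched, nvol$index)])
  attr(res, "unmatched_nuclei") <-
    setdiff(nuc_ids, res$nucleus_index[!is.na(res$nucleus_index)])
  res
}
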