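#' Parameters of the synthetic leaf phantom
#'
#' Describes a two-channel confocal phantom of cereal leaf epidermis: a
#' smooth curved surface carrying a bright cell-wall ridge network (with a
#' dimmer continuous outer periclinal wall sheet, the premise of surface
#' detection), one sub-surface nucleus per cell, optional trichome
#' protrusions rising above the surface, and detector-style noise.  The
#' resolvability rule of the imaging protocol is enforced: walls at least
#' 3 px thick and nuclei at least 3 px in diameter.
#'
#' @param shape `c(Z, Y, X)` stack dimensions.
#' @param voxel_size `c(dz, dy, dx)` in micrometres.
#' @param surface_base mean surface position, slices (1-based).
#' @param surface_amplitude sinusoid amplitude, slices.
#' @param surface_period `c(py, px)` sinusoid periods in px (defaults to
#'   the image extent).
#' @param surface_tilt `c(ty, tx)` plane slopes in slices/px.
#' @param pattern `"rows"` (jittered brick layout elongated along x,
#'   mimicking longitudinal cell rows) or `"voronoi"` (puzzle-like).
#' @param n_rows,n_cols rows-pattern grid; `n_cells = n_rows * n_cols`.
#' @param n_cells cell count for the voronoi pattern.
#' @param row_elongation x:y anisotropy of the voronoi metric.
#' @param wall_width anticlinal wall thickness in px (>= 3).
#' @param wall_intensity ridge peak intensity at the surface.
#' @param sheet_intensity outer periclinal wall sheet intensity.
#' @param wall_depth ridge extent below the surface, slices.
#' @param nucleus_radius nucleus radius in px (xy; diameter >= 3 px).
#' @param nucleus_radius_z nucleus radius in slices (defaults to an
#'   isotropic nucleus given the voxel anisotropy).
#' @param nucleus_intensity nucleus peak intensity.
#' @param nucleus_depth nucleus centre depth below the surface, slices.
#' @param trichome_count,trichome_base_radius,trichome_height,trichome_intensity
#'   trichome protrusions: count, base radius (px), height (slices, toward
#'   smaller z), wall intensity (trichome walls image brighter than
#'   pavement-cell walls).
#' @param noise_sd Gaussian read-noise standard deviation (0 disables).
#' @param noise_poisson apply Poisson shot noise before the Gaussian term.
#' @param seed integer seed making the phantom fully reproducible.
#' @return object of class `leaf_phantom_params`.
#' @export
leaf_phantom_params <- function(shape = c(24, 128, 192),
                                voxel_size = c(1, 0.5, 0.5),
                                surface_base = 10,
                                surface_amplitude = 3,
                                surface_period = NULL,
                                surface_tilt = c(0, 0),
                                pattern = c("rows", "voronoi"),
                                n_rows = 5, n_cols = 8,
                                n_cells = NULL,
                                row_elongation = 2,
                                wall_width = 3,
                                wall_intensity = 220,
                                sheet_intensity = 120,
                                wall_depth = 6,
                                nucleus_radius = 4,
                                nucleus_radius_z = NULL,
                                nucleus_intensity = 200,
                                nucleus_depth = 4,
                                trichome_count = 0,
                                trichome_base_radius = 3,
                                trichome_height = 6,
                                trichome_intensity = 255,
                                noise_sd = 0,
                                noise_poisson = FALSE,
                                seed = 1L) {
  pattern <- match.arg(pattern)
  if (wall_width < 3) stop("wall_width must be >= 3 px (resolvability rule)")
  if (2 * nucleus_radius < 3) {
    stop("nucleus diameter must be >= 3 px (resolvability rule)")
  }
  if (is.null(surface_period)) surface_period <- c(shape[2], shape[3])
  if (is.null(nucleus_radius_z)) {
    nucleus_radius_z <- max(1.5, nucleus_radius * voxel_size[2] / voxel_size[1])
  }
  if (is.null(n_cells)) n_cells <- n_rows * n_cols
  zmin <- surface_base - surface_amplitude -
    abs(surface_tilt[1]) * shape[2] - abs(surface_tilt[2]) * shape[3]
  zmax <- surface_base + surface_amplitude +
    abs(surface_tilt[1]) * shape[2] + abs(surface_tilt[2]) * shape[3]
  if (zmin < 1 || zmax + wall_depth > shape[1]) {
    stop("surface (plus wall_depth) must stay inside [1, Z]")
  }
  structure(as.list(environment()), class = "leaf_phantom_params")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic leaf stack with ground truth
#'
#' Builds a deterministic two-channel phantom (`wall`, `nucleus`) according
#' to `params`.  Wall ridges run along the cell tessellation boundaries in
#' a band `wall_width` wide, from the surface down `wall_depth` slices with
#' intensity decaying linearly to 40% of the surface value (the outer wall
#' images brightest).  The continuous outer wall sheet covers every
#' position at the surface.  Each cell carries one ellipsoidal nucleus
#' below the surface; trichomes locally lift the surface by
#' `trichome_height` slices.  Shot/read noise is applied last and
#' intensities are quantised to integer detector counts.
#'
#' @param params a [leaf_phantom_params()].
#' @return list with `grid` (a [voxel_grid()]) and `truth`: the analytic
#'   surface `z0`, 2D cell labels, 3D nucleus labels, per-cell areas,
#'   per-nucleus volumes and centroids, the cell-nucleus pairing (a
#'   bijection by construction), and the trichome footprint mask.
#' @export
generate_leaf_stack <- function(params = leaf_phantom_params()) {
  stopifnot(inherits(params, "leaf_phantom_params"))
  with_seed(params$seed, generate_leaf_stack_impl(params))
}

generate_leaf_stack_impl <- function(p) {
  Z <- p$shape[1]; Y <- p$shape[2]; X <- p$shape[3]
  yy <- matrix(seq_len(Y), Y, X)
  xx <- matrix(seq_len(X), Y, X, byrow = TRUE)
  phy <- runif(1, 0, 2 * pi); phx <- runif(1, 0, 2 * pi)
  z0 <- p$surface_base +
    p$surface_tilt[1] * (yy - 1) + p$surface_tilt[2] * (xx - 1) +
    p$surface_amplitude * sin(2 * pi * (xx - 1) / p$surface_period[2] + phx) *
      sin(2 * pi * (yy - 1) / p$surface_period[1] + phy)

  # --- cell tessellation ---------------------------------------------------
  if (p$pattern == "rows") {
    tess <- tessellate_rows(Y, X, p$n_rows, p$n_cols)
  } else {
    tess <- tessellate_voronoi(Y, X, p$n_cells, p$row_elongation)
  }
  assign2d <- tess  # integer cell index 1..n per pixel
  n_cells <- max(assign2d)

  # 1-px boundary crack: pixels whose right or lower 4-neighbour differs
  bnd <- matrix(FALSE, Y, X)
  bnd[, -X] <- bnd[, -X] | (assign2d[, -X] != assign2d[, -1])
  bnd[-Y, ] <- bnd[-Y, ] | (assign2d[-Y, ] != assign2d[-1, ])
  cells2d <- assign2d + 1L
  cells2d[bnd] <- 1L

  # wall band: pixels within wall_width/2 of the crack, imaged brightest at
  # the wall midline (peaked transverse profile keeps the ridge crest on
  # the true boundary)
  dmap <- EBImage::distmap(1 - bnd)
  half <- (p$wall_width - 1) / 2
  wall2d <- dmap <= half
  transverse <- matrix(0, Y, X)
  transverse[wall2d] <- 1 - 0.4 * dmap[wall2d] / max(half, 1)

  # --- trichomes -----------------------------------------------------------
  trich_mask <- matrix(FALSE, Y, X)
  z_surf <- z0
  if (p$trichome_count > 0) {
    ty <- runif(p$trichome_count, 1 + p$trichome_base_radius,
                Y - p$trichome_base_radius)
    tx <- runif(p$trichome_count, 1 + p$trichome_base_radius,
                X - p$trichome_base_radius)
    for (t in seq_len(p$trichome_count)) {
      d <- sqrt((yy - ty[t])^2 + (xx - tx[t])^2)
      inb <- d < p$trichome_base_radius
      trich_mask <- trich_mask | inb
      lift <- p$trichome_height * (1 - d / p$trichome_base_radius)
      z_surf[inb] <- pmax(1, z_surf[inb] - lift[inb])
    }
  }

  # --- wall channel --------------------------------------------------------
  wall <- array(0, c(Y, X, Z))
  zs <- array(rep(seq_len(Z), each = Y * X), c(Y, X, Z))
  z_surf_a <- array(z_surf, c(Y, X, Z))
  # continuous outer sheet: tent profile around the surface, width 1 slice
  sheet_int <- ifelse(trich_mask, p$trichome_intensity, p$sheet_intensity)
  sheet <- array(sheet_int, c(Y, X, Z)) * pmax(0, 1 - abs(zs - z_surf_a))
  wall <- pmax(wall, sheet)
  # anticlinal ridges: from the surface down wall_depth slices, decaying
  frac <- (zs - z_surf_a) / p$wall_depth
  ridge <- array(0, c(Y, X, Z))
  inz <- zs >= z_surf_a - 0.5 & zs <= z_surf_a + p$wall_depth + 0.5
  wall2d_a <- array(wall2d, c(Y, X, Z))
  trans_a <- array(transverse, c(Y, X, Z))
  sel <- inz & wall2d_a
  ridge[sel] <- p$wall_intensity * trans_a[sel] *
    (1 - 0.6 * pmin(pmax(frac[sel], 0), 1))
  wall <- pmax(wall, ridge)

  # --- nuclei --------------------------------------------------------------
  nuc <- array(0, c(Y, X, Z))
  nuclab <- array(0L, c(Y, X, Z))
  centers <- matrix(NA_real_, n_cells, 3)  # y, x, z
  for (cid in seq_len(n_cells)) {
    pxs <- which(assign2d == cid, arr.ind = TRUE)
    cy <- mean(pxs[, 1]); cx <- mean(pxs[, 2])
    cy <- cy + runif(1, -2, 2); cx <- cx + runif(1, -2, 2)
    cy <- min(max(cy, 1 + p$nucleus_radius), Y - p$nucleus_radius)
    cx <- min(max(cx, 1 + p$nucleus_radius), X - p$nucleus_radius)
    cz <- z0[round(cy), round(cx)] + p$nucleus_depth
    cz <- min(max(cz, 1 + p$nucleus_radius_z), Z - p$nucleus_radius_z)
    centers[cid, ] <- c(cy, cx, cz)
    y0 <- max(1L, floor(cy - p$nucleus_radius)); y1 <- min(Y, ceiling(cy + p$nucleus_radius))
    x0 <- max(1L, floor(cx - p$nucleus_radius)); x1 <- min(X, ceiling(cx + p$nucleus_radius))
    zlo <- max(1L, floor(cz - p$nucleus_radius_z)); zhi <- min(Z, ceiling(cz + p$nucleus_radius_z))
    for (k in zlo:zhi) {
      dz2 <- ((k - cz) / p$nucleus_radius_z)^2
      if (dz2 > 1) next
      iy <- y0:y1; ix <- x0:x1
      rho2 <- outer((iy - cy)^2, rep(1, length(ix))) +
        outer(rep(1, length(iy)), (ix - cx)^2)
      rho2 <- rho2 / p$nucleus_radius^2 + dz2
      inside <- rho2 <= 1
      if (any(inside)) {
        blk <- nuc[iy, ix, k]
        prof <- p$nucleus_intensity * (1 - 0.4 * rho2)
        blk[inside] <- pmax(blk[inside], prof[inside])
        nuc[iy, ix, k] <- blk
        lb <- nuclab[iy, ix, k]
        lb[inside] <- cid + 1L
        nuclab[iy, ix, k] <- lb
      }
    }
  }

  # --- noise + quantisation ------------------------------------------------
  if (p$noise_poisson) {
    wall <- array(rpois(length(wall), wall), dim(wall))
    nuc <- array(rpois(length(nuc), nuc), dim(nuc))
  }
  if (p$noise_sd > 0) {
    wall <- wall + rnorm(length(wall), 0, p$noise_sd)
    nuc <- nuc + rnorm(length(nuc), 0, p$noise_sd)
  }
  wall <- round(pmin(pmax(wall, 0), 65535))
  nuc <- round(pmin(pmax(nuc, 0), 65535))

  arr <- array(0, c(Y, X, Z, 2))
  arr[, , , 1] <- wall
  arr[, , , 2] <- nuc
  grid <- voxel_grid(arr, voxel_size = p$voxel_size,
                     channel_names = c("wall", "nucleus"))

  areas <- as.numeric(table(factor(cells2d[cells2d >= 2L],
                                   levels = seq_len(n_cells) + 1L)))
  vox <- table(factor(nuclab[nuclab >= 2L], levels = seq_len(n_cells) + 1L))
  truth <- list(
    z0 = z0,
    z_surface = z_surf,       # including trichome lift
    cells = label_image(cells2d, voxel_size = p$voxel_size),
    nuclei = label_image(nuclab, voxel_size = p$voxel_size),
    cell_areas_px = stats::setNames(areas, seq_len(n_cells) + 1L),
    nucleus_voxels = stats::setNames(as.numeric(vox), seq_len(n_cells) + 1L),
    nucleus_centers = centers,  # columns y, x, z (px/slices)
    pairing = data.frame(cell_index = seq_len(n_cells) + 1L,
                         nucleus_index = seq_len(n_cells) + 1L),
    trichome_mask = trich_mask,
    wall2d = wall2d,
    params = p)
  list(grid = grid, truth = truth)
}

tessellate_rows <- function(Y, X, n_rows, n_cols) {
  hy <- Y / n_rows
  wx <- X / n_cols
  out <- matrix(0L, Y, X)
  for (r in seq_len(n_rows)) {
    y0 <- floor((r - 1) * hy) + 1L
    y1 <- if (r == n_rows) Y else floor(r * hy)
    brick <- if (r %% 2 == 0) wx / 2 else 0
    edges <- (seq_len(n_cols - 1)) * wx + brick +
      runif(n_cols - 1, -0.15 * wx, 0.15 * wx)
    edges <- pmin(pmax(edges, 2), X - 1)
    cuts <- c(0, sort(edges), X)
    cid <- findInterval(seq_len(X) - 0.5, cuts, rightmost.closed = TRUE)
    out[y0:y1, ] <- matrix((r - 1L) * n_cols + cid, y1 - y0 + 1L, X,
                           byrow = TRUE)
  }
  out
}

tessellate_voronoi <- function(Y, X, n_cells, elong) {
  # dart-throwing sites with a minimal scaled distance, then nearest-site
  # assignment under the row-elongated metric (x distances shrunk)
  target_min <- 0.6 * sqrt(Y * (X / elong) / n_cells)
  sites <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(sites) < n_cells && tries < 50000) {
    cand <- c(runif(1, 1, Y), runif(1, 1, X))
    tries <- tries + 1
    if (nrow(sites)) {
      d <- sqrt((sites[, 1] - cand[1])^2 + ((sites[, 2] - cand[2]) / elong)^2)
      if (min(d) < target_min) next
    }
    sites <- rbind(sites, cand)
  }
  if (nrow(sites) < n_cells) stop("could not place ", n_cells, " sites")
  yy <- matrix(seq_len(Y), Y, X)
  xx <- matrix(seq_len(X), Y, X, byrow = TRUE)
  best <- matrix(Inf, Y, X)
  out <- matrix(0L, Y, X)
  for (s in seq_len(n_cells)) {
    d <- (yy - sites[s, 1])^2 + ((xx - sites[s, 2]) / elong)^2
    upd <- d < best
    best[upd] <- d[upd]
    out[upd] <- s
  }
  out
}

#' Generate a sinusoidally lobed test polygon
#'
#' `r(theta) = base_radius + amplitude * sin(n_lobes * theta)`, sampled
#' densely; a circle for `amplitude = 0`, increasingly wavy as the
#' amplitude grows (lobeyness decreases strictly).
#'
#' @param base_radius circle radius.
#' @param n_lobes number of lobes.
#' @param amplitude lobe amplitude (< `base_radius`).
#' @param n_vertices vertex count (>= 720 for accurate arc lengths).
#' @return two-column matrix (`y`, `x`).
#' @export
generate_lobed_polygon <- function(base_radius, n_lobes, amplitude,
                                   n_vertices = 720L) {
  if (amplitude >= base_radius) stop("`amplitude` must be < `base_radius`")
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- base_radius + amplitude * sin(n_lobes * th)
  cbind(y = r * sin(th), x = r * cos(th))
}
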