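test_that("closed-form shape oracles: square, rectangle, disk, pentomino", {
  sq <- label_image(pad_region(matrix(2L, 20, 20)))
  f <- compute_shape_features(sq, voxel_size = c(1, 1, 1))
  expect_equal(f$area_um2, 400)
  expect_equal(f$perimeter_um, 80)
  expect_equal(f$circularity, 2 * sqrt(pi * 400) / 80, tolerance = 1e-6)
  expect_equal(f$elongation, 0, tolerance = 1e-6)
  expect_equal(f$rectangularity, 1, tolerance = 0.02)
  expect_equal(f$lobeyness, 1, tolerance = 1e-6)

  rc <- label_image(pad_region(matrix(2L, 40, 10)))
  fr <- compute_shape_features(rc, c(1, 1, 1))
  expect_equal(fr$elongation, 0.75, tolerance = 0.02)
  expect_equal(fr$length_um / fr$width_um, 4, tolerance = 0.02)

  dk <- label_image(pad_region(digital_disk(30)))
  fd <- compute_shape_features(dk, c(1, 1, 1))
  expect_gte(fd$circularity, 0.99)
  expect_gte(fd$lobeyness, 0.99)
  expect_lte(fd$elongation, 0.02)

  # plus-pentomino outline as exact geometry: perimeter 12, hull 4 + 4*sqrt(2)
  plus <- rbind(c(0, 1), c(0, 2), c(1, 2), c(1, 3), c(2, 3), c(2, 2),
                c(3, 2), c(3, 1), c(2, 1), c(2, 0), c(1, 0), c(1, 1))
  expect_equal(lobeyness(plus), (4 + 4 * sqrt(2)) / 12, tolerance = 1e-9)
  # and its rasterisation agrees
  s <- 10
  m <- matrix(0L, 3 * s, 3 * s)
  m[(s + 1):(2 * s), ] <- 2L
  m[, (s + 1):(2 * s)] <- 2L
  fp <- compute_shape_features(label_image(pad_region(m)), c(1, 1, 1))
  expect_equal(fp$lobeyness, (4 + 4 * sqrt(2)) / 12, tolerance = 0.01)
})

test_that("features respect physical pixel sizes", {
  sq <- label_image(pad_region(matrix(2L, 20, 20)))
  f <- compute_shape_features(sq, voxel_size = c(1, 0.5, 0.5))
  expect_equal(f$area_um2, 100)
  expect_equal(f$perimeter_um, 40)
  expect_equal(f$centroid_y_um, f$centroid_x_um)
})

test_that("lobeyness is 1 exactly for convex polygons and errors on degenerate input", {
  sqp <- rbind(c(0, 0), c(0, 4), c(4, 4), c(4, 0))
  expect_equal(lobeyness(sqp), 1)
  hexa <- t(vapply(0:5, function(k) {
    c(sin(k * pi / 3), cos(k * pi / 3))
  }, numeric(2)))
  expect_equal(lobeyness(hexa), 1, tolerance = 1e-12)
  expect_error(lobeyness(rbind(c(0, 0), c(1, 1))), "3 vertices")
  expect_error(lobeyness(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
})

test_that("lobed-polygon family: strictly decreasing, matches arc-length oracle", {
  R <- 30
  for (k in c(4, 8, 12)) {
    # start above the convexity threshold A = R / (k^2 - 1), below which
    # the outline is still convex and lobeyness pegs at 1
    amps <- seq(0.1, 0.38, length.out = 8) * R
    lobs <- vapply(amps, function(A) {
      lobeyness(generate_lobed_polygon(R, k, A))
    }, numeric(1))
    expect_true(all(diff(lobs) < 0))
    for (A in amps[c(2, 5, 8)]) {
      p <- generate_lobed_polygon(R, k, A)
      hull <- p[grDevices::chull(p[, 2], p[, 1]), ]
      oracle <- polygon_perimeter(hull) / lobed_arc_length(R, k, A)
      expect_equal(lobeyness(p), oracle, tolerance = 0.01)
    }
  }
  expect_equal(lobeyness(generate_lobed_polygon(30, 8, 0)), 1,
               tolerance = 1e-6)
  expect_error(generate_lobed_polygon(10, 4, 11), "amplitude")
})

test_that("volumes: exact voxel arithmetic and digitised ball", {
  v <- array(0L, c(20, 20, 10)); v[1:10, 1:10, 1:10] <- 2L
  tab <- compute_volumes(label_image(v), c(1.0, 0.5, 0.5))
  expect_equal(tab$volume_um3, 250)
  expect_equal(tab$voxel_count, 1000L)

  ball <- digital_ball(10)
  bt <- compute_volumes(label_image(ball), c(1, 1, 1))
  expect_equal(bt$volume_um3, 4 / 3 * pi * 1000, tolerance = 0.05)

  empty <- label_image(array(0L, c(4, 4, 4)))
  expect_equal(nrow(compute_volumes(empty, c(1, 1, 1))), 0L)
  expect_error(compute_volumes(label_image(matrix(2L, 3, 3)), c(1, 1, 1)),
               "3D")
  expect_error(compute_shape_features(label_image(array(2L, c(3, 3, 3)))),
               "2D")
})

test_that("cylinder volume is area times depth", {
  expect_equal(cylinder_cell_volume(100, 15), 1500)
  expect_equal(cylinder_cell_volume(100, 30), 2 * cylinder_cell_volume(100, 15))
  expect_error(cylinder_cell_volume(100, 0), "positive")
})

test_that("cell size index obeys its closed form and complement identity", {
  expect_equal(cell_size_index(3, 5), 0.375)
  expect_equal(cell_size_index(7, 7), 0.5)
  set.seed(41)
  m <- runif(50, 0.1, 100); s <- runif(50, 0.1, 100)
  expect_equal(cell_size_index(m, s) + cell_size_index(s, m), rep(1, 50))
  expect_error(cell_size_index(-1, 5), "positive")
})

test_that("neighbor relation: chain counts, symmetry, marginal policy", {
  chain <- matrix(0L, 8, 16)
  chain[2:7, 2:5] <- 2L; chain[2:7, 6] <- 1L
  chain[2:7, 7:10] <- 3L; chain[2:7, 11] <- 1L; chain[2:7, 12:15] <- 4L
  nc <- neighbor_counts(label_image(chain))
  expect_equal(nc$neighbor_count, c(1L, 2L, 1L))
  expect_false(any(nc$is_marginal))
  # cells touching the border are marginal
  chain2 <- chain; chain2[1, 2:5] <- 2L
  nc2 <- neighbor_counts(label_image(chain2))
  expect_true(nc2$is_marginal[nc2$index == 2L])

  # symmetry / handshake on a voronoi phantom
  ph <- generate_leaf_stack(leaf_phantom_params(seed = 42,
                                                pattern = "voronoi",
                                                n_cells = 25))
  pairs <- leafcut:::region_adjacency_pairs(unclass(ph$truth$cells))
  expect_true(all(pairs[, 1] < pairs[, 2]))
  ncv <- neighbor_counts(ph$truth$cells)
  expect_equal(sum(ncv$neighbor_count), 2L * nrow(pairs))
})

test_that("guard-mother-cell candidates: four neighbours, size index, flags", {
  li <- gmc_fixture()
  f <- compute_shape_features(li)
  nc <- f$neighbor_count[f$index == 5L]
  expect_equal(nc, 4L)
  cand <- flag_gmc_candidates(f, li)
  expect_equal(cand$cell_index, 5L)
  expect_equal(cand$left_sister_index, 4L)
  m <- f$area_um2[f$index == 5L]; s <- f$area_um2[f$index == 4L]
  expect_equal(cand$cell_size_index, m / (m + s))
  expect_false(cand$trichome_precursor)      # small cell, index < 0.5
  # index > 0.5 flags a trichome precursor
  f2 <- f
  f2$area_um2[f2$index == 5L] <- 1.5 * f2$area_um2[f2$index == 4L]
  cand2 <- flag_gmc_candidates(f2, li)
  expect_true(cand2$trichome_precursor)
  # no 4-neighbour cells -> empty candidate list
  f3 <- f; f3$neighbor_count[] <- 6L
  expect_equal(nrow(flag_gmc_candidates(f3, li)), 0L)
})

test_that("feature invariants hold over many random synthetic regions", {
  set.seed(43)
  for (rep in 1:6) {
    ph <- generate_leaf_stack(leaf_phantom_params(
      seed = 100 + rep,
      pattern = if (rep %% 2) "rows" else "voronoi",
      n_cells = 24, n_rows = 4, n_cols = 6))
    f <- compute_shape_features(ph$truth$cells)
    expect_true(all(f$elongation >= 0 & f$elongation < 1))
    expect_true(all(f$circularity > 0 & f$circularity <= 1 + 0.02))
    expect_true(all(f$rectangularity > 0 & f$rectangularity <= 1 + 0.02))
    expect_true(all(f$lobeyness > 0 & f$lobeyness <= 1 + 1e-9))
    expect_true(all(f$length_um >= f$width_um & f$width_um > 0))
  }
})

test_that("features are consistent across rasterisation resolution", {
  blob <- function(scale) {
    n <- 40 * scale
    cx <- (n + 1) / 2
    y <- matrix(seq_len(n), n, n); x <- t(y)
    th <- atan2(y - cx, x - cx)
    r <- sqrt((y - cx)^2 + (x - cx)^2)
    m <- matrix(0L, n, n)
    m[r <= scale * (14 + 3 * sin(5 * th))] <- 2L
    label_image(pad_region(m), voxel_size = c(1, 1 / scale, 1 / scale))
  }
  f1 <- compute_shape_features(blob(1))
  f2 <- compute_shape_features(blob(2))
  expect_equal(f2$area_um2, f1$area_um2, tolerance = 0.02)
  expect_equal(f2$perimeter_um, f1$perimeter_um, tolerance = 0.03)
  expect_equal(f2$lobeyness, f1$lobeyness, tolerance = 0.03)
  expect_equal(f2$elongation, f1$elongation, tolerance = 0.02)
})

test_that("cells and nuclei match through the cylinder window", {
  # one cell filling the frame, one nucleus inside the window
  cells <- label_image(matrix(2L, 20, 20))
  nuc <- array(0L, c(20, 20, 12))
  nuc[9:12, 9:12, 5:7] <- 2L
  mask <- surface_mask(matrix(3, 20, 20), n_slices = 12)
  m <- match_cells_to_nuclei(cells, label_image(nuc), mask, depth = 6,
                             voxel_size = c(1, 1, 1))
  expect_equal(m$nucleus_index, 2L)
  # nucleus below the window is unmatched
  deep <- array(0L, c(20, 20, 12)); deep[9:12, 9:12, 11:12] <- 2L
  m2 <- match_cells_to_nuclei(cells, label_image(deep), mask, depth = 3,
                              voxel_size = c(1, 1, 1))
  expect_true(is.na(m2$nucleus_index))
  expect_equal(attr(m2, "unmatched_nuclei"), 2L)
  # two nuclei in one cylinder: larger inside-count wins
  two <- array(0L, c(20, 20, 12))
  two[5:10, 5:10, 4:7] <- 2L                   # larger
  two[14:16, 14:16, 4:6] <- 3L                 # smaller
  m3 <- match_cells_to_nuclei(cells, label_image(two), mask, depth = 6,
                              voxel_size = c(1, 1, 1))
  expect_equal(m3$nucleus_index, 2L)
  expect_equal(attr(m3, "unmatched_nuclei"), 3L)
  expect_error(match_cells_to_nuclei(cells, label_image(array(0L, c(5, 5, 3))),
                                     mask, 3), "shape mismatch")
})

test_that("generator nuclei volumes and pairing are fully recovered", {
  ph <- generate_leaf_stack(leaf_phantom_params(seed = 44))
  tr <- ph$truth
  vols <- compute_volumes(tr$nuclei, ph$grid$voxel_size)
  expect_equal(vols$voxel_count,
               unname(as.integer(tr$nucleus_voxels[as.character(vols$index)])))
  m <- build_surface_mask(ph$grid, "wall", min_intensity = 50)
  res <- match_cells_to_nuclei(tr$cells, tr$nuclei, m, depth = 8,
                               voxel_size = ph$grid$voxel_size)
  expect_true(all(!is.na(res$nucleus_index)))
  expect_equal(res$nucleus_index, res$cell_index)  # GT pairing is identity
})
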