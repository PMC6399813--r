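test_that("a single bright plane is recovered exactly", {
  arr <- array(0, c(16, 16, 12, 1))
  arr[, , 7, 1] <- 100
  g <- voxel_grid(arr)
  m <- build_surface_mask(g, 1L, min_intensity = 50, smooth_radius = 0)
  expect_true(all(m$z == 7))
  expect_true(all(m$raw_valid))
})

test_that("a tilted staircase surface is recovered within half a slice", {
  Y <- 64; X <- 64; Z <- 16
  arr <- array(0, c(Y, X, Z, 1))
  zx <- 2 + (seq_len(X) - 1) %/% 8           # z(x) = 2 + floor(x/8), 1-based
  for (x in seq_len(X)) arr[, x, zx[x], 1] <- 100
  g <- voxel_grid(arr)
  m <- build_surface_mask(g, 1L, min_intensity = 50, smooth_radius = 2)
  true_z <- matrix(zx, Y, X, byrow = TRUE)
  expect_lte(sqrt(mean((m$z - true_z)^2)), 0.5)
})

test_that("dark punctures are flagged invalid and filled from the nearest valid", {
  arr <- array(0, c(16, 16, 10, 1))
  arr[, , 5, 1] <- 80
  arr[6:9, 6:9, , 1] <- 0                    # all-zero punctures
  g <- voxel_grid(arr)
  m <- build_surface_mask(g, 1L, min_intensity = 40, smooth_radius = 0)
  expect_false(any(m$raw_valid[6:9, 6:9]))
  expect_true(all(m$valid))
  expect_true(all(m$z[6:9, 6:9] == 5))       # nearest-valid fill
  # ties at equal maxima resolve to the outermost (smallest z) slice
  arr2 <- array(0, c(8, 8, 6, 1))
  arr2[, , 3, 1] <- 50; arr2[, , 5, 1] <- 50
  m2 <- build_surface_mask(voxel_grid(arr2), 1L, smooth_radius = 0)
  expect_true(all(m2$z == 3))
  expect_error(build_surface_mask(g, 1L, min_intensity = 1e5),
               "empty surface")
  expect_error(build_surface_mask(g, "nope"), "not found")
})

test_that("trichome protrusions are closed away; small radii leave them", {
  flat <- surface_mask(matrix(10, 32, 32), n_slices = 20)
  expect_equal(remove_trichomes(flat, 4)$z, flat$z)

  z <- matrix(10, 40, 40)
  d <- sqrt(outer((1:40 - 20)^2, (1:40 - 20)^2, "+"))
  z[d <= 3] <- 4 + 2 * d[d <= 3]             # cone dipping to 4 (outward)
  m <- surface_mask(z, n_slices = 20)
  closed <- remove_trichomes(m, 5)
  expect_equal(closed$z, matrix(10, 40, 40))
  small <- remove_trichomes(m, 2)
  expect_lt(min(small$z), 10)                # bump persists
  # idempotence
  expect_equal(remove_trichomes(closed, 5)$z, closed$z)
})

test_that("virtual cut samples with interpolation and clamping", {
  Z <- 12
  arr <- array(rep(seq_len(Z), each = 8 * 8), c(8, 8, Z, 1))  # I(z) = z
  g <- voxel_grid(arr)
  flat3 <- surface_mask(matrix(3, 8, 8), n_slices = Z)
  expect_true(all(extract_virtual_cut(g, flat3, 1L, 0)$intensity == 3))
  expect_true(all(extract_virtual_cut(g, flat3, 1L, 2.5)$intensity == 5.5))
  flat10 <- surface_mask(matrix(10, 8, 8), n_slices = Z)
  expect_true(all(extract_virtual_cut(g, flat10, 1L, 20)$intensity == Z))
  expect_error(extract_virtual_cut(g, flat3, 1L, -1), ">= 0")
  # monotone in depth for intensities increasing in z
  d1 <- extract_virtual_cut(g, flat3, 1L, 1)$intensity
  d2 <- extract_virtual_cut(g, flat3, 1L, 4)$intensity
  expect_true(all(d2 >= d1))
})

test_that("depth-0 cut returns each puncture's maximum when unique", {
  set.seed(9)
  ph <- generate_leaf_stack(leaf_phantom_params(seed = 9))
  m <- build_surface_mask(ph$grid, "wall", min_intensity = 50,
                          smooth_radius = 0)
  cut0 <- extract_virtual_cut(ph$grid, m, "wall", 0)
  wall <- grid_channel(ph$grid, "wall")
  mx <- apply(wall, c(1, 2), max)
  sel <- m$raw_valid
  expect_true(mean(abs(cut0$intensity[sel] - mx[sel]) < 1e-9) > 0.99)
})

test_that("the cut at wall depth reproduces the wall network image", {
  ph <- generate_leaf_stack(leaf_phantom_params(seed = 10))
  m <- build_surface_mask(ph$grid, "wall", min_intensity = 50,
                          smooth_radius = 2)
  cut <- extract_virtual_cut(ph$grid, m, "wall", depth = 2)
  truth_walls <- ph$truth$wall2d * 1
  expect_gt(cor(c(cut$intensity), c(truth_walls)), 0.95)
})

test_that("surface masks round-trip through float TIFF", {
  set.seed(13)
  m <- surface_mask(matrix(runif(64, 1, 19), 8), n_slices = 20)
  path <- withr::local_tempfile(fileext = ".tif")
  write_surface_mask(m, path)
  m2 <- read_surface_mask(path)
  expect_equal(m2$z, m$z, tolerance = 1e-6)
  expect_equal(m2$n_slices, 20L)
})
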