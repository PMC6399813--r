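test_that("stack write/read round-trips arrays and voxel metadata", {
  set.seed(11)
  g <- voxel_grid(array(sample(0:255, 16 * 16 * 8 * 2, TRUE),
                        c(16, 16, 8, 2)),
                  voxel_size = c(1.0, 0.5, 0.5),
                  channel_names = c("wall", "nucleus"))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(g, path)
  g2 <- read_stack(path)
  expect_true(all(g$data == g2$data))
  expect_equal(g2$voxel_size, c(dz = 1.0, dy = 0.5, dx = 0.5))
  expect_equal(g2$channel_names, c("wall", "nucleus"))
  expect_equal(dim(g2$data)[4], 2L)

  # continuous intensities survive through the scaled 32-bit path
  gf <- voxel_grid(array(runif(16 * 16 * 4) * 1000, c(16, 16, 4, 1)),
                   voxel_size = c(2, 1, 1))
  write_stack(gf, path)
  gf2 <- read_stack(path)
  expect_lt(max(abs(gf$data - gf2$data)), 1e-5 * 1000)
})

test_that("missing voxel metadata falls back to unit voxels with a warning", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(64), 8), path)   # foreign file, no sidecar
  expect_warning(g <- read_stack(path), "unit voxels")
  expect_equal(unname(g$voxel_size), c(1, 1, 1))
})

test_that("ragged stacks are rejected with the offending dimensions", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.5, 8, 8), matrix(0.5, 8, 6)), path,
                  reduce = FALSE)
  expect_error(read_stack(path), "ragged")
  tiff::writeTIFF(matrix(0.5, 8, 6), path)
  expect_error(read_stack(path, allow_nonsquare = FALSE), "non-square")
})

test_that("label images round-trip bit-exactly, 3D stacks page per slice", {
  set.seed(12)
  lab <- label_image(matrix(sample(c(0L, 1L, 2:9), 144, TRUE), 12),
                     voxel_size = c(1, 0.5, 0.5))
  path <- withr::local_tempfile(fileext = ".tif")
  write_label_image(lab, path)
  lab2 <- read_label_image(path)
  expect_identical(unclass(lab2)[, ], unclass(lab)[, ])

  zero <- label_image(matrix(0L, 6, 6))
  write_label_image(zero, path)
  expect_true(all(unclass(read_label_image(path)) == 0L))

  l3 <- label_image(array(sample(c(0L, 2L, 3L, 4L), 4 * 5 * 6, TRUE),
                          c(4, 5, 6)))
  write_label_image(l3, path)
  l32 <- read_label_image(path)
  expect_equal(dim(unclass(l32)), c(4L, 5L, 6L))
  expect_identical(c(unclass(l32)), c(unclass(l3)))

  expect_error(write_label_image(matrix(-1L, 3, 3), path), "non-negative")
})

test_that("feature tables export as sorted CSV with unit headers", {
  tab <- data.frame(index = c(4L, 2L, 3L),
                    area_um2 = c(400.123456, 112.9876543, 77.1),
                    lobeyness = c(0.81234567, 1, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  lines <- readLines(path)
  expect_length(lines, 4L)                      # header + 3 records
  expect_match(lines[1], "area_um2")
  back <- read_feature_table(path)
  expect_equal(back$index, c(2L, 3L, 4L))       # sorted by index
  expect_equal(back$area_um2, signif(tab$area_um2[order(tab$index)], 6))

  write_feature_table(tab[0, ], path)
  expect_length(readLines(path), 1L)            # header only
})

test_that("combine_channels is a clipped linear map over channels", {
  a <- array(0, c(6, 6, 3, 2))
  a[, , , 1] <- 10; a[, , , 2] <- 30
  g <- voxel_grid(a, voxel_size = c(1, 1, 1))
  expect_equal(unique(c(combine_channels(g, c(1, 0))$data)), 10)
  expect_equal(unique(c(combine_channels(g, c(0.5, 0.5))$data)), 20)
  gg <- voxel_grid(array(rep(5, 6 * 6 * 3 * 2), c(6, 6, 3, 2)))
  expect_true(all(combine_channels(gg, c(1, -1))$data == 0))
  expect_error(combine_channels(g, c(1, 2, 3)), "per channel")

  # linearity before clipping: combine(a*w) == a*combine(w)
  set.seed(3)
  r <- voxel_grid(array(runif(6 * 6 * 3 * 2) * 50, c(6, 6, 3, 2)))
  w <- c(0.3, 0.6)
  expect_equal(combine_channels(r, 2 * w)$data,
               2 * combine_channels(r, w)$data)
})

test_that("stitching reconstructs a split image and recovers jittered offsets", {
  set.seed(21)
  base <- array(runif(96 * 96 * 4) * 100, c(96, 96, 4, 1))
  # structured content so correlation has something to lock onto
  tex <- 200 * outer(sin(1:96 / 5), cos(1:96 / 7))^2
  for (z in 1:4) base[, , z, 1] <- base[, , z, 1] + tex
  gb <- voxel_grid(base, c(1, 1, 1))
  cutq <- function(ys, xs) voxel_grid(base[ys, xs, , , drop = FALSE],
                                      c(1, 1, 1))
  # 2 x 2 tiles of 56 px with 16 px overlaps
  tiles <- list(cutq(1:56, 1:56), cutq(1:56, 41:96),
                cutq(41:96, 1:56), cutq(41:96, 41:96))
  true_off <- rbind(c(1, 1), c(1, 41), c(41, 1), c(41, 41))
  mos <- stitch_frames(tile_set(tiles, true_off))
  expect_equal(dim(mos$data), dim(base))
  expect_equal(mos$data, base, tolerance = 1e-12)  # exact with true offsets

  jit <- true_off + rbind(c(0, 0), c(2, -2), c(-2, 2), c(2, 2))
  mos2 <- stitch_frames(tile_set(tiles, jit), refine = TRUE,
                        search_radius = 5)
  expect_equal(mos2$data, base, tolerance = 1e-12) # offsets recovered

  # two 64-wide tiles with a stated 16 px overlap -> 112 px mosaic
  wide <- array(runif(32 * 112 * 2) * 100, c(32, 112, 2, 1))
  t1 <- voxel_grid(wide[, 1:64, , , drop = FALSE], c(1, 1, 1))
  t2 <- voxel_grid(wide[, 49:112, , , drop = FALSE], c(1, 1, 1))
  m2 <- stitch_frames(tile_set(list(t1, t2), rbind(c(1, 1), c(1, 49))))
  expect_equal(dim(m2$data)[2], 112L)
  # pixels outside the overlap equal the source tiles
  expect_equal(m2$data[, 1:48, , ], wide[, 1:48, , ])
  expect_equal(m2$data[, 65:112, , ], wide[, 65:112, , ])

  bad <- voxel_grid(wide[, 1:32, 1:1, , drop = FALSE], c(1, 1, 1))
  expect_error(tile_set(list(t1, bad), rbind(c(1, 1), c(1, 20))),
               "z-depth")
})
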