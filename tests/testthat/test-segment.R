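test_that("two basins split by a ridge give two regions with a thin line", {
  img <- matrix(30, 20, 31)
  img[, 1:15] <- 20
  img[, 16] <- 100
  seg <- segment_watershed(img, segmentation_params("border",
                                                    dynamic_tolerance = 5))
  expect_equal(length(label_ids(seg)), 2L)
  expect_true(watershed_lines_are_thin(seg))
  # boundary runs along the ridge
  expect_true(all(unclass(seg)[, 16] == 1L))
  # tolerance above every ridge merges everything
  seg1 <- segment_watershed(img, segmentation_params("border",
                                                     dynamic_tolerance = 200))
  expect_equal(length(label_ids(seg1)), 1L)
  expect_error(
    segment_watershed(matrix(0, 5, 5),
                      segmentation_params("object",
                                          background_threshold = 10)),
    "lower")
})

test_that("region indices are deterministic row-major and partition holds", {
  set.seed(31)
  ph <- generate_leaf_stack(leaf_phantom_params(seed = 31))
  m <- build_surface_mask(ph$grid, "wall", min_intensity = 50)
  cut <- extract_virtual_cut(ph$grid, m, "wall", 2)
  seg1 <- segment_watershed(cut, segmentation_params("border",
                                                     dynamic_tolerance = 30))
  seg2 <- segment_watershed(cut, segmentation_params("border",
                                                     dynamic_tolerance = 30))
  expect_identical(unclass(seg1)[, ], unclass(seg2)[, ])
  ids <- label_ids(seg1)
  expect_equal(ids, seq_along(ids) + 1L)       # contiguous from 2
  expect_true(watershed_lines_are_thin(seg1))
  # background + boundary + regions tile the image
  expect_true(all(unclass(seg1) >= 0L))
})

test_that("object mode segments bright blobs against a dark background", {
  img <- matrix(5, 40, 40)
  d1 <- sqrt(outer((1:40 - 12)^2, (1:40 - 12)^2, "+"))
  d2 <- sqrt(outer((1:40 - 28)^2, (1:40 - 28)^2, "+"))
  img[d1 < 6] <- 200 - 5 * d1[d1 < 6]
  img[d2 < 6] <- 200 - 5 * d2[d2 < 6]
  seg <- segment_watershed(img, segmentation_params(
    "object", dynamic_tolerance = 20, background_threshold = 50))
  expect_equal(length(label_ids(seg)), 2L)
  expect_true(all(unclass(seg)[img < 50] %in% c(0L, 1L)))
  # min_size drops sub-resolution debris
  img[2, 2] <- 120
  seg2 <- segment_watershed(img, segmentation_params(
    "object", dynamic_tolerance = 20, background_threshold = 50))
  seg3 <- segment_watershed(img, segmentation_params(
    "object", dynamic_tolerance = 20, background_threshold = 50,
    min_size = 15))
  expect_equal(length(label_ids(seg2)), 3L)
  expect_equal(length(label_ids(seg3)), 2L)
})

test_that("marker count equals region count", {
  set.seed(32)
  for (k in 1:3) {
    img <- matrix(runif(900) * 50, 30, 30)
    img <- anisotropic_diffusion(img, diffusion_params(5, kappa = 100))
    seg <- segment_watershed(img, segmentation_params("border",
                                                      dynamic_tolerance = 2))
    relief <- img
    hm <- hminima_transform(relief, 2, 4L)
    mk <- leafcut:::regional_minima_labels(array(hm, c(dim(hm), 1L)), 4L)
    expect_equal(length(label_ids(seg)), max(mk))
  }
})

test_that("merging fuses adjacent regions and absorbs their separator", {
  img <- matrix(30, 20, 31); img[, 1:15] <- 20; img[, 16] <- 100
  seg <- segment_watershed(img, segmentation_params("border",
                                                    dynamic_tolerance = 5))
  merged <- merge_labels(seg, c(2L, 3L))
  expect_equal(length(label_ids(merged)), 1L)
  expect_equal(sum(unclass(merged) == 1L), 0L)
  expect_identical(unclass(merge_labels(seg, 2L))[, ], unclass(seg)[, ])

  chain <- matrix(0L, 8, 16)
  chain[2:7, 2:5] <- 2L; chain[2:7, 6] <- 1L
  chain[2:7, 7:10] <- 3L; chain[2:7, 11] <- 1L; chain[2:7, 12:15] <- 4L
  li <- label_image(chain)
  expect_error(merge_labels(li, c(2L, 4L)), "not mutually adjacent")
  expect_equal(length(label_ids(merge_labels(li, c(2L, 3L, 4L)))), 1L)
})

test_that("removing a region keeps shared watershed lines", {
  img <- matrix(30, 20, 31); img[, 1:15] <- 20; img[, 16] <- 100
  seg <- segment_watershed(img, segmentation_params("border",
                                                    dynamic_tolerance = 5))
  r <- remove_label(seg, 2L)
  expect_equal(label_ids(r), 3L)
  expect_true(any(unclass(r) == 1L))           # shared line persists
  r2 <- remove_label(r, 3L)
  expect_true(all(unclass(r2) == 0L))          # last region: all background
  expect_error(remove_label(seg, 99L), "not present")
  # re-measuring loses exactly one row
  f_all <- compute_shape_features(seg, c(1, 1, 1))
  f_one <- compute_shape_features(r, c(1, 1, 1))
  expect_equal(nrow(f_all) - nrow(f_one), 1L)
})

test_that("healing merges only 1-px-separated fragments, to a fixpoint", {
  blob <- matrix(0L, 12, 12)
  blob[3:10, 3:10] <- 2L
  blob[3:10, 7] <- 1L
  blob[blob == 2L & col(blob) > 7] <- 3L
  healed <- heal_fragmented_labels(label_image(blob))
  expect_equal(length(label_ids(healed)), 1L)
  expect_equal(sum(unclass(healed) == 1L), 0L)

  gap <- matrix(0L, 10, 14)
  gap[3:8, 2:5] <- 2L; gap[3:8, 9:13] <- 3L    # 3-px background gap
  expect_identical(unclass(heal_fragmented_labels(label_image(gap)))[, ],
                   gap)

  tri <- matrix(0L, 12, 20)
  tri[3:10, 2:18] <- 2L
  tri[3:10, 7] <- 1L; tri[3:10, 13] <- 1L
  tri[tri == 2L & col(tri) > 7 & col(tri) < 13] <- 3L
  tri[tri == 2L & col(tri) > 13] <- 4L
  healed3 <- heal_fragmented_labels(label_image(tri))
  expect_equal(length(label_ids(healed3)), 1L)  # fixpoint over two seams
  # idempotent at fixpoint
  expect_identical(unclass(heal_fragmented_labels(healed3))[, ],
                   unclass(healed3)[, ])
})

test_that("healing never merges across separations wider than one pixel", {
  set.seed(33)
  for (rep in 1:25) {
    w <- sample(2:4, 1)                        # separation width >= 2
    m <- matrix(0L, 14, 20 + w)
    m[3:12, 3:9] <- 2L
    m[3:12, 10:(9 + w)] <- 1L                  # wide boundary band
    m[3:12, (10 + w):(18 + w)] <- 3L
    healed <- heal_fragmented_labels(label_image(m))
    expect_equal(length(label_ids(healed)), 2L)
  }
  for (rep in 1:25) {
    m <- matrix(0L, 14, 22)
    m[3:12, 3:9] <- 2L
    m[3:12, 10] <- 1L                          # exactly 1 px
    m[3:12, 11:19] <- 3L
    healed <- heal_fragmented_labels(label_image(m))
    expect_equal(length(label_ids(healed)), 1L)
  }
})

test_that("group assignments propagate to the feature table", {
  chain <- matrix(0L, 8, 16)
  chain[2:7, 2:5] <- 2L; chain[2:7, 6] <- 1L
  chain[2:7, 7:10] <- 3L; chain[2:7, 11] <- 1L; chain[2:7, 12:15] <- 4L
  li <- label_image(chain, voxel_size = c(1, 1, 1))
  li <- group_labels(li, list("2" = "rowA", "3" = "rowA"))
  f <- compute_shape_features(li)
  expect_equal(f$group[f$index %in% c(2L, 3L)], c("rowA", "rowA"))
  expect_equal(f$group[f$index == 4L], "")
  expect_warning(group_labels(li, list("2" = "a", "2" = "b")), "last one")
  expect_error(group_labels(li, list("9" = "x")), "unknown region")
})
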