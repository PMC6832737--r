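mk_img <- function(r, g, b) {
  # build an h x w x 3 array from matrices or scalars
  if (is.matrix(r)) dims <- dim(r) else dims <- c(1, 1)
  array(c(matrix(r, dims[1], dims[2]), matrix(g, dims[1], dims[2]),
          matrix(b, dims[1], dims[2])), dim = c(dims, 3))
}

test_that("ExG matches hand-computed values and handles edge pixels", {
  p <- segmentation_params()
  expect_equal(compute_exg(mk_img(100, 100, 100), p)[1, 1], 0)
  expect_equal(compute_exg(mk_img(0, 255, 0), p)[1, 1], 2)
  expect_equal(compute_exg(mk_img(50, 150, 100), p)[1, 1], 0.5)
  expect_equal(compute_exg(mk_img(0, 0, 0), p)[1, 1], 0)  # zero-sum pixel
  expect_error(compute_exg(matrix(1, 3, 3), p), "3-band")
  # equal normalizers cancel: bit-depth result reproduced on raw DN ratio
  set.seed(2)
  img <- array(sample(0:255, 60, TRUE), dim = c(4, 5, 3))
  ex <- compute_exg(img, p)
  raw <- (2 * img[, , 2] - img[, , 1] - img[, , 3]) /
    pmax(img[, , 1] + img[, , 2] + img[, , 3], 1e-12)
  expect_equal(ex, raw, tolerance = 1e-12)
})

test_that("ExG is scale-invariant under per-band-maximum normalization", {
  set.seed(3)
  img <- array(runif(300, 10, 200), dim = c(10, 10, 3))
  p <- segmentation_params(normalization = "per_band_image_max")
  expect_equal(compute_exg(img, p), compute_exg(img * 0.37, p),
               tolerance = 1e-12)
})

test_that("binarization is strict at the threshold", {
  p <- segmentation_params()
  exg <- matrix(c(0.05, 0.1, 0.15, 0.5), 2, 2)
  expect_identical(binarize_exg(exg, p),
                   matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  expect_identical(binarize_exg(matrix(0, 3, 3), p), matrix(FALSE, 3, 3))
})

test_that("object extraction counts area, perimeter and centroid correctly", {
  m <- matrix(FALSE, 7, 7)
  m[3:5, 3:5] <- TRUE  # 3x3 solid square
  obj <- extract_objects(m, segmentation_params())
  expect_equal(nrow(obj), 1L)
  expect_equal(obj$area_px, 9L)
  expect_equal(obj$perimeter_px, 8L)  # all but the centre pixel
  expect_equal(obj$centroid_col, 3)   # 0-based centre
  expect_equal(obj$centroid_row, 3)
  expect_equal(nrow(extract_objects(matrix(FALSE, 5, 5),
                                    segmentation_params())), 0L)
})

test_that("relative filters use pre-filter means and spare the largest", {
  # areas {200, 200, 20}: mean 140, threshold 42 -> the 20 px object goes
  m <- matrix(FALSE, 40, 80)
  m[2:11, 2:21] <- TRUE    # 200 px
  m[20:29, 30:49] <- TRUE  # 200 px
  m[35:38, 60:64] <- TRUE  # 20 px
  obj <- extract_objects(m, segmentation_params())
  expect_equal(sort(obj$area_px), c(20L, 200L, 200L))
  kept <- filter_objects(obj, segmentation_params(shape_filter_mode =
                                                    "thin_object"))
  expect_equal(sort(kept$area_px), c(200L, 200L))
  # all at the mean: nothing removed on area
  m2 <- matrix(FALSE, 30, 30)
  m2[2:6, 2:6] <- TRUE; m2[12:16, 12:16] <- TRUE; m2[22:26, 22:26] <- TRUE
  obj2 <- extract_objects(m2, segmentation_params())
  expect_equal(nrow(filter_objects(obj2, segmentation_params())), 3L)
  # a single object never removes itself
  one <- extract_objects(matrix(TRUE, 3, 3), segmentation_params())
  expect_equal(nrow(filter_objects(one, segmentation_params())), 1L)
  # property: the largest-area object always survives
  set.seed(9)
  for (i in 1:20) {
    mm <- matrix(runif(50 * 50) < 0.3, 50, 50)
    o <- extract_objects(mm, segmentation_params())
    if (!nrow(o)) next
    f <- filter_objects(o, segmentation_params())
    expect_true(max(o$area_px) %in% f$area_px)
    expect_lte(nrow(f), nrow(o))
  }
})

test_that("shape filter direction follows the configured mode", {
  # one compact blob among thin lines: literal mode removes the *compact*
  # (low perimeter/area) object when its ratio < 0.3 x mean ratio
  m <- matrix(FALSE, 40, 40)
  m[5:24, 5:24] <- TRUE       # 400 px compact, P/A = 76/400 = 0.19
  m[30, 2:39] <- TRUE         # thin line, P/A = 1
  m[35, 2:39] <- TRUE         # thin line, P/A = 1
  obj <- extract_objects(m, segmentation_params())
  lit <- filter_objects(obj, segmentation_params(filter_factor = 0.5,
                                                 shape_filter_mode =
                                                   "literal_less_than"))
  expect_false(400L %in% lit$area_px)
  thin <- filter_objects(obj, segmentation_params(filter_factor = 0.5,
                                                  shape_filter_mode =
                                                    "thin_object"))
  expect_true(400L %in% thin$area_px)
  expect_false(any(thin$area_px == 38L))
})

test_that("dilation merging joins fragments and conserves original pixels", {
  # two 5x5 squares, 4 px horizontal gap: dilation 10 merges into area 50
  m <- matrix(FALSE, 20, 30)
  m[5:9, 5:9] <- TRUE
  m[5:9, 14:18] <- TRUE
  obj <- extract_objects(m, segmentation_params())
  expect_equal(nrow(obj), 2L)
  merged <- merge_fragments(obj, segmentation_params(dilation_size = 10))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$area_px, 50L)
  # 30 px apart: stays two objects under dilation 10
  m2 <- matrix(FALSE, 20, 60)
  m2[5:9, 5:9] <- TRUE
  m2[5:9, 40:44] <- TRUE
  obj2 <- extract_objects(m2, segmentation_params())
  merged2 <- merge_fragments(obj2, segmentation_params(dilation_size = 10))
  expect_equal(nrow(merged2), 2L)
  expect_equal(merged2$area_px, c(25L, 25L))
  # isolated object: idempotent
  one <- extract_objects(matrix(c(rep(FALSE, 12), rep(TRUE, 4),
                                  rep(FALSE, 20)), 6, 6),
                         segmentation_params())
  m1 <- merge_fragments(one, segmentation_params())
  expect_equal(m1$area_px, one$area_px)
  expect_equal(m1$centroid_col, one$centroid_col)
})

test_that("merging never increases count and conserves filtered pixels", {
  set.seed(14)
  for (i in 1:10) {
    mm <- matrix(runif(60 * 60) < 0.25, 60, 60)
    o <- extract_objects(mm, segmentation_params())
    f <- filter_objects(o, segmentation_params())
    if (!nrow(f)) next
    mg <- merge_fragments(f, segmentation_params(dilation_size = 4))
    expect_lte(nrow(mg), nrow(f))
    expect_equal(sum(mg$area_px), sum(f$area_px))
  }
})

test_that("full detection chain finds simulated plants at truth positions", {
  cam <- test_camera()
  sc <- simulate_scene(clean_plan(8), cam)
  det <- detect_plants(sc$image, cam, test_seg())
  expect_equal(nrow(det), nrow(sc$truth))
  # corrected centroids pair off with truth within the match tolerance
  m <- match_detections(data.frame(id = det$label, x = det$x, y = det$y),
                        sc$truth, 0.05)
  expect_equal(m$TP, nrow(sc$truth))
  # all-soil image -> no detections
  p0 <- scene_plan(weed_density = 0, rng_seed = 2)
  sc0 <- render_scene(plan_scene(p0)[0, ], cam, p0)
  expect_equal(nrow(detect_plants(sc0$image, cam, test_seg())), 0L)
})

test_that("a fragmented plant is reassembled into one object", {
  # three fragments within dilation reach -> one plant
  img <- array(0, dim = c(40, 40, 3))
  img[, , 1] <- 120; img[, , 2] <- 90; img[, , 3] <- 60  # soil
  green <- function(r, c) {
    img[r, c, 1] <<- 60; img[r, c, 2] <<- 140; img[r, c, 3] <<- 55
  }
  green(10:14, 10:13)
  green(10:14, 17:20)   # 3 px gap
  green(18:21, 12:16)   # 3 px gap below
  cam <- camera_model(4, 78.8, 40, 40, 0.1)
  det <- detect_plants(img, cam, segmentation_params(dilation_size = 5))
  expect_equal(nrow(det), 1L)
})
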