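test_that("median projection reduces to per-pixel medians", {
  set.seed(20)
  v <- array(runif(6 * 5 * 5), dim = c(6, 5, 5))
  st <- image_stack(v, pixel_size = 1)
  # odd window
  m3 <- median_projection(st, start_slice = 2, n = 3)
  expect_equal(m3, apply(v[, , 2:4], c(1, 2), median))
  # even window (mean of the middle order statistics)
  m4 <- median_projection(st, start_slice = 1, n = 4)
  expect_equal(m4, apply(v[, , 1:4], c(1, 2), median))
  # default centers the window
  md <- median_projection(st, n = 4)
  expect_equal(md, apply(v[, , 1:4], c(1, 2), median))
  expect_error(median_projection(st, n = 6), "exceeds")
  expect_error(median_projection(st, start_slice = 4, n = 3), "exceeds")
})

test_that("median projection suppresses single-slice outliers", {
  v <- array(10, dim = c(8, 8, 4))
  v[4, 4, 2] <- 1000   # a bright fleck in one slice only
  st <- image_stack(v, pixel_size = 1)
  expect_equal(median_projection(st, n = 4)[4, 4], 10)
})

test_that("difference of Gaussians responds to soma-scale blobs", {
  img <- matrix(0, 64, 64)
  img <- draw_disk(img, 32, 32, 6, value = 100)  # soma-like
  img[10, 10:30] <- 100                          # thin process
  dog <- dog_filter(img, sigma1 = 4, pixel_size = 1)
  expect_gt(dog[32, 32], 3 * dog[10, 20])
  expect_equal(dim(dog), dim(img))
})

test_that("CLAHE preserves the intensity range and warns on tiny images", {
  set.seed(21)
  img <- matrix(runif(256 * 256, 0, 50), 256, 256)
  eq <- clahe_norm(img, tile = 64, clip = 2)
  expect_equal(dim(eq), dim(img))
  expect_gte(min(eq), min(img) - 1e-9)
  expect_lte(max(eq), max(img) + 1e-9)
  expect_warning(clahe_norm(img[1:32, 1:32], tile = 128), "global")
  # constant image passes through unchanged
  expect_equal(clahe_norm(matrix(5, 64, 64)), matrix(5, 64, 64))
})

test_that("automatic thresholds separate a bimodal image", {
  set.seed(22)
  img <- matrix(rnorm(10000, 10, 2), 100, 100)
  img[30:60, 30:60] <- rnorm(31 * 31, 60, 2)
  for (m in c("isodata", "otsu")) {
    mask <- auto_threshold(img, method = m)
    t0 <- attr(mask, "threshold")
    expect_true(t0 > 20 && t0 < 50)
    # foreground is essentially the bright square
    expect_gt(mean(mask[30:60, 30:60]), 0.99)
    expect_lt(mean(mask[1:20, ]), 0.01)
  }
  expect_warning(m0 <- auto_threshold(matrix(3, 10, 10)), "constant")
  expect_true(all(m0 == 0))
})

test_that("watershed separates touching disks and preserves the mask", {
  img <- matrix(0, 80, 80)
  img <- draw_disk(img, 30, 40, 9)
  img <- draw_disk(img, 47, 40, 9)   # centers 17 px apart: blobs touch
  lab <- watershed_split(img)
  expect_equal(max(lab), 2L)
  expect_equal(lab > 0, img > 0)
  expect_equal(max(watershed_split(matrix(0, 10, 10))), 0L)
})

test_that("particle filter accepts disks and rejects bars by circularity", {
  img <- matrix(0L, 100, 100)
  img <- draw_disk(img, 30, 30, 7)          # area ~154 um^2, circular
  img[60:63, 10:90] <- 1L                   # 4 x 81 bar: elongated
  lab <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(img)))), 100, 100)
  params <- segmentation_params(pixel_size = 1, min_area = 100,
                                max_area = 400, min_circularity = 0.6)
  rec <- particle_filter(lab, params)
  expect_equal(nrow(rec), 1L)
  expect_lt(abs(rec$x_um - 30), 1)
  expect_lt(abs(rec$y_um - 30), 1)
  # a hard-edged digital disk scores slightly below 1: the 8-connected
  # chain overestimates a smooth outline's length by a few percent
  expect_gt(rec$circularity, 0.8)
  expect_lte(rec$circularity, 1.05)
  # the bar is present before filtering and fails on circularity
  all_rec <- particle_filter(lab, segmentation_params(
    pixel_size = 1, min_area = 10, max_area = 1e5, min_circularity = 0))
  expect_equal(nrow(all_rec), 2L)
  expect_lt(min(all_rec$circularity), 0.6)
})

test_that("pixel centers map to origin + (index - 0.5) * pixel_size", {
  lab <- matrix(0L, 20, 20)
  lab[5, 8] <- 1L  # single pixel at index (5, 8)
  params <- segmentation_params(pixel_size = 2, min_area = 0.5,
                                max_area = 10, min_circularity = 0,
                                max_circularity = 10)
  rec <- particle_filter(lab, params, origin_um = c(100, 200))
  expect_equal(rec$x_um, 100 + 4.5 * 2)
  expect_equal(rec$y_um, 200 + 7.5 * 2)
  expect_equal(rec$area_um2, 4)
})

test_that("match_to_truth handles the canonical cases", {
  wl <- rect_window(c(0, 100), c(0, 100))
  set.seed(23)
  truth <- point_pattern(runif(10, 5, 95), runif(10, 5, 95), wl)
  ident <- data.frame(x_um = truth$x, y_um = truth$y)
  m <- match_to_truth(ident, truth, tolerance = 3)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$rmse_um, 0)
  spur <- rbind(ident, data.frame(x_um = 1:5, y_um = rep(1, 5)))
  m2 <- match_to_truth(spur, truth, tolerance = 3)
  expect_equal(m2$recall, 1)
  expect_equal(m2$precision, 10 / 15)
  shifted <- data.frame(x_um = truth$x + 0.5, y_um = truth$y)
  m3 <- match_to_truth(shifted, truth, tolerance = 3)
  expect_equal(m3$rmse_um, 0.5)
  m4 <- match_to_truth(ident[0, ], truth, tolerance = 3)
  expect_equal(m4$recall, 0)
})

test_that("segmentation chain is deterministic", {
  sc <- make_test_scene(501, n_cells = 15, side = 300)
  rec1 <- segment_cells(sc$stack, scene_seg_params())
  rec2 <- segment_cells(sc$stack, scene_seg_params())
  expect_identical(rec1, rec2)
  log <- attr(rec1, "stage_log")
  expect_equal(log$stage,
               c("mask_components", "watershed_labels", "selected_particles"))
  expect_gte(log$count[2], log$count[1])  # watershed only splits
  expect_lte(log$count[3], log$count[2])  # the filter only removes
})

test_that("detections are invariant to a global intensity scale", {
  sc <- make_test_scene(502, n_cells = 15, side = 300)
  rec1 <- segment_cells(sc$stack, scene_seg_params())
  scaled <- sc$stack
  scaled$voxels <- scaled$voxels * 7.3
  rec2 <- segment_cells(scaled, scene_seg_params())
  # detection count changes by < 2%
  expect_lte(abs(nrow(rec2) - nrow(rec1)), ceiling(0.02 * nrow(rec1)))
})

test_that("chain recovers a clean small scene", {
  sc <- make_test_scene(503, n_cells = 15, side = 300, clutter = 0)
  rec <- segment_cells(sc$stack, scene_seg_params())
  m <- match_to_truth(rec, sc$pattern, tolerance = 6)
  expect_gte(m$precision, 0.98)
  expect_gte(m$recall, 0.98)
  expect_lt(m$rmse_um, 1)
})
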