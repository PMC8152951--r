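th <- c(300, 200, 300, 300)
ann <- make_layered_annotation(th, width = 1000)

test_that("rectangular annotation thickness is exact", {
  expect_equal(cortical_thickness(ann), sum(th))
  for (i in seq_along(th))
    expect_equal(layer_thickness(ann, ann$layer_names[i]), th[i])
  bt <- boundary_thickness(ann, "L4_L5", "top_of_L23")
  expect_equal(bt$median_um, 500)
})

test_that("thickness is invariant under rigid motion", {
  theta <- 20 * pi / 180
  Rm <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  shift <- c(123.4, -56.7)
  rot <- lapply(ann$boundaries, function(b)
    sweep(b %*% t(Rm), 2, -shift))
  ann_r <- cortical_annotation(rot, ann$layer_names)
  expect_lt(abs(cortical_thickness(ann_r) - sum(th)), 0.1)
  for (i in seq_along(th))
    expect_lt(abs(layer_thickness(ann_r, ann$layer_names[i]) - th[i]), 0.1)
})

test_that("wavy-boundary thickness stays near nominal", {
  annw <- make_layered_annotation(th, waviness = 20, seed = 4L)
  # boundaries are perturbed by at most +/- 20 um, so the median matched
  # distance of each layer stays within 40 um of nominal
  for (i in seq_along(th))
    expect_lt(abs(layer_thickness(annw, annw$layer_names[i]) - th[i]), 40)
})

test_that("layer assignment partitions in-ROI points exactly", {
  set.seed(3)
  x <- runif(500, 0, 1000); y <- runif(500, 0, 1100)
  lab <- assign_layers(x, ann, y = y)
  inside <- y <= sum(th)
  expect_true(all(lab[!inside] == "outside"))
  expect_true(all(lab[inside] %in% ann$layer_names))
  # every inside point belongs to exactly one layer; counts partition
  counts <- table(factor(lab[inside], levels = ann$layer_names))
  expect_equal(sum(counts), sum(inside))
})

test_that("points on a boundary go to the layer above (toward the pia)", {
  # y = 300 is the L2/3-L4 border; y = 0 the top of the first layer
  lab <- assign_layers(c(500, 500, 500, 500), ann,
                       y = c(0, 300, 500, 1100))
  expect_equal(lab, c("L2/3", "L2/3", "L4", "L6"))
})

test_that("region areas in mm^2 sum over layers to the ROI area", {
  areas <- vapply(ann$layer_names, function(l) region_area(ann, l),
                  numeric(1))
  expect_equal(unname(areas), 1000 * th / 1e6)
  expect_equal(sum(areas), region_area(ann))
  annw <- make_layered_annotation(th, waviness = 25, seed = 8L)
  areasw <- vapply(annw$layer_names, function(l) region_area(annw, l),
                   numeric(1))
  expect_equal(sum(areasw), region_area(annw))
})

test_that("laminar summary is consistent: counts, densities, fractions", {
  p <- sample_layered_pattern(ann, c(40, 30, 120, 40), seed = 6L)
  ls <- laminar_summary(p, ann)
  expect_equal(ls$layer, c(ann$layer_names, "total"))
  k <- length(th)
  expect_equal(sum(ls$count[1:k]), ls$count[k + 1])
  expect_equal(sum(ls$fraction[1:k]), 1)
  expect_equal(ls$density, ls$count / ls$area_mm2)
  expect_equal(ls$fraction[1:k], ls$count[1:k] / ls$count[k + 1])
})

test_that("empty ROI yields NA fractions, zero densities", {
  empty <- point_pattern(numeric(0), numeric(0), annotation_window(ann))
  ls <- laminar_summary(empty, ann)
  expect_true(all(is.na(ls$fraction)))
  expect_true(all(ls$count == 0))
  expect_true(all(ls$density == 0))
})
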