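# Shared synthetic-scene machinery for segmentation tests.
#
# Scenes are built by dart throwing: soma centers are drawn uniformly and
# rejected until all pairs are at least 2 * soma_radius + 4 um apart, so
# somata never overlap (the regime the detection-quality guarantees are
# stated for). Rendered scenes are cached per parameter set because
# rendering dominates test runtime.

.scene_cache <- new.env(parent = emptyenv())

make_test_scene <- function(seed, n_cells = 50, side = 500, clutter = 800,
                            snr = 18, nz = 4L) {
  key <- paste(seed, n_cells, side, clutter, snr, nz, sep = "_")
  if (!is.null(.scene_cache[[key]])) return(.scene_cache[[key]])
  set.seed(seed)
  w <- rect_window(c(0, side), c(0, side))
  R <- 6
  margin <- 15
  min_d2 <- (2 * R + 4)^2
  xs <- ys <- numeric(0)
  while (length(xs) < n_cells) {
    x <- runif(1, margin, side - margin)
    y <- runif(1, margin, side - margin)
    if (length(xs) == 0 || min((xs - x)^2 + (ys - y)^2) > min_d2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  pat <- point_pattern(xs, ys, w)
  rs <- render_spec(soma_radius = R, psf_sigma = 1, peak_intensity = 100,
                    background_level = 10, noise_sd = 90 / snr,
                    clutter_density = clutter, pixel_size = 1,
                    z_slices = nz, z_interval = 2, seed = seed + 5000L)
  sc <- render_scene(pat, render = rs)
  .scene_cache[[key]] <- sc
  sc
}

# Segmentation configuration matched to the rendered scenes: somata are
# ideal disks of radius 6 um, so the area gate brackets the blob areas the
# DoG + blur chain produces (observed 108-317 um^2) and the circularity
# floor sits between elongated clutter clumps (<= ~0.6) and rendered
# somata (>= ~0.84). CLAHE clip 1.5: on these low-dynamic-range scenes
# stronger equalization amplifies cell-free background tiles and
# destabilizes the ISODATA threshold.
scene_seg_params <- function() {
  segmentation_params(pixel_size = 1, clahe_clip = 1.5,
                      min_area = 100, max_area = 700,
                      min_circularity = 0.6)
}

# Draw a filled disk into a matrix (for particle-shape unit tests).
draw_disk <- function(mat, cx, cy, r, value = 1) {
  ix <- pmax(1, floor(cx - r - 1)):pmin(nrow(mat), ceiling(cx + r + 1))
  iy <- pmax(1, floor(cy - r - 1)):pmin(ncol(mat), ceiling(cy + r + 1))
  d2 <- outer((ix - cx)^2, (iy - cy)^2, "+")
  mat[ix, iy][d2 <= r^2] <- value
  mat
}
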