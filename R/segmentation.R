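#' Calibrated image stacks
#'
#' A single-channel 3-D fluorescence stack with spatial calibration.
#' Voxels are stored as an `[x, y, z]` array (image x rightward, y
#' downward with increasing cortical depth); `origin_um` is the physical
#' coordinate of the top-left pixel corner so detections can be mapped
#' back into annotation space.
#'
#' @param voxels numeric array `[x, y, z]` (a matrix is treated as one
#'   slice); finite, non-negative.
#' @param pixel_size um per pixel.
#' @param z_interval um between optical slices.
#' @param channel_name marker label carried through to detections.
#' @param origin_um physical (x, y) of the array origin (um).
#' @export
image_stack <- function(voxels, pixel_size, z_interval = 2,
                        channel_name = "unknown", origin_um = c(0, 0)) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  stopifnot(length(dim(voxels)) == 3, pixel_size > 0, z_interval > 0)
  if (!all(is.finite(voxels)) || any(voxels < 0))
    stop("voxel intensities must be finite and non-negative")
  structure(list(voxels = voxels, pixel_size = pixel_size,
                 z_interval = z_interval, channel_name = channel_name,
                 origin_um = as.numeric(origin_um)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image stack '%s': %d x %d px, %d slices, %.3g um/px, dz = %.3g um\n",
              x$channel_name, d[1], d[2], d[3], x$pixel_size, x$z_interval))
  invisible(x)
}

#' Segmentation parameters
#'
#' Tunables of the soma-detection chain. `dog_sigma1` should sit slightly
#' below the radius of the smallest expected soma (default 0.8 x 5 um);
#' the second difference-of-Gaussians scale is fixed at twice the first.
#' Size and circularity bounds select soma-like particles; circularity is
#' `4 pi A / P^2` with an upper bound of 1.05 to tolerate discretization
#' of small disks.
#'
#' @param pixel_size um per pixel (required to convert um-valued
#'   parameters to pixels).
#' @param projection_slices slices in the median projection (default 4,
#'   an 8-um optical section at a 2-um z step).
#' @param dog_sigma1 first Gaussian scale (um).
#' @param clahe_tile CLAHE tile side (px, >= 8).
#' @param clahe_clip CLAHE clip limit.
#' @param threshold_method `"isodata"` (iterative intermeans, the common
#'   tool default) or `"otsu"`.
#' @param min_area,max_area particle area bounds (um^2).
#' @param min_circularity,max_circularity circularity bounds.
#' @export
segmentation_params <- function(pixel_size, projection_slices = 4L,
                                dog_sigma1 = 4, clahe_tile = 128L,
                                clahe_clip = 3,
                                threshold_method = c("isodata", "otsu"),
                                min_area = 40, max_area = 400,
                                min_circularity = 0.5,
                                max_circularity = 1.05) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(pixel_size > 0, dog_sigma1 > 0, min_area < max_area,
            min_circularity >= 0, max_circularity >= min_circularity,
            clahe_tile >= 8)
  structure(list(pixel_size = pixel_size,
                 projection_slices = as.integer(projection_slices),
                 dog_sigma1 = dog_sigma1, clahe_tile = as.integer(clahe_tile),
                 clahe_clip = clahe_clip, threshold_method = threshold_method,
                 min_area = min_area, max_area = max_area,
                 min_circularity = min_circularity,
                 max_circularity = max_circularity),
            class = "segmentation_params")
}

#' Median intensity projection
#'
#' Per-pixel median over `n` consecutive optical slices, producing a thin
#' optical section (4 slices at a 2-um step give 8 um) that suppresses
#' signal from cells outside the focal slab. Default takes the middle `n`
#' slices of the stack.
#'
#' @param stack an [image_stack()].
#' @param start_slice first slice of the projection window (1-based);
#'   default centers the window in the stack.
#' @param n number of slices.
#' @return 2-D matrix `[x, y]`.
#' @export
median_projection <- function(stack, start_slice = NULL, n = 4L) {
  nz <- dim(stack$voxels)[3]
  if (n > nz) stop("projection window exceeds available slices")
  if (is.null(start_slice)) start_slice <- (nz - n) %/% 2L + 1L
  if (start_slice + n - 1L > nz)
    stop("projection window exceeds available slices")
  sub <- stack$voxels[, , start_slice + seq_len(n) - 1L, drop = FALSE]
  d <- dim(sub)
  m <- matrix(sub, nrow = d[1] * d[2], ncol = d[3])
  # row-wise sort in one vectorized pass, then median from order statistics
  srt <- matrix(m[order(row(m), m)], nrow = nrow(m), byrow = TRUE)
  k <- d[3]
  med <- if (k %% 2L == 1L) srt[, (k + 1L) %/% 2L]
         else (srt[, k %/% 2L] + srt[, k %/% 2L + 1L]) / 2
  matrix(med, nrow = d[1], ncol = d[2])
}

#' Difference-of-Gaussians band-pass filter
#'
#' Subtracts a blur at `2 sigma1` from a blur at `sigma1`, enhancing
#' soma-scale blobs while suppressing both fine neurite-like processes and
#' slowly varying background.
#'
#' @param image 2-D matrix.
#' @param sigma1 first Gaussian scale in um.
#' @param pixel_size um per pixel.
#' @return filtered image (may contain negative values).
#' @export
dog_filter <- function(image, sigma1, pixel_size) {
  stopifnot(sigma1 > 0, pixel_size > 0)
  s1 <- sigma1 / pixel_size
  img <- EBImage::Image(image)
  b1 <- EBImage::gblur(img, sigma = s1)
  b2 <- EBImage::gblur(img, sigma = 2 * s1)
  as.matrix(b1 - b2)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Local contrast normalization correcting illumination and staining
#' brightness variability across the field, so a single global threshold
#' is meaningful. Falls back to global histogram equalization with a
#' warning when the tile does not fit the image.
#'
#' @param image 2-D matrix.
#' @param tile tile side in px (>= 8).
#' @param clip clip limit (>= 1 disables very little; common values 2-4).
#' @return equalized image scaled to the input range.
#' @export
clahe_norm <- function(image, tile = 128L, clip = 3) {
  stopifnot(tile >= 8)
  rng <- range(image)
  if (diff(rng) == 0) return(image)
  norm <- (image - rng[1]) / diff(rng)
  nx <- floor(dim(image)[1] / tile)
  ny <- floor(dim(image)[2] / tile)
  out <- if (nx < 2 || ny < 2) {
    warning("tile larger than image allows; using global equalization")
    as.matrix(EBImage::equalize(EBImage::Image(norm), range = c(0, 1)))
  } else {
    # pad to a tile multiple by edge replication, equalize, crop back
    d <- dim(norm)
    px <- ceiling(d[1] / nx) * nx
    py <- ceiling(d[2] / ny) * ny
    padded <- norm[c(seq_len(d[1]), rep(d[1], px - d[1])),
                   c(seq_len(d[2]), rep(d[2], py - d[2]))]
    eq <- as.matrix(EBImage::clahe(EBImage::Image(padded), nx = nx, ny = ny,
                                   limit = clip))
    eq[seq_len(d[1]), seq_len(d[2])]
  }
  out * diff(rng) + rng[1]
}

#' Automatic global threshold
#'
#' Computes one global threshold and returns the foreground mask
#' `image > t`. The default method is iterative intermeans (ISODATA), the
#' behavior behind common tools' default automatic threshold; Otsu is the
#' pluggable alternative. A constant image yields an empty mask with a
#' warning rather than an error.
#'
#' @param image 2-D matrix.
#' @param method `"isodata"` or `"otsu"`.
#' @return logical/integer matrix mask with attribute `"threshold"`.
#' @export
auto_threshold <- function(image, method = c("isodata", "otsu")) {
  method <- match.arg(method)
  rng <- range(image)
  if (diff(rng) == 0) {
    warning("constant image: no foreground")
    mask <- matrix(0L, nrow(image), ncol(image))
    attr(mask, "threshold") <- NA_real_
    return(mask)
  }
  t0 <- if (method == "isodata") {
    t <- mean(image)
    repeat {
      lo <- image[image <= t]; hi <- image[image > t]
      tn <- (mean(lo) + mean(hi)) / 2
      if (!is.finite(tn) || abs(tn - t) < 1e-9 * diff(rng)) break
      t <- tn
    }
    t
  } else {
    norm <- (image - rng[1]) / diff(rng)
    EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) * diff(rng) + rng[1]
  }
  mask <- (image > t0) + 0L
  attr(mask, "threshold") <- t0
  mask
}

#' Watershed separation of touching particles
#'
#' Distance-transform watershed on the binary mask: each convex blob
#' becomes one label and touching blobs are cut at their neck. The union
#' of labels equals the mask and the label count is at least the
#' connected-component count.
#'
#' @param mask binary matrix.
#' @param tolerance minimum distance-map depth between basins (px).
#' @return integer label matrix.
#' @export
watershed_split <- function(mask, tolerance = 1) {
  m <- EBImage::Image(mask > 0)
  if (!any(mask > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  dm <- EBImage::distmap(m)
  lab <- EBImage::watershed(dm, tolerance = tolerance)
  matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
}

# Perimeter of each labeled object by 8-connected boundary tracing
# (EBImage::ocontour): chain-code length with sqrt(2) diagonal steps plus
# pi, the half-pixel dilation term — the traced polygon runs through
# boundary pixel centers, half a pixel inside the true object outline.
label_perimeters <- function(labels) {
  oc <- EBImage::ocontour(EBImage::Image(labels))
  vapply(oc, function(ct) {
    if (nrow(ct) < 2) return(pi)  # isolated pixel
    dd <- sqrt(rowSums((ct - ct[c(2:nrow(ct), 1), ])^2))
    sum(dd) + pi
  }, numeric(1))
}

#' Select soma-like particles and emit cell records
#'
#' Keeps labels whose physical area and circularity (`4 pi A / P^2`,
#' perimeter from 8-connected boundary tracing) fall inside the
#' configured bounds and reports centroids in um. Pixel centers map to
#' `origin + (index - 0.5) * pixel_size`.
#'
#' @param labels integer label matrix from [watershed_split()].
#' @param params a [segmentation_params()].
#' @param origin_um physical coordinate of the array origin.
#' @param channel_name type label attached to the records.
#' @return data frame of cell records: `x_um`, `y_um`, `area_um2`,
#'   `circularity`, `type`.
#' @export
particle_filter <- function(labels, params, origin_um = c(0, 0),
                            channel_name = "unknown") {
  nlab <- max(labels)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), circularity = numeric(0),
                      type = character(0), stringsAsFactors = FALSE)
  if (nlab == 0) return(empty)
  idx <- which(labels > 0)
  lv <- labels[idx]
  nx <- nrow(labels)
  px <- (idx - 1L) %% nx + 1L
  py <- (idx - 1L) %/% nx + 1L
  area_px <- tabulate(lv, nbins = nlab)
  cx <- tapply(px, lv, mean)
  cy <- tapply(py, lv, mean)
  per <- label_perimeters(labels)
  keep_lab <- sort(unique(lv))
  area_um2 <- area_px[keep_lab] * params$pixel_size^2
  circ <- 4 * pi * area_px[keep_lab] / per[keep_lab]^2
  ok <- area_um2 >= params$min_area & area_um2 <= params$max_area &
    circ >= params$min_circularity & circ <= params$max_circularity
  data.frame(
    x_um = origin_um[1] + (as.numeric(cx)[ok] - 0.5) * params$pixel_size,
    y_um = origin_um[2] + (as.numeric(cy)[ok] - 0.5) * params$pixel_size,
    area_um2 = area_um2[ok], circularity = circ[ok],
    type = rep(channel_name, sum(ok)), stringsAsFactors = FALSE)
}

#' Full soma-detection chain
#'
#' Deterministic composition: median projection, difference-of-Gaussians
#' enhancement, CLAHE, automatic global threshold, distance-transform
#' watershed, size/circularity particle selection. The per-stage particle
#' counts are attached as attribute `"stage_log"` for review; detections
#' can be exported to CSV, hand-curated, and re-imported, which stands in
#' for an interactive quality-control pass.
#'
#' @param stack an [image_stack()].
#' @param params a [segmentation_params()].
#' @return data frame of cell records (see [particle_filter()]).
#' @export
segment_cells <- function(stack, params) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(params, "segmentation_params"))
  proj <- median_projection(stack, n = min(params$projection_slices,
                                           dim(stack$voxels)[3]))
  dog <- dog_filter(proj, params$dog_sigma1, params$pixel_size)
  eq <- clahe_norm(dog, tile = params$clahe_tile, clip = params$clahe_clip)
  mask <- auto_threshold(eq, method = params$threshold_method)
  labels <- watershed_split(mask)
  rec <- particle_filter(labels, params, origin_um = stack$origin_um,
                         channel_name = stack$channel_name)
  ncc <- max(matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(mask > 0)))), nrow(mask)), 0)
  attr(rec, "stage_log") <- data.frame(
    stage = c("mask_components", "watershed_labels", "selected_particles"),
    count = c(ncc, max(labels), nrow(rec)))
  rec
}

#' Match detections against ground truth
#'
#' Greedy one-to-one matching on sorted distances within a tolerance
#' (optimal enough for well-separated somata; the discipline is
#' documented, not assignment-optimal). Reports precision
#' (matched/detected), recall (matched/truth) and centroid RMSE over the
#' matched pairs.
#'
#' @param records detection data frame (`x_um`, `y_um`).
#' @param truth a [point_pattern()] of true centers.
#' @param tolerance maximum match distance (um).
#' @return list with `precision`, `recall`, `rmse_um`, `n_matched`.
#' @export
match_to_truth <- function(records, truth, tolerance) {
  stopifnot(tolerance > 0)
  nd <- nrow(records); nt <- truth$n
  if (nd == 0 || nt == 0)
    return(list(precision = if (nd == 0) NA_real_ else 0,
                recall = if (nt == 0) NA_real_ else 0,
                rmse_um = NA_real_, n_matched = 0L))
  d <- sqrt(outer(records$x_um, truth$x, "-")^2 +
              outer(records$y_um, truth$y, "-")^2)
  cand <- which(d <= tolerance, arr.ind = TRUE)
  usedD <- logical(nd); usedT <- logical(nt); dd <- numeric(0)
  if (nrow(cand) > 0) {
    cand <- cand[order(d[cand]), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!usedD[i] && !usedT[j]) {
        usedD[i] <- TRUE; usedT[j] <- TRUE
        dd <- c(dd, d[i, j])
      }
    }
  }
  m <- sum(usedD)
  list(precision = m / nd, recall = m / nt,
       rmse_um = if (m > 0) sqrt(mean(dd^2)) else NA_real_,
       n_matched = m)
}
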