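#' Rendering parameters for synthetic fluorescence stacks
#'
#' Controls how a ground-truth point pattern is turned into an image
#' stack resembling immunofluorescence microscopy: bright spherical somata
#' on a noisy background with fine neurite-like clutter. Defaults follow
#' typical cortical interneuron somata (10-15 um diameter) and a 2-um
#' optical z step.
#'
#' @param soma_radius soma radius (um).
#' @param psf_sigma Gaussian blur applied per slice (um); crude optical
#'   point-spread stand-in.
#' @param peak_intensity,background_level,noise_sd arbitrary intensity
#'   units; SNR is `(peak - background) / noise_sd`.
#' @param clutter_density short bright neurite-like segments per mm^2.
#' @param clutter_intensity peak intensity of clutter segments; defaults to
#'   60% of `peak_intensity`, reflecting that fine labeled processes stain
#'   dimmer than somata.
#' @param pixel_size um per pixel; must not exceed `soma_radius`.
#' @param z_slices number of optical slices (default 16: a 30-um stack at
#'   a 2-um interval).
#' @param z_interval um between slices.
#' @param seed integer seed for depths, clutter and noise.
#' @export
render_spec <- function(soma_radius = 6, psf_sigma = 1, peak_intensity = 100,
                        background_level = 10, noise_sd = 5,
                        clutter_density = 0,
                        clutter_intensity = 0.6 * peak_intensity,
                        pixel_size = 1,
                        z_slices = 16L, z_interval = 2, seed = 1L) {
  stopifnot(soma_radius > 0, pixel_size > 0, z_slices >= 1, z_interval > 0,
            psf_sigma >= 0, noise_sd >= 0, clutter_density >= 0)
  structure(list(soma_radius = soma_radius, psf_sigma = psf_sigma,
                 peak_intensity = peak_intensity,
                 background_level = background_level, noise_sd = noise_sd,
                 clutter_density = clutter_density,
                 clutter_intensity = clutter_intensity,
                 pixel_size = pixel_size,
                 z_slices = as.integer(z_slices), z_interval = z_interval,
                 seed = as.integer(seed)),
            class = "render_spec")
}

#' Render a point pattern into a synthetic fluorescence scene
#'
#' Each ground-truth cell becomes a bright sphere: its depth is sampled
#' uniformly over the stack, each optical slice shows the spherical
#' cross-section at that slice's depth (so the soma is brightest and
#' widest in the nearest slice), and every slice is blurred by the
#' point-spread sigma. Clutter is added as short bright line segments
#' (5-20 um long, one pixel wide, i.e. thinner than half a soma radius at
#' the default calibration) spanning a few consecutive slices, mimicking
#' fine labeled processes that the detection chain must reject. Gaussian
#' noise is added last and intensities are clamped at zero.
#'
#' @param pattern a [point_pattern()]; all points must lie in the
#'   annotation ROI.
#' @param annotation a [cortical_annotation()] defining the rendered
#'   field, or `NULL` to use the pattern's window.
#' @param render a [render_spec()].
#' @return A `synthetic_scene`: list with `pattern` (ground truth),
#'   `stack` (an [image_stack()]), `annotation`.
#' @export
render_scene <- function(pattern, annotation = NULL, render = render_spec()) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(render, "render_spec"))
  if (render$pixel_size > render$soma_radius)
    stop("pixel_size exceeds soma_radius: somata would be undetectable")
  w <- if (is.null(annotation)) pattern$window else annotation_window(annotation)
  if (!all(in_window(pattern$x, pattern$y, w)))
    stop("pattern extends outside the annotation ROI")
  ps <- render$pixel_size
  x0 <- w$xrange[1]; y0 <- w$yrange[1]
  nx <- ceiling(diff(w$xrange) / ps)
  ny <- ceiling(diff(w$yrange) / ps)
  nz <- render$z_slices
  depth <- (nz - 1L) * render$z_interval
  R <- render$soma_radius

  vox <- with_seed(render$seed, {
    v <- array(0, dim = c(nx, ny, nz))
    zcell <- if (nz == 1L) rep(0, pattern$n) else stats::runif(pattern$n, 0, depth)
    zs <- (seq_len(nz) - 1L) * render$z_interval
    for (i in seq_len(pattern$n)) {
      cxp <- (pattern$x[i] - x0) / ps + 0.5
      cyp <- (pattern$y[i] - y0) / ps + 0.5
      ix <- max(1L, floor(cxp - R / ps - 1)):min(nx, ceiling(cxp + R / ps + 1))
      iy <- max(1L, floor(cyp - R / ps - 1)):min(ny, ceiling(cyp + R / ps + 1))
      d2 <- outer((ix - cxp)^2, (iy - cyp)^2, "+") * ps^2
      for (s in seq_len(nz)) {
        dz <- zs[s] - zcell[i]
        if (abs(dz) >= R) next
        rz2 <- R^2 - dz^2
        v[ix, iy, s] <- v[ix, iy, s] +
          render$peak_intensity * (d2 <= rz2)
      }
    }
    # neurite-like clutter: thin bright segments over a few slices
    ncl <- stats::rpois(1, render$clutter_density * window_area(w) / 1e6)
    for (k in seq_len(ncl)) {
      len <- stats::runif(1, 5, 20)
      ang <- stats::runif(1, 0, pi)
      sx <- stats::runif(1, w$xrange[1], w$xrange[2])
      sy <- stats::runif(1, w$yrange[1], w$yrange[2])
      t <- seq(0, len, by = ps / 2)
      px <- round((sx + t * cos(ang) - x0) / ps + 0.5)
      py <- round((sy + t * sin(ang) - y0) / ps + 0.5)
      ok <- px >= 1 & px <= nx & py >= 1 & py <= ny
      if (!any(ok)) next
      # fine processes are ~1 um thick; crossing the optical slab
      # obliquely they show up in two adjacent slices, so the median
      # projection attenuates but does not remove them
      s0 <- sample.int(nz, 1)
      slices <- intersect(s0 + 0:1, seq_len(nz))
      for (s in slices)
        v[cbind(px[ok], py[ok], s)] <- v[cbind(px[ok], py[ok], s)] +
          render$clutter_intensity
    }
    if (render$psf_sigma > 0) {
      sp <- render$psf_sigma / ps
      for (s in seq_len(nz))
        v[, , s] <- as.matrix(EBImage::gblur(EBImage::Image(v[, , s]),
                                             sigma = sp))
    }
    v <- v + render$background_level
    if (render$noise_sd > 0)
      v <- v + stats::rnorm(length(v), 0, render$noise_sd)
    pmax(v, 0)
  })

  stack <- image_stack(vox, pixel_size = ps, z_interval = render$z_interval,
                       channel_name = if (!is.null(pattern$type) &&
                                          length(unique(pattern$type)) == 1)
                         pattern$type[1] else "synthetic",
                       origin_um = c(x0, y0))
  structure(list(pattern = pattern, stack = stack, annotation = annotation),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("synthetic scene:\n  ")
  print(x$pattern)
  cat("  ")
  print(x$stack)
  invisible(x)
}
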