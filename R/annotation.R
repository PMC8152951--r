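#' Layered cortical annotations
#'
#' An annotation is the manually drawn geometry of one region of interest:
#' a closed ROI polygon plus ordered layer-boundary polylines running from
#' the pial side downwards (e.g. `top_of_L23`, `L23_L4`, `L4_L5`, `L5_L6`,
#' `bottom_of_L6`). L1 carries no labeled interneurons and is excluded by
#' construction: the top boundary is the top of the first analyzed layer.
#' The y axis increases with cortical depth.
#'
#' @param boundaries named list of two-column matrices (x, y in um),
#'   ordered top to bottom; one more boundary than layers.
#' @param layer_names character vector of layer names, top to bottom.
#' @return A `cortical_annotation` object.
#' @export
cortical_annotation <- function(boundaries, layer_names) {
  stopifnot(is.list(boundaries), length(boundaries) == length(layer_names) + 1L)
  boundaries <- lapply(boundaries, function(b) {
    b <- as.matrix(b)
    stopifnot(ncol(b) == 2, nrow(b) >= 2)
    colnames(b) <- c("x", "y")
    if (b[1, 1] > b[nrow(b), 1]) b <- b[rev(seq_len(nrow(b))), ]  # left->right
    b
  })
  check_boundary_order(boundaries)
  top <- boundaries[[1]]
  bot <- boundaries[[length(boundaries)]]
  roi <- rbind(top, bot[rev(seq_len(nrow(bot))), ])
  structure(list(roi = roi, boundaries = boundaries,
                 layer_names = as.character(layer_names)),
            class = "cortical_annotation")
}

# Boundaries must not cross: at a dense shared x grid each must lie at or
# below its predecessor's depth ordering (y increases downward).
check_boundary_order <- function(boundaries) {
  xr <- range(unlist(lapply(boundaries, function(b) range(b[, 1]))))
  xs <- seq(xr[1], xr[2], length.out = 201)
  ys <- vapply(boundaries, function(b)
    stats::approx(b[, 1], b[, 2], xout = xs, rule = 2)$y, numeric(201))
  if (any(diff(t(ys)) < -1e-9))
    stop("layer boundaries cross; annotation is invalid")
  invisible(TRUE)
}

#' @export
print.cortical_annotation <- function(x, ...) {
  cat(sprintf("cortical annotation: %d layers (%s), ROI area %.4g mm^2\n",
              length(x$layer_names), paste(x$layer_names, collapse = ", "),
              region_area(x) ))
  invisible(x)
}

#' Generate a synthetic layered annotation
#'
#' Builds an ROI of the given width (default 1 mm, a typical manually drawn
#' field) partitioned into layers of the given nominal thicknesses by
#' boundary polylines. `waviness` adds a smooth random vertical perturbation
#' (sum of low-frequency sinusoids, peak amplitude `waviness` um) to each
#' interior boundary, mimicking hand-drawn undulating laminar borders;
#' `waviness = 0` gives straight horizontal boundaries. Perturbed
#' boundaries are regenerated if they would cross.
#'
#' @param layer_thicknesses numeric vector of layer thicknesses (um),
#'   ordered from the pial side down (e.g. L2/3, L4, L5, L6).
#' @param width ROI width (um).
#' @param waviness peak boundary perturbation amplitude (um).
#' @param seed integer seed.
#' @param layer_names layer names; defaults to the standard 4-layer set, or
#'   the pooled 3-layer perinatal set when 3 thicknesses are given.
#' @return a [cortical_annotation()].
#' @export
make_layered_annotation <- function(layer_thicknesses, width = 1000,
                                    waviness = 0, seed = 1L,
                                    layer_names = NULL) {
  stopifnot(all(layer_thicknesses > 0), width > 0, waviness >= 0)
  k <- length(layer_thicknesses)
  if (is.null(layer_names)) {
    layer_names <- if (k == 4) c("L2/3", "L4", "L5", "L6")
    else if (k == 3) c("L2-4", "L5", "L6")
    else paste0("layer", seq_len(k))
  }
  stopifnot(length(layer_names) == k)
  depths <- cumsum(c(0, layer_thicknesses))
  xs <- seq(0, width, length.out = max(41L, ceiling(width / 25) + 1L))
  min_gap <- min(layer_thicknesses)
  with_seed(seed, {
    for (attempt in 1:25) {
      ys <- lapply(seq_along(depths), function(i) {
        if (waviness == 0) return(rep(depths[i], length(xs)))
        f1 <- sample(1:2, 1); f2 <- sample(2:4, 1)
        ph <- stats::runif(2, 0, 2 * pi)
        w <- sin(2 * pi * f1 * xs / width + ph[1]) +
          0.5 * sin(2 * pi * f2 * xs / width + ph[2])
        depths[i] + waviness * w / max(abs(w))
      })
      ok <- all(vapply(seq_len(length(ys) - 1L), function(i)
        all(ys[[i + 1L]] - ys[[i]] > 0.05 * min_gap), logical(1)))
      if (ok) break
    }
    if (!ok) stop("could not generate non-crossing boundaries; reduce waviness")
    bnames <- boundary_names(layer_names)
    boundaries <- stats::setNames(
      lapply(ys, function(y) cbind(x = xs, y = y)), bnames)
    cortical_annotation(boundaries, layer_names)
  })
}

boundary_names <- function(layer_names) {
  s <- gsub("[^A-Za-z0-9]", "", layer_names)
  c(paste0("top_of_", s[1]),
    if (length(s) > 1)
      paste(s[-length(s)], s[-1], sep = "_"),
    paste0("bottom_of_", s[length(s)]))
}

#' Sample a layered inhomogeneous pattern
#'
#' Within each annotated layer, points are completely spatially random at
#' that layer's intensity, so expected layer counts are
#' `intensity * layer area`. Reproduces the laminar structure of labeled
#' interneuron populations (e.g. most cells in L5, none in L1).
#'
#' @param annotation a [cortical_annotation()].
#' @param per_layer_intensity cells per mm^2, one value per layer.
#' @param seed integer seed.
#' @return a [point_pattern()] with `layer` labels set, whose window is the
#'   ROI polygon.
#' @export
sample_layered_pattern <- function(annotation, per_layer_intensity, seed = 1L) {
  k <- length(annotation$layer_names)
  if (length(per_layer_intensity) != k)
    stop("need one intensity per layer (", k, ")")
  if (any(per_layer_intensity < 0)) stop("intensities must be >= 0")
  w <- annotation_window(annotation)
  with_seed(seed, {
    xs <- ys <- numeric(0); lab <- character(0)
    for (i in seq_len(k)) {
      poly <- layer_polygon(annotation, i)
      lw <- poly_window(poly[, 1], poly[, 2])
      mu <- per_layer_intensity[i] * window_area(lw) / 1e6
      n <- stats::rpois(1, mu)
      if (n > 0) {
        xy <- runif_in_window(n, lw)
        xs <- c(xs, xy[, 1]); ys <- c(ys, xy[, 2])
        lab <- c(lab, rep(annotation$layer_names[i], n))
      }
    }
    # nudge any point off the shared window border by numerical jitter
    keep <- in_window(xs, ys, w)
    point_pattern(xs[keep], ys[keep], w, layer = lab[keep])
  })
}

#' Observation window corresponding to an annotation ROI
#' @param annotation a [cortical_annotation()].
#' @export
annotation_window <- function(annotation) {
  poly_window(annotation$roi[, 1], annotation$roi[, 2])
}
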