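#' Resample a polyline at fixed arc-length spacing
#'
#' @param xy two-column matrix of vertices (um).
#' @param spacing target spacing (um); ignored if `n` is given.
#' @param n number of points, spread equally over the full arc length.
#' @return matrix of resampled points.
#' @keywords internal
resample_polyline <- function(xy, spacing = 1, n = NULL) {
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L < 2) stop("boundary shorter than 2 um")
  t <- if (is.null(n)) seq(0, L, by = spacing) else seq(0, L, length.out = n)
  cbind(x = stats::approx(s, xy[, 1], xout = t)$y,
        y = stats::approx(s, xy[, 2], xout = t)$y)
}

#' Thickness between two layer boundaries
#'
#' Implements the measuring-lines procedure: points are generated at 1-um
#' arc-length intervals along the lower boundary, the same number of points
#' is spread equally along the upper boundary, and the matched pairwise
#' distances form the thickness distribution, summarized by its median.
#' Cortical thickness is the distance from the bottom of the deepest layer
#' to the top of the most superficial one; each layer's thickness uses its
#' own bounding polylines.
#'
#' An all-pairs variant (every lower point against every upper point) is
#' available behind `all_pairs = TRUE` for sensitivity analysis; it
#' systematically exceeds the perpendicular gap and is not the default.
#'
#' @param annotation a [cortical_annotation()].
#' @param lower_boundary,upper_boundary boundary names present in the
#'   annotation; `lower` is the deeper one.
#' @param spacing sampling interval along the lower boundary (um).
#' @param all_pairs use all-pairs distances instead of matched pairs.
#' @return list with `median_um` and the full `distances_um` distribution.
#' @export
boundary_thickness <- function(annotation, lower_boundary, upper_boundary,
                               spacing = 1, all_pairs = FALSE) {
  lo <- annotation$boundaries[[lower_boundary]]
  up <- annotation$boundaries[[upper_boundary]]
  if (is.null(lo) || is.null(up)) stop("unknown boundary name")
  plo <- resample_polyline(lo, spacing = spacing)
  pup <- resample_polyline(up, n = nrow(plo))
  if (all_pairs) {
    d <- sqrt(outer(plo[, 1], pup[, 1], "-")^2 +
                outer(plo[, 2], pup[, 2], "-")^2)
    d <- as.numeric(d)
  } else {
    d <- sqrt((plo[, 1] - pup[, 1])^2 + (plo[, 2] - pup[, 2])^2)
  }
  list(median_um = stats::median(d), distances_um = d)
}

#' Cortical thickness of an annotation
#'
#' Median matched-pair distance from the bottom boundary to the top
#' boundary; see [boundary_thickness()].
#' @param annotation a [cortical_annotation()].
#' @export
cortical_thickness <- function(annotation) {
  b <- names(annotation$boundaries)
  boundary_thickness(annotation, b[length(b)], b[1])$median_um
}

#' Thickness of one layer
#' @param annotation a [cortical_annotation()].
#' @param layer layer name.
#' @export
layer_thickness <- function(annotation, layer) {
  i <- match(layer, annotation$layer_names)
  if (is.na(i)) stop("unknown layer: ", layer)
  b <- names(annotation$boundaries)
  boundary_thickness(annotation, b[i + 1L], b[i])$median_um
}

# Depth of boundary i interpolated at arbitrary x (um); constant
# extrapolation past the drawn ends.
boundary_depth_at <- function(annotation, i, x) {
  b <- annotation$boundaries[[i]]
  stats::approx(b[, 1], b[, 2], xout = x, rule = 2)$y
}

#' Assign each point to a cortical layer
#'
#' A point belongs to the layer whose bounding polylines enclose it
#' vertically (depth interpolated at the point's x). A point lying exactly
#' on a boundary is assigned to the layer above it (toward the pia); a
#' point on the top boundary belongs to the first layer. Points outside
#' the ROI get the label `"outside"`.
#'
#' @param x,y coordinates (um), or pass a [point_pattern()] as `x`.
#' @param annotation a [cortical_annotation()].
#' @return character vector of layer labels.
#' @export
assign_layers <- function(x, annotation, y = NULL) {
  if (inherits(x, "point_pattern")) { y <- x$y; x <- x$x }
  if (length(x) == 0) return(character(0))
  check_boundary_order(annotation$boundaries)
  nb <- length(annotation$boundaries)
  ys <- vapply(seq_len(nb), function(i) boundary_depth_at(annotation, i, x),
               numeric(length(x)))
  ys <- matrix(ys, nrow = length(x))
  xr <- range(annotation$roi[, 1])
  lab <- rep("outside", length(x))
  inx <- x >= xr[1] & x <= xr[2]
  for (i in seq_len(nb - 1L)) {
    top <- ys[, i]; bot <- ys[, i + 1L]
    hit <- if (i == 1L) inx & y >= top & y <= bot
           else inx & y > top & y <= bot
    lab[hit] <- annotation$layer_names[i]
  }
  lab
}

#' Polygon of one layer's region
#' @param annotation a [cortical_annotation()].
#' @param i layer index.
#' @return two-column vertex matrix.
#' @keywords internal
layer_polygon <- function(annotation, i) {
  top <- annotation$boundaries[[i]]
  bot <- annotation$boundaries[[i + 1L]]
  rbind(top, bot[rev(seq_len(nrow(bot))), ])
}

#' Planar area of the ROI or one layer
#'
#' Shoelace-formula area of the bounding polygon, in mm^2.
#' @param annotation a [cortical_annotation()].
#' @param layer layer name, or `NULL` for the whole ROI.
#' @export
region_area <- function(annotation, layer = NULL) {
  poly <- if (is.null(layer)) annotation$roi
  else {
    i <- match(layer, annotation$layer_names)
    if (is.na(i)) stop("unknown layer: ", layer)
    layer_polygon(annotation, i)
  }
  a <- abs(shoelace_area(poly[, 1], poly[, 2]))
  if (a <= 0) stop("degenerate region polygon")
  a / 1e6
}

#' Per-layer counts, areas, densities, fractions and thicknesses
#'
#' The laminar summary of one ROI: for each layer the cell count, the
#' area between its annotation lines (mm^2), the density (count / area,
#' cells per mm^2), the fraction of all in-ROI cells, and the median layer
#' thickness (um); plus a `total` row over the whole ROI. Fractions are
#' `NA` (not 0) when no cell is in the ROI. Points labeled `"outside"` are
#' excluded from every quantity.
#'
#' @param points a [point_pattern()] or data frame with `x_um`, `y_um`.
#' @param annotation a [cortical_annotation()].
#' @return data frame, one row per layer plus a total row.
#' @export
laminar_summary <- function(points, annotation) {
  if (is.data.frame(points)) {
    x <- points$x_um; y <- points$y_um
  } else { x <- points$x; y <- points$y }
  lab <- assign_layers(x, annotation, y = y)
  layers <- annotation$layer_names
  counts <- vapply(layers, function(l) sum(lab == l), numeric(1))
  areas <- vapply(layers, function(l) region_area(annotation, l), numeric(1))
  thick <- vapply(layers, function(l) layer_thickness(annotation, l),
                  numeric(1))
  total <- sum(counts)
  fr <- if (total > 0) counts / total else rep(NA_real_, length(counts))
  out <- data.frame(
    layer = c(layers, "total"),
    count = c(counts, total),
    area_mm2 = c(areas, region_area(annotation)),
    density = c(counts / areas, total / region_area(annotation)),
    fraction = c(fr, if (total > 0) 1 else NA_real_),
    thickness_um = c(thick, cortical_thickness(annotation)),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}
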