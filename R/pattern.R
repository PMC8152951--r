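#' Typed planar point patterns
#'
#' The central container: cell coordinates in micrometers inside an
#' observation window, optionally carrying a type label (e.g. marker
#' identity) and a layer label per point, plus an optional per-pattern
#' soma radius used by the double-positive rule.
#'
#' @param x,y point coordinates (um).
#' @param window a [rect_window()] or [poly_window()].
#' @param type optional character/factor label per point.
#' @param layer optional layer label per point.
#' @param soma_radius optional soma radius (um) for this pattern.
#' @return An object of class `point_pattern`: a list with elements `x`,
#'   `y`, `type`, `layer`, `window`, `soma_radius`, `n`.
#' @export
point_pattern <- function(x, y, window, type = NULL, layer = NULL,
                          soma_radius = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  if (!inherits(window, "cm_window")) stop("window must be a cm_window")
  if (length(x) > 0 && !all(in_window(x, y, window)))
    stop("all points must lie inside the window")
  if (!is.null(type)) {
    type <- as.character(type)
    stopifnot(length(type) == length(x))
  }
  if (!is.null(layer)) {
    layer <- as.character(layer)
    stopifnot(length(layer) == length(x))
  }
  structure(list(x = x, y = y, type = type, layer = layer, window = window,
                 soma_radius = soma_radius, n = length(x)),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points", x$n))
  if (!is.null(x$type)) {
    tb <- table(x$type)
    cat(" (", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  print(x$window)
  invisible(x)
}

#' @export
as.data.frame.point_pattern <- function(x, ...) {
  data.frame(x_um = x$x, y_um = x$y,
             type = if (is.null(x$type)) NA_character_ else x$type,
             layer = if (is.null(x$layer)) NA_character_ else x$layer,
             stringsAsFactors = FALSE)
}

# Subset a pattern, keeping the window.
subset_pattern <- function(p, idx) {
  point_pattern(p$x[idx], p$y[idx], p$window,
                type = if (!is.null(p$type)) p$type[idx],
                layer = if (!is.null(p$layer)) p$layer[idx],
                soma_radius = p$soma_radius)
}

# Indices of points of a given type; NULL type on the pattern means all
# points match the special type "all".
type_index <- function(p, type) {
  if (is.null(p$type)) {
    if (!identical(type, "all"))
      stop("pattern carries no type labels; use type = 'all'")
    seq_len(p$n)
  } else {
    which(p$type == type)
  }
}

#' Estimated overall intensity of a pattern
#'
#' Point count divided by window area, in cells per mm^2 ("the density of
#' the entire field" referenced by the pair correlation function).
#' @param p a `point_pattern`.
#' @param type optional type label; default uses all points.
#' @export
intensity_estimate <- function(p, type = NULL) {
  n <- if (is.null(type)) p$n else length(type_index(p, type))
  n / (window_area(p$window) / 1e6)
}
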