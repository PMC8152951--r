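#' Observation windows
#'
#' A window is the planar region inside which a point pattern is observed.
#' Two shapes are supported: an axis-aligned rectangle and a simple polygon.
#' All coordinates are in micrometers.
#'
#' @param xrange,yrange numeric length-2 vectors, window extent in um.
#' @return An object of class `cm_window`.
#' @examples
#' w <- rect_window(c(0, 1000), c(0, 1000))
#' window_area(w)   # 1e6 um^2 = 1 mm^2
#' @export
rect_window <- function(xrange, yrange) {
  stopifnot(length(xrange) == 2, length(yrange) == 2)
  if (diff(xrange) <= 0 || diff(yrange) <= 0)
    stop("invalid-spec: degenerate window (zero or negative extent)")
  structure(list(type = "rect", xrange = as.numeric(xrange),
                 yrange = as.numeric(yrange)),
            class = "cm_window")
}

#' @param x,y vertex coordinates (um) of a simple closed polygon, listed once
#'   (the closing edge is implicit).
#' @rdname rect_window
#' @export
poly_window <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  a <- shoelace_area(x, y)
  if (abs(a) <= 0) stop("invalid-spec: degenerate window (zero area)")
  if (a < 0) { x <- rev(x); y <- rev(y) }  # force counter-clockwise
  structure(list(type = "poly", x = as.numeric(x), y = as.numeric(y),
                 xrange = range(x), yrange = range(y)),
            class = "cm_window")
}

#' @export
print.cm_window <- function(x, ...) {
  cat(sprintf("window [%s]: x in [%.6g, %.6g] um, y in [%.6g, %.6g] um, area %.6g mm^2\n",
              x$type, x$xrange[1], x$xrange[2], x$yrange[1], x$yrange[2],
              window_area(x) / 1e6))
  invisible(x)
}

# Signed polygon area (shoelace); positive for counter-clockwise vertices.
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Window area in square micrometers
#' @param window a `cm_window`.
#' @export
window_area <- function(window) {
  if (window$type == "rect")
    diff(window$xrange) * diff(window$yrange)
  else
    abs(shoelace_area(window$x, window$y))
}

#' Test whether points fall inside a window
#'
#' Ray-casting point-in-polygon test; points exactly on the rectangle border
#' count as inside.
#' @param x,y point coordinates (um).
#' @param window a `cm_window`.
#' @return logical vector.
#' @export
in_window <- function(x, y, window) {
  if (window$type == "rect") {
    x >= window$xrange[1] & x <= window$xrange[2] &
      y >= window$yrange[1] & y <= window$yrange[2]
  } else {
    point_in_polygon(x, y, window$x, window$y)
  }
}

# Vectorized even-odd ray casting.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Uniform points in a window (rejection sampling for polygons).
runif_in_window <- function(n, window) {
  if (n == 0L)
    return(cbind(x = numeric(0), y = numeric(0)))
  if (window$type == "rect") {
    cbind(x = stats::runif(n, window$xrange[1], window$xrange[2]),
          y = stats::runif(n, window$yrange[1], window$yrange[2]))
  } else {
    out <- matrix(numeric(0), ncol = 2)
    while (nrow(out) < n) {
      m <- max(2L * (n - nrow(out)), 16L)
      cx <- stats::runif(m, window$xrange[1], window$xrange[2])
      cy <- stats::runif(m, window$yrange[1], window$yrange[2])
      keep <- in_window(cx, cy, window)
      out <- rbind(out, cbind(cx[keep], cy[keep]))
    }
    out <- out[seq_len(n), , drop = FALSE]
    colnames(out) <- c("x", "y")
    out
  }
}

#' Set covariance of a window
#'
#' Area of the intersection of the window with a translate of itself,
#' `|W n (W + v)|`, the denominator of the translation edge-correction
#' weight. Exact for rectangles; for polygons it is evaluated from an
#' FFT autocorrelation of a rasterized mask of the window (grid step
#' about 1/256 of the larger extent), interpolated at the requested shifts.
#'
#' @param window a `cm_window`.
#' @param dx,dy translation components (um), vectorized.
#' @return numeric vector of intersection areas (um^2).
#' @export
set_covariance <- function(window, dx, dy) {
  if (window$type == "rect") {
    a <- pmax(0, diff(window$xrange) - abs(dx))
    b <- pmax(0, diff(window$yrange) - abs(dy))
    return(a * b)
  }
  sc <- window_setcov_grid(window)
  # bilinear interpolation on the symmetric grid (setcov(v) = setcov(-v))
  adx <- pmin(abs(dx), max(sc$sx)); ady <- pmin(abs(dy), max(sc$sy))
  ix <- findInterval(adx, sc$sx, all.inside = TRUE)
  iy <- findInterval(ady, sc$sy, all.inside = TRUE)
  fx <- (adx - sc$sx[ix]) / diff(sc$sx)[1]
  fy <- (ady - sc$sy[iy]) / diff(sc$sy)[1]
  m <- sc$m
  v <- (1 - fx) * (1 - fy) * m[cbind(ix, iy)] +
    fx * (1 - fy) * m[cbind(ix + 1L, iy)] +
    (1 - fx) * fy * m[cbind(ix, iy + 1L)] +
    fx * fy * m[cbind(ix + 1L, iy + 1L)]
  pmax(v, 0)
}

# Rasterized set covariance, cached on the window object via an environment.
window_setcov_grid <- function(window, n = 256L) {
  key <- paste0(window$type, digest_coords(window))
  cached <- setcov_cache[[key]]
  if (!is.null(cached)) return(cached)
  step <- max(diff(window$xrange), diff(window$yrange)) / n
  gx <- seq(window$xrange[1] + step / 2, window$xrange[2], by = step)
  gy <- seq(window$yrange[1] + step / 2, window$yrange[2], by = step)
  mask <- outer(gx, gy, function(a, b) as.numeric(in_window(a, b, window)))
  nx <- length(gx); ny <- length(gy)
  # zero-pad to avoid circular wrap-around
  pad <- matrix(0, 2L * nx, 2L * ny)
  pad[seq_len(nx), seq_len(ny)] <- mask
  f <- stats::fft(pad)
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / length(pad)
  # ac[1 + i, 1 + j] = number of overlapping cells at shift (i, j), i, j >= 0
  m <- ac[seq_len(nx), seq_len(ny)] * step^2
  out <- list(sx = (seq_len(nx) - 1L) * step, sy = (seq_len(ny) - 1L) * step,
              m = m)
  setcov_cache[[key]] <- out
  out
}

setcov_cache <- new.env(parent = emptyenv())

digest_coords <- function(w) {
  v <- if (w$type == "rect") c(w$xrange, w$yrange) else c(w$x, w$y)
  paste(signif(v, 10), collapse = ",")
}
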