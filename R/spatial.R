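#' Nearest-neighbor distances between cell types
#'
#' For every point of `from_type`, the Euclidean distance to its nearest
#' point of `to_type`, excluding the point itself when the types match.
#' The statistic is asymmetric: `nnd(p, "PV", "SST")` and
#' `nnd(p, "SST", "PV")` generally differ. No edge correction is applied;
#' distances near the window border carry a small upward-censoring bias,
#' which is the convention the summary statistics downstream assume.
#'
#' With `periodic = TRUE` (rectangular windows only) distances wrap
#' around the window edges, removing boundary censoring entirely; this
#' toroidal variant is the right estimator when validating against
#' closed-form results for the unbounded process, and is never the
#' default for real data.
#'
#' @param pattern a typed [point_pattern()] (or untyped, with both types
#'   `"all"`).
#' @param from_type,to_type type labels.
#' @param periodic use toroidal (wrap-around) distances.
#' @return An `nnd_result`: list with `distances` (um, one per from-point),
#'   `mean`, `sd` (sample, n-1), `cv`, and the type pair.
#' @export
nnd <- function(pattern, from_type = "all", to_type = from_type,
                periodic = FALSE) {
  ia <- type_index(pattern, from_type)
  ib <- type_index(pattern, to_type)
  same <- identical(from_type, to_type)
  if (same && length(ia) < 2)
    stop("insufficient-data: need >= 2 points of type '", from_type, "'")
  if (!same && (length(ia) < 1 || length(ib) < 1))
    stop("insufficient-data: need >= 1 point of each type")
  dx <- abs(outer(pattern$x[ia], pattern$x[ib], "-"))
  dy <- abs(outer(pattern$y[ia], pattern$y[ib], "-"))
  if (periodic) {
    if (pattern$window$type != "rect")
      stop("periodic distances require a rectangular window")
    wx <- diff(pattern$window$xrange); wy <- diff(pattern$window$yrange)
    dx <- pmin(dx, wx - dx)
    dy <- pmin(dy, wy - dy)
  }
  d2 <- dx * dx + dy * dy
  if (same) diag(d2) <- Inf
  # points of equal type at identical indices only are excluded; coincident
  # distinct points legitimately give distance 0
  dmin <- sqrt(apply(d2, 1, min))
  m <- mean(dmin)
  s <- if (length(dmin) >= 2) stats::sd(dmin) else NA_real_
  structure(list(from_type = from_type, to_type = to_type,
                 distances = dmin, mean = m, sd = s,
                 cv = if (!is.na(s) && m > 0) s / m else NA_real_,
                 n = length(dmin)),
            class = "nnd_result")
}

#' @export
print.nnd_result <- function(x, ...) {
  cat(sprintf("NND %s -> %s: n = %d, mean = %.3g um, sd = %.3g um, CV = %.3g\n",
              x$from_type, x$to_type, x$n, x$mean, x$sd, x$cv))
  invisible(x)
}

#' Coefficient of variation of nearest-neighbor distances
#'
#' The standard deviation of the NND divided by its mean: a dimensionless
#' regularity index. Regularly spaced mosaics have low CV, Poisson
#' patterns about `sqrt((4 - pi)/pi)` (~0.523), clustered patterns higher.
#'
#' @param result an `nnd_result` from [nnd()].
#' @export
cv_of_nnd <- function(result) {
  stopifnot(inherits(result, "nnd_result"))
  if (result$n < 2) stop("insufficient-data: need >= 2 distances for a CV")
  if (!(result$mean > 0)) stop("insufficient-data: mean NND is not positive")
  stats::sd(result$distances) / result$mean
}

#' Merge double-positive cells across two marker channels
#'
#' Cells detected in both channels appear as a cross-channel pair closer
#' than the soma radius; such pairs are merged into a single
#' double-positive cell. Matching is greedy nearest-first and one-to-one:
#' candidate cross pairs with distance below `soma_radius` are processed in
#' increasing distance order and each cell merges at most once. The merged
#' point keeps the first pattern's coordinates.
#'
#' @param patternA,patternB two [point_pattern()]s in the same window.
#' @param soma_radius merge threshold (um).
#' @param labels type labels for A-only, B-only and double-positive points.
#' @return a typed [point_pattern()] with `|A| + |B| - merges` points.
#' @export
merge_double_positive <- function(patternA, patternB, soma_radius,
                                  labels = c("A", "B", "AB")) {
  if (!identical(unclass(patternA$window), unclass(patternB$window)))
    stop("patterns must share a window")
  stopifnot(soma_radius > 0)
  nA <- patternA$n; nB <- patternB$n
  usedA <- logical(nA); usedB <- logical(nB)
  if (nA > 0 && nB > 0) {
    d <- sqrt(outer(patternA$x, patternB$x, "-")^2 +
                outer(patternA$y, patternB$y, "-")^2)
    cand <- which(d < soma_radius, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!usedA[i] && !usedB[j]) { usedA[i] <- TRUE; usedB[j] <- TRUE }
      }
    }
  }
  point_pattern(
    c(patternA$x, patternB$x[!usedB]),
    c(patternA$y, patternB$y[!usedB]),
    patternA$window,
    type = c(ifelse(usedA, labels[3], labels[1]),
             rep(labels[2], sum(!usedB))),
    soma_radius = soma_radius)
}

# Epanechnikov kernel with half-width h.
epanechnikov <- function(t, h) {
  ifelse(abs(t) < h, 0.75 / h * (1 - (t / h)^2), 0)
}

# Stoyan's bandwidth rule: half-width 0.15 / sqrt(lambda), lambda per um^2.
stoyan_bandwidth <- function(lambda_per_um2, c = 0.15) c / sqrt(lambda_per_um2)

#' Kernel-smoothed pair correlation function
#'
#' Estimates g(r), the ratio of the observed density of cells at distance
#' r from a reference cell to the density expected under complete spatial
#' randomness; g = 1 for a random pattern, below 1 for spatial inhibition,
#' above 1 for clustering. The estimator accumulates an Epanechnikov
#' kernel over all (ordered) inter-point distances with translation
#' edge-correction weights `|W| / |W n W_v|` and normalizes by `2 pi r`
#' and the intensity product:
#' \deqn{\hat g_{AB}(r) = \frac{1}{2\pi r\, \hat\lambda_A \hat\lambda_B}
#'       \sum_{i \in A}\sum_{j \in B, j \ne i}
#'       \frac{\kappa_h(r - d_{ij})}{|W \cap W_{x_j - x_i}|}}
#' with \eqn{\hat\lambda = n / |W|}. Within-type estimation uses
#' `typeB = typeA` (every unordered pair contributes twice); cross-type
#' uses two distinct labels.
#'
#' @param pattern a [point_pattern()].
#' @param typeA,typeB type labels (`"all"` for an untyped pattern).
#' @param r_grid strictly increasing distances (um); default 100 values up
#'   to a quarter of the shorter window side. Values beyond half the
#'   window extent are trimmed with a warning.
#' @param bandwidth Epanechnikov half-width (um); default is Stoyan's rule
#'   `0.15 / sqrt(lambda)` on the pooled intensity of the two types.
#' @param correction `"translation"` (default) or `"none"`.
#' @param min_points below this count per type the estimate is flagged
#'   unstable (still computed).
#' @return A `pcf_estimate`: list with `r`, `g`, `bandwidth`, `correction`,
#'   `lambda_hat` (cells/mm^2 per type), `n_points`, `unstable`, and empty
#'   envelope slots.
#' @seealso [csr_envelope()], [average_pcf()]
#' @export
pcf <- function(pattern, typeA = "all", typeB = typeA, r_grid = NULL,
                bandwidth = NULL, correction = c("translation", "none"),
                min_points = 10L) {
  correction <- match.arg(correction)
  ia <- type_index(pattern, typeA)
  ib <- type_index(pattern, typeB)
  nA <- length(ia); nB <- length(ib)
  if (nA == 0 || nB == 0)
    stop("insufficient-data: empty type for pair correlation")
  w <- pattern$window
  area <- window_area(w)
  ext <- min(diff(w$xrange), diff(w$yrange))
  if (is.null(r_grid)) r_grid <- seq(1, ext / 4, length.out = 100L)
  if (any(diff(r_grid) <= 0) || any(r_grid <= 0))
    stop("r_grid must be strictly increasing and positive")
  if (any(r_grid > ext / 2)) {
    warning("r values beyond half the window extent trimmed")
    r_grid <- r_grid[r_grid <= ext / 2]
  }
  within <- identical(typeA, typeB)
  lam_pool <- (if (within) nA else nA + nB) / area  # per um^2
  if (is.null(bandwidth)) bandwidth <- stoyan_bandwidth(lam_pool)
  unstable <- nA < min_points || nB < min_points
  if (unstable)
    warning("fewer than ", min_points,
            " points of a type; pair correlation estimate flagged unstable")

  dx <- outer(pattern$x[ia], pattern$x[ib], "-")
  dy <- outer(pattern$y[ia], pattern$y[ib], "-")
  d <- sqrt(dx * dx + dy * dy)
  keep <- d <= max(r_grid) + bandwidth
  if (within) keep[cbind(seq_len(nA), seq_len(nA))] <- FALSE
  dv <- d[keep]
  wts <- if (correction == "translation")
    area / set_covariance(w, dx[keep], dy[keep])
  else rep(1, length(dv))

  g <- vapply(r_grid, function(r)
    sum(epanechnikov(r - dv, bandwidth) * wts), numeric(1))
  g <- g / (2 * pi * r_grid * (nA / area) * (nB / area) * area)

  structure(list(r = r_grid, g = g, bandwidth = bandwidth,
                 correction = correction,
                 lambda_hat = c(A = nA, B = nB) / (area / 1e6),
                 n_points = c(A = nA, B = nB),
                 typeA = typeA, typeB = typeB, unstable = unstable,
                 envelope_lo = NULL, envelope_hi = NULL),
            class = "pcf_estimate")
}

#' @export
print.pcf_estimate <- function(x, ...) {
  cat(sprintf("pair correlation estimate %s-%s: %d r values in [%.3g, %.3g] um, h = %.3g um, %s correction%s\n",
              x$typeA, x$typeB, length(x$r), min(x$r), max(x$r), x$bandwidth,
              x$correction, if (isTRUE(x$unstable)) " [unstable]" else ""))
  invisible(x)
}

#' @export
as.data.frame.pcf_estimate <- function(x, ...) {
  data.frame(r_um = x$r, g = x$g,
             lo = if (is.null(x$envelope_lo)) NA_real_ else x$envelope_lo,
             hi = if (is.null(x$envelope_hi)) NA_real_ else x$envelope_hi)
}

#' @export
plot.pcf_estimate <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "l", xlab = "r (um)", ylab = "g(r)",
                 ylim = range(c(0, x$g, x$envelope_hi, 1.2), na.rm = TRUE),
                 ...)
  if (!is.null(x$envelope_lo)) {
    graphics::polygon(c(x$r, rev(x$r)), c(x$envelope_lo, rev(x$envelope_hi)),
                      col = grDevices::adjustcolor("grey", 0.5), border = NA)
    graphics::lines(x$r, x$g)
  }
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Monte-Carlo envelope of the pair correlation under randomness
#'
#' Simulates patterns with the observed counts, types and window under
#' complete spatial randomness and returns 95% bands of the estimated
#' g(r) — the single-pattern reference against which observed inhibition
#' or clustering is judged. For a cross-type pair, the null can be
#' `"independent"` (both types resimulated as independent uniform
#' patterns, the default) or `"relabel"` (locations fixed, type labels
#' randomly permuted).
#'
#' Two band constructions are offered. `"pointwise"` (the default, the
#' construction the per-distance envelope plots use) takes 2.5/97.5
#' percentiles at each r; its 95% coverage holds per distance, so a null
#' curve will typically cross it somewhere along a fine r grid.
#' `"global"` builds a simultaneous band — mean curve plus/minus a common
#' multiple of the per-r simulation standard deviation, the multiplier
#' set to the 95th percentile of each simulation's maximum studentized
#' deviation — so that about 95% of null curves lie inside over the
#' whole grid at once. Use `"global"` when the question is "does the
#' curve stay consistent with randomness at all r".
#'
#' @param pattern,typeA,typeB,r_grid,bandwidth,correction as in [pcf()].
#' @param n_sim number of null simulations; at least 39 for a 5%
#'   pointwise test.
#' @param seed integer seed.
#' @param method null model for cross-type pairs.
#' @param type `"pointwise"` or `"global"` band construction.
#' @return the observed `pcf_estimate` with `envelope_lo`/`envelope_hi`
#'   filled in.
#' @export
csr_envelope <- function(pattern, typeA = "all", typeB = typeA, n_sim = 99L,
                         seed = 1L, r_grid = NULL, bandwidth = NULL,
                         correction = "translation",
                         method = c("independent", "relabel"),
                         type = c("pointwise", "global")) {
  method <- match.arg(method)
  type <- match.arg(type)
  if (n_sim < 1) stop("n_sim must be >= 1 (>= 39 for a 5% pointwise test)")
  obs <- pcf(pattern, typeA, typeB, r_grid = r_grid, bandwidth = bandwidth,
             correction = correction)
  w <- pattern$window
  within <- identical(typeA, typeB)
  nA <- obs$n_points["A"]; nB <- obs$n_points["B"]
  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(s) {
      if (within) {
        xy <- runif_in_window(nA, w)
        p <- point_pattern(xy[, 1], xy[, 2], w)
        pcf(p, r_grid = obs$r, bandwidth = obs$bandwidth,
            correction = correction, min_points = 0L)$g
      } else if (method == "independent") {
        xya <- runif_in_window(nA, w); xyb <- runif_in_window(nB, w)
        p <- point_pattern(c(xya[, 1], xyb[, 1]), c(xya[, 2], xyb[, 2]), w,
                           type = c(rep(typeA, nA), rep(typeB, nB)))
        pcf(p, typeA, typeB, r_grid = obs$r, bandwidth = obs$bandwidth,
            correction = correction, min_points = 0L)$g
      } else {
        ii <- c(type_index(pattern, typeA), type_index(pattern, typeB))
        lab <- sample(c(rep(typeA, nA), rep(typeB, nB)))
        p <- point_pattern(pattern$x[ii], pattern$y[ii], w, type = lab)
        pcf(p, typeA, typeB, r_grid = obs$r, bandwidth = obs$bandwidth,
            correction = correction, min_points = 0L)$g
      }
    }, numeric(length(obs$r)))
  })
  if (type == "pointwise") {
    obs$envelope_lo <- apply(sims, 1, stats::quantile, probs = 0.025)
    obs$envelope_hi <- apply(sims, 1, stats::quantile, probs = 0.975)
  } else {
    m <- rowMeans(sims)
    s <- apply(sims, 1, stats::sd)
    s[s == 0] <- Inf  # degenerate r values impose no constraint
    dev <- apply(abs(sims - m) / s, 2, max)
    crit <- stats::quantile(dev, probs = 0.95)
    obs$envelope_lo <- m - crit * s
    obs$envelope_hi <- m + crit * s
  }
  obs$envelope_type <- type
  obs$n_sim <- n_sim
  obs
}

#' Average pair correlation estimates
#'
#' Unweighted pointwise mean of g(r) across estimates, after interpolation
#' to the first estimate's r grid. This is the replicate-averaging rule of
#' the study design: g(r) per animal is the mean over that animal's ROIs,
#' and per group the mean over its animals — apply this function at each
#' level (see [aggregate_study()] for the two-level driver).
#'
#' @param estimates list of `pcf_estimate`s sharing bandwidth and
#'   correction.
#' @return a single `pcf_estimate`.
#' @export
average_pcf <- function(estimates) {
  if (length(estimates) == 0) stop("empty list of estimates")
  stopifnot(all(vapply(estimates, inherits, logical(1), "pcf_estimate")))
  bw <- vapply(estimates, `[[`, numeric(1), "bandwidth")
  corr <- vapply(estimates, `[[`, character(1), "correction")
  if (length(unique(corr)) != 1)
    stop("estimates use different edge corrections")
  ref <- estimates[[1]]
  gs <- vapply(estimates, function(e) {
    if (identical(e$r, ref$r)) e$g
    else stats::approx(e$r, e$g, xout = ref$r, rule = 2)$y
  }, numeric(length(ref$r)))
  out <- ref
  out$g <- rowMeans(matrix(gs, nrow = length(ref$r)))
  out$bandwidth <- mean(bw)
  out$n_points <- NULL
  out$n_averaged <- length(estimates)
  out$envelope_lo <- out$envelope_hi <- NULL
  out
}
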