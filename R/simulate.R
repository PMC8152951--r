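#' Specification of a simulated point process
#'
#' Describes one of three planar point processes used as ground truth:
#' complete spatial randomness (`csr`, homogeneous Poisson), a Matern
#' type-II hard-core process (`matern_ii`, mark-based thinning so that no
#' two surviving points are closer than `inhibition_radius`), or a Thomas
#' cluster process (`thomas`, Poisson parents with Gaussian-dispersed
#' offspring).
#'
#' @param process_kind one of `"csr"`, `"matern_ii"`, `"thomas"`.
#' @param intensity cells per mm^2. For `matern_ii` this is the proposal
#'   intensity before thinning; for `thomas` it is the parent intensity.
#' @param window observation window ([rect_window()] / [poly_window()]).
#' @param seed integer seed; identical spec + seed gives an identical
#'   pattern.
#' @param inhibition_radius hard-core distance in um (`matern_ii` only).
#' @param offspring_mean mean offspring per parent (`thomas` only).
#' @param cluster_sd isotropic Gaussian offspring displacement sd in um
#'   (`thomas` only).
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(process_kind = c("csr", "matern_ii", "thomas"),
                            intensity, window, seed = 1L,
                            inhibition_radius = NULL, offspring_mean = NULL,
                            cluster_sd = NULL) {
  process_kind <- match.arg(process_kind)
  if (!is.numeric(intensity) || intensity <= 0)
    stop("invalid-spec: intensity must be > 0")
  if (!inherits(window, "cm_window")) stop("invalid-spec: bad window")
  if (window_area(window) <= 0) stop("invalid-spec: window area must be > 0")
  if (process_kind == "matern_ii") {
    if (is.null(inhibition_radius) || inhibition_radius < 0)
      stop("invalid-spec: inhibition_radius must be >= 0")
  }
  if (process_kind == "thomas") {
    if (is.null(offspring_mean) || offspring_mean < 0)
      stop("invalid-spec: offspring_mean must be >= 0")
    if (is.null(cluster_sd) || cluster_sd < 0)
      stop("invalid-spec: cluster_sd must be >= 0")
  }
  structure(list(process_kind = process_kind, intensity = intensity,
                 window = window, seed = as.integer(seed),
                 inhibition_radius = inhibition_radius,
                 offspring_mean = offspring_mean, cluster_sd = cluster_sd),
            class = "simulation_spec")
}

# All randomness flows from one user seed. Child streams are derived with a
# multiplicative-congruential step so that independent components (pattern,
# depths, clutter, noise, blinding) never share a stream.
split_seed <- function(seed, k) {
  # (seed mod m) * 48271 stays below 2^53, so the product is exact in
  # double precision before the reduction
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + k) %% 2147483647)
}

# Evaluate expr under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a point process from a spec
#'
#' Dispatches on `process_kind`. Intensities are per mm^2; coordinates per
#' um, so the Poisson mean is `intensity * area / 1e6`.
#'
#' @param spec a [simulation_spec()].
#' @return a [point_pattern()].
#' @export
simulate_pattern <- function(spec) {
  switch(spec$process_kind,
         csr = simulate_csr(spec),
         matern_ii = simulate_matern_ii(spec),
         thomas = simulate_thomas(spec))
}

#' @rdname simulate_pattern
#' @export
simulate_csr <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"), spec$process_kind == "csr")
  with_seed(spec$seed, {
    mu <- spec$intensity * window_area(spec$window) / 1e6
    n <- stats::rpois(1, mu)
    xy <- runif_in_window(n, spec$window)
    point_pattern(xy[, 1], xy[, 2], spec$window)
  })
}

#' @rdname simulate_pattern
#' @export
simulate_matern_ii <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"),
            spec$process_kind == "matern_ii")
  h <- spec$inhibition_radius
  with_seed(spec$seed, {
    mu <- spec$intensity * window_area(spec$window) / 1e6
    n <- stats::rpois(1, mu)
    xy <- runif_in_window(n, spec$window)
    if (n == 0L || h == 0)
      return(point_pattern(xy[, 1], xy[, 2], spec$window))
    marks <- stats::runif(n)
    keep <- logical(n)
    for (i in seq_len(n)) {
      d2 <- (xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2
      rival <- d2 < h^2 & marks < marks[i]
      rival[i] <- FALSE
      keep[i] <- !any(rival)
    }
    point_pattern(xy[keep, 1], xy[keep, 2], spec$window)
  })
}

#' @rdname simulate_pattern
#' @export
simulate_thomas <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"), spec$process_kind == "thomas")
  sd <- spec$cluster_sd
  w <- spec$window
  with_seed(spec$seed, {
    # parents in a window dilated by 4 sd so edge clusters are not lost
    ext <- 4 * sd
    pw <- rect_window(w$xrange + c(-ext, ext), w$yrange + c(-ext, ext))
    mu <- spec$intensity * window_area(pw) / 1e6
    npar <- stats::rpois(1, mu)
    pxy <- runif_in_window(npar, pw)
    if (npar == 0L)
      return(point_pattern(numeric(0), numeric(0), w))
    noff <- stats::rpois(npar, spec$offspring_mean)
    px <- rep(pxy[, 1], noff); py <- rep(pxy[, 2], noff)
    m <- length(px)
    cx <- px + stats::rnorm(m, 0, sd)
    cy <- py + stats::rnorm(m, 0, sd)
    keep <- in_window(cx, cy, w)
    point_pattern(cx[keep], cy[keep], w)
  })
}

#' Superpose two independent simulated patterns with type labels
#'
#' Simulates both specs independently and labels points `A` and `B`.
#' The natural use is a two-marker scene (e.g. PV- and SST-like types)
#' whose cross-type structure is known to be absent by construction.
#'
#' @param specA,specB two [simulation_spec()]s sharing the same window.
#' @param labels length-2 character vector of type labels.
#' @return a typed [point_pattern()].
#' @export
simulate_bitype <- function(specA, specB, labels = c("A", "B")) {
  if (!identical(unclass(specA$window), unclass(specB$window)))
    stop("invalid-spec: the two specs must share the same window")
  pa <- simulate_pattern(specA)
  pb <- simulate_pattern(specB)
  point_pattern(c(pa$x, pb$x), c(pa$y, pb$y), specA$window,
                type = c(rep(labels[1], pa$n), rep(labels[2], pb$n)))
}
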