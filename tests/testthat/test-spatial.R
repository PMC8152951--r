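w <- rect_window(c(0, 1000), c(0, 1000))

test_that("nearest-neighbor distances match a brute-force oracle", {
  set.seed(10)
  p <- point_pattern(runif(40, 0, 1000), runif(40, 0, 1000), w,
                     type = sample(c("PV", "SST"), 40, replace = TRUE))
  res <- nnd(p, "PV", "PV")
  ia <- which(p$type == "PV")
  oracle <- vapply(ia, function(i) {
    min(sqrt((p$x[ia] - p$x[i])^2 + (p$y[ia] - p$y[i])^2)[ia != i])
  }, numeric(1))
  expect_equal(res$distances, oracle)
  cross <- nnd(p, "PV", "SST")
  ib <- which(p$type == "SST")
  oracle2 <- vapply(ia, function(i)
    min(sqrt((p$x[ib] - p$x[i])^2 + (p$y[ib] - p$y[i])^2)), numeric(1))
  expect_equal(cross$distances, oracle2)
  # asymmetry of the cross statistic
  expect_false(isTRUE(all.equal(nnd(p, "SST", "PV")$mean, cross$mean)))
})

test_that("periodic distances wrap around a rectangular window", {
  p <- point_pattern(c(10, 990), c(500, 500), w)
  expect_equal(nnd(p)$distances, c(980, 980))
  expect_equal(nnd(p, periodic = TRUE)$distances, c(20, 20))
  wp <- poly_window(c(0, 100, 50), c(0, 0, 90))
  pp <- point_pattern(c(40, 60), c(10, 10), wp)
  expect_error(nnd(pp, periodic = TRUE), "rectangular")
})

test_that("nnd demands enough points", {
  p1 <- point_pattern(5, 5, w)
  expect_error(nnd(p1), "insufficient-data")
  pt <- point_pattern(c(1, 2), c(1, 2), w, type = c("A", "A"))
  expect_error(nnd(pt, "A", "B"), "insufficient-data")
})

test_that("CV of NND is sd over mean", {
  set.seed(11)
  p <- point_pattern(runif(60, 0, 1000), runif(60, 0, 1000), w)
  res <- nnd(p)
  expect_equal(cv_of_nnd(res), sd(res$distances) / mean(res$distances))
  expect_equal(res$cv, cv_of_nnd(res))
})

test_that("double-positive merge: hand-checked configurations", {
  wl <- rect_window(c(0, 100), c(0, 100))
  a <- point_pattern(c(10, 50), c(10, 50), wl)
  b <- point_pattern(c(12, 90), c(10, 50), wl)
  m <- merge_double_positive(a, b, soma_radius = 6,
                             labels = c("PV", "SST", "PV+SST"))
  expect_equal(m$n, 3L)
  expect_equal(sort(m$type), c("PV", "PV+SST", "SST"))
  # merged point keeps the first pattern's coordinates
  expect_true(any(m$x == 10 & m$type == "PV+SST"))
  # no pair within radius: plain superposition
  m2 <- merge_double_positive(a, point_pattern(30, 90, wl), 6)
  expect_equal(m2$n, 3L)
  expect_equal(sum(m2$type == "AB"), 0L)
})

test_that("greedy merge equals exhaustive matching on small configurations", {
  # Exhaustive maximum matching by recursion over candidate pairs.
  exhaustive <- function(d, r) {
    cand <- which(d < r, arr.ind = TRUE)
    if (nrow(cand) == 0) return(0L)
    best <- 0L
    rec <- function(k, usedA, usedB, cnt) {
      if (cnt + (nrow(cand) - k + 1L) <= best) return()
      if (k > nrow(cand)) { best <<- max(best, cnt); return() }
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!usedA[i] && !usedB[j]) {
        usedA[i] <- TRUE; usedB[j] <- TRUE
        rec(k + 1L, usedA, usedB, cnt + 1L)
        usedA[i] <- FALSE; usedB[j] <- FALSE
      }
      rec(k + 1L, usedA, usedB, cnt)
    }
    rec(1L, logical(nrow(d)), logical(ncol(d)), 0L)
    best
  }
  wl <- rect_window(c(0, 200), c(0, 200))
  r <- 6
  for (trial in 1:30) {
    set.seed(400 + trial)
    # the operating regime: distinct somata well separated, double
    # positives as tightly colocalized cross-channel pairs
    centers <- cbind(runif(4, 20, 180), runif(4, 20, 180))
    ax <- c(centers[1:3, 1], runif(2, 20, 180))
    ay <- c(centers[1:3, 2], runif(2, 20, 180))
    bx <- c(centers[1:3, 1] + runif(3, -2, 2), runif(1, 20, 180))
    by <- c(centers[1:3, 2] + runif(3, -2, 2), runif(1, 20, 180))
    a <- point_pattern(ax, ay, wl)
    b <- point_pattern(bx, by, wl)
    m <- merge_double_positive(a, b, r)
    d <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
    n_opt <- exhaustive(d, r)
    expect_equal(sum(m$type == "AB"), n_opt)
    expect_equal(m$n, length(ax) + length(bx) - n_opt)
  }
})

test_that("Epanechnikov kernel integrates to one and has the right support", {
  h <- 12
  t <- seq(-h, h, length.out = 20001)
  expect_lt(abs(sum(cortexmosaic:::epanechnikov(t, h)) * diff(t)[1] - 1),
            1e-4)
  expect_equal(cortexmosaic:::epanechnikov(c(-h, h, h + 1), h), c(0, 0, 0))
})

test_that("pcf matches a literal double-loop recomputation", {
  set.seed(12)
  p <- point_pattern(runif(45, 0, 1000), runif(45, 0, 1000), w)
  rg <- seq(10, 200, by = 10)
  est <- pcf(p, r_grid = rg, bandwidth = 20)
  area <- 1e6
  oracle <- vapply(rg, function(r) {
    s <- 0
    for (i in 1:45) for (j in 1:45) {
      if (i == j) next
      dx <- p$x[i] - p$x[j]; dy <- p$y[i] - p$y[j]
      d <- sqrt(dx^2 + dy^2)
      if (abs(r - d) < 20) {
        k <- 0.75 / 20 * (1 - ((r - d) / 20)^2)
        wt <- area / ((1000 - abs(dx)) * (1000 - abs(dy)))
        s <- s + k * wt
      }
    }
    s / (2 * pi * r * (45 / area)^2 * area)
  }, numeric(1))
  expect_equal(est$g, oracle, tolerance = 1e-12)
})

test_that("pcf without correction underestimates at large r", {
  set.seed(13)
  sp <- simulation_spec("csr", intensity = 200, window = w, seed = 77L)
  p <- simulate_pattern(sp)
  rg <- seq(100, 250, by = 10)
  g_t <- pcf(p, r_grid = rg)$g
  g_n <- pcf(p, r_grid = rg, correction = "none")$g
  expect_true(mean(g_n) < mean(g_t))
})

test_that("pcf guards its r grid and flags unstable estimates", {
  set.seed(14)
  p <- point_pattern(runif(30, 0, 1000), runif(30, 0, 1000), w)
  expect_error(pcf(p, r_grid = c(10, 5)), "increasing")
  expect_warning(est <- pcf(p, r_grid = c(100, 400, 700)), "trimmed")
  expect_equal(est$r, c(100, 400))
  p5 <- point_pattern(runif(5, 0, 1000), runif(5, 0, 1000), w)
  expect_warning(e5 <- pcf(p5, r_grid = c(50, 100)), "unstable")
  expect_true(e5$unstable)
})

test_that("average_pcf is the pointwise arithmetic mean", {
  set.seed(15)
  ests <- lapply(1:3, function(i) {
    p <- point_pattern(runif(50, 0, 1000), runif(50, 0, 1000), w)
    pcf(p, r_grid = seq(20, 100, by = 20), bandwidth = 15)
  })
  avg <- average_pcf(ests)
  expect_equal(avg$g, (ests[[1]]$g + ests[[2]]$g + ests[[3]]$g) / 3)
  expect_equal(avg$n_averaged, 3L)
  # estimates on a different grid are interpolated onto the first grid
  p <- point_pattern(runif(50, 0, 1000), runif(50, 0, 1000), w)
  e2 <- pcf(p, r_grid = seq(10, 110, by = 5), bandwidth = 15)
  avg2 <- average_pcf(list(ests[[1]], e2))
  expect_equal(avg2$r, ests[[1]]$r)
})

test_that("csr envelope brackets a CSR pattern most places", {
  sp <- simulation_spec("csr", intensity = 150, window = w, seed = 31L)
  p <- simulate_pattern(sp)
  rg <- seq(20, 150, by = 10)
  env <- csr_envelope(p, n_sim = 39, seed = 2L, r_grid = rg)
  expect_length(env$envelope_lo, length(rg))
  expect_true(all(env$envelope_lo < env$envelope_hi))
  inside <- mean(env$g >= env$envelope_lo & env$g <= env$envelope_hi)
  expect_gt(inside, 0.7)
  # global band contains the pointwise band
  envg <- csr_envelope(p, n_sim = 39, seed = 2L, r_grid = rg,
                       type = "global")
  expect_true(all(envg$g >= envg$envelope_lo & envg$g <= envg$envelope_hi))
})
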