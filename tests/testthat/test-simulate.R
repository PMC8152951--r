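w1 <- rect_window(c(0, 1000), c(0, 1000))

test_that("identical spec and seed reproduce the identical pattern", {
  sp <- simulation_spec("csr", intensity = 100, window = w1, seed = 42L)
  a <- simulate_pattern(sp)
  b <- simulate_pattern(sp)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  # simulation restores the caller's RNG state
  set.seed(7); before <- runif(3)
  set.seed(7); invisible(simulate_pattern(sp)); after <- runif(3)
  expect_identical(before, after)
})

test_that("derived seed streams are valid integers for any user seed", {
  for (s in c(0, 1, 20260101, 2147483646, 2^31 - 1)) {
    ks <- vapply(1:100, function(k) cortexmosaic:::split_seed(s, k),
                 integer(1))
    expect_false(anyNA(ks))
    expect_true(all(ks >= 0 & ks < 2^31))
    expect_false(any(duplicated(ks)))
  }
})

test_that("simulation_spec validates its arguments", {
  expect_error(simulation_spec("csr", intensity = -5, window = w1),
               "invalid-spec")
  expect_error(simulation_spec("matern_ii", intensity = 100, window = w1),
               "invalid-spec")
  expect_error(simulation_spec("thomas", intensity = 10, window = w1,
                               offspring_mean = 5), "invalid-spec")
  expect_error(simulation_spec("csr", intensity = 100, window = "box"),
               "invalid-spec")
})

test_that("CSR counts follow the Poisson mean", {
  ns <- vapply(1:100, function(i)
    simulate_pattern(simulation_spec("csr", intensity = 100, window = w1,
                                     seed = i))$n, numeric(1))
  # mean 100, sd 10: the average of 100 draws lies within 4 standard errors
  expect_lt(abs(mean(ns) - 100), 4)
  expect_true(all(in_window(0, 0, w1)))
})

test_that("Matern II respects the hard core and the retention formula", {
  h <- 30
  sp <- simulation_spec("matern_ii", intensity = 300, window = w1,
                        seed = 11L, inhibition_radius = h)
  p <- simulate_pattern(sp)
  d <- as.matrix(dist(cbind(p$x, p$y)))
  diag(d) <- Inf
  expect_gte(min(d), h)
  # E[retained intensity] = (1 - exp(-lambda * pi h^2)) / (pi h^2)
  lam <- 300 / 1e6
  expected <- (1 - exp(-lam * pi * h^2)) / (pi * h^2) * 1e6
  ns <- vapply(1:60, function(i)
    simulate_pattern(simulation_spec("matern_ii", intensity = 300,
                                     window = w1, seed = 1000L + i,
                                     inhibition_radius = h))$n, numeric(1))
  expect_lt(abs(mean(ns) - expected) / expected, 0.05)
})

test_that("Matern II with zero radius degenerates to CSR", {
  sp <- simulation_spec("matern_ii", intensity = 100, window = w1,
                        seed = 3L, inhibition_radius = 0)
  sp_csr <- simulation_spec("csr", intensity = 100, window = w1, seed = 3L)
  expect_identical(simulate_pattern(sp)$x, simulate_pattern(sp_csr)$x)
})

test_that("Thomas offspring stay in the window at near-nominal intensity", {
  sp <- simulation_spec("thomas", intensity = 25, window = w1, seed = 5L,
                        offspring_mean = 8, cluster_sd = 15)
  p <- simulate_pattern(sp)
  expect_true(all(in_window(p$x, p$y, w1)))
  ns <- vapply(1:60, function(i)
    simulate_pattern(simulation_spec("thomas", intensity = 25, window = w1,
                                     seed = 2000L + i, offspring_mean = 8,
                                     cluster_sd = 15))$n, numeric(1))
  # parent dilation keeps the edge-cluster contribution: mean close to
  # kappa * mu = 200 (small deficit only from clusters straddling the edge)
  expect_lt(abs(mean(ns) - 200) / 200, 0.08)
})

test_that("bitype superposition labels the two components", {
  sa <- simulation_spec("csr", intensity = 80, window = w1, seed = 21L)
  sb <- simulation_spec("csr", intensity = 40, window = w1, seed = 22L)
  p <- simulate_bitype(sa, sb, labels = c("PV", "SST"))
  na <- simulate_pattern(sa)$n
  nb <- simulate_pattern(sb)$n
  expect_equal(sum(p$type == "PV"), na)
  expect_equal(sum(p$type == "SST"), nb)
  expect_equal(p$n, na + nb)
  sb2 <- simulation_spec("csr", intensity = 40,
                         window = rect_window(c(0, 500), c(0, 500)))
  expect_error(simulate_bitype(sa, sb2), "share the same window")
})

test_that("regularity ordering of the NND coefficient of variation", {
  # lattice < Matern II < CSR < Thomas: hard-core thinning regularizes,
  # clustering broadens the NND distribution
  cvs <- function(p) cv_of_nnd(nnd(p))
  gx <- seq(50, 950, by = 100)
  lattice <- point_pattern(rep(gx, 10), rep(gx, each = 10), w1)
  mat <- simulate_pattern(simulation_spec("matern_ii", intensity = 300,
                                          window = w1, seed = 31L,
                                          inhibition_radius = 30))
  csr <- simulate_pattern(simulation_spec("csr", intensity = 100,
                                          window = w1, seed = 31L))
  tho <- simulate_pattern(simulation_spec("thomas", intensity = 12,
                                          window = w1, seed = 31L,
                                          offspring_mean = 9,
                                          cluster_sd = 12))
  expect_lt(cvs(lattice), cvs(mat))
  expect_lt(cvs(mat), cvs(csr))
  expect_lt(cvs(csr), cvs(tho))
})
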