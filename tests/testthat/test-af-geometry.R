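test_that("relative coordinates reduce pairs correctly", {
  rc <- relative_coordinates(edge_tbl(0, 0, 0), edge_tbl(2, 0, 0))
  expect_equal(rc$d, 2)
  expect_equal(rc$phi, 0)
  expect_equal(rc$dtheta, 0)

  # independent trigonometric hand computation
  rc2 <- relative_coordinates(edge_tbl(0, 0, pi / 2), edge_tbl(1, 1, pi))
  expect_equal(rc2$d, sqrt(2))
  expect_equal(rc2$phi, atan2(1, 1) - pi / 2)
  expect_equal(rc2$dtheta, pi / 2)

  expect_error(relative_coordinates(edge_tbl(1, 1, 0), edge_tbl(1, 1, 2)),
               class = "afield_degenerate_geometry")
})

test_that("relative coordinates are invariant under joint rigid motion", {
  set.seed(11)
  for (i in 1:50) {
    s <- edge_tbl(runif(1, -5, 5), runif(1, -5, 5), runif(1, 0, 2 * pi))
    t <- edge_tbl(runif(1, -5, 5), runif(1, -5, 5), runif(1, 0, 2 * pi))
    if (sqrt((s$x - t$x)^2 + (s$y - t$y)^2) < 1e-6) next
    a <- runif(1, 0, 2 * pi)
    dx <- runif(1, -3, 3); dy <- runif(1, -3, 3)
    rot <- function(e) edge_tbl(cos(a) * e$x - sin(a) * e$y + dx,
                                sin(a) * e$x + cos(a) * e$y + dy,
                                e$theta + a)
    expect_equal(as.numeric(relative_coordinates(rot(s), rot(t))),
                 as.numeric(relative_coordinates(s, t)), tolerance = 1e-12)
  }
})

test_that("von Mises density is normalized, unimodal and sigma-scaled", {
  g <- seq(0, 2 * pi, length.out = 20001)
  for (s in c(0.05, 0.3, 1.5)) {
    d <- von_mises_density(g, mu = 1, sigma = s)
    integral <- sum((d[-1] + d[-length(d)]) / 2) * diff(g[1:2])
    expect_equal(integral, 1, tolerance = 1e-8)
    expect_equal(g[which.max(d)], 1, tolerance = 1e-3)
  }
  # peak-to-antimode ratio follows exp(2 kappa) with kappa = 1/sigma^2
  s <- 0.3
  expect_equal(von_mises_density(0, 0, s) / von_mises_density(pi, 0, s),
               exp(2 / s^2), tolerance = 1e-10)
  expect_error(von_mises_density(0, 0, -1), class = "afield_parameter_error")
})

test_that("angular AF part peaks at colinear continuation and is normalized", {
  p <- af_params(0.2, 0.4, 3)
  phi <- seq(-pi, pi, length.out = 721)
  a <- af_angular_density(phi, 0, p)
  expect_equal(phi[which.max(a)], 0, tolerance = 0.01)
  # monotone decrease in |dtheta| at phi = 0
  dth <- seq(0.01, pi - 0.01, length.out = 100)
  vals <- af_angular_density(0, dth, p)
  expect_true(all(diff(vals) < 0))
  # integral over (-pi, pi]^2 equals 1
  n <- 400
  g <- seq(-pi, pi, length.out = n + 1)[-1] - pi / n
  total <- mean(outer(g, g, function(u, v) af_angular_density(u, v, p))) *
    (2 * pi)^2
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("backward placement of the next edge is suppressed", {
  p <- af_params(0.2, 0.3, 3)
  # same direction, directly behind vs directly ahead
  ahead <- af_density(edge_tbl(0, 0, 0), edge_tbl(2, 0, 0), p)
  behind <- af_density(edge_tbl(0, 0, 0), edge_tbl(-2, 0, 0), p)
  expect_lt(behind / ahead, 1e-10)
})

test_that("AF density is reversal-symmetric and rigid-motion invariant", {
  set.seed(21)
  p <- af_params(0.25, 0.5, 2)
  n <- 1000
  s <- edge_tbl(runif(n, -5, 5), runif(n, -5, 5), runif(n, 0, 2 * pi))
  t <- edge_tbl(s$x + runif(n, 0.2, 4) * cos(runif(n, 0, 2 * pi)),
                s$y + runif(n, 0.2, 4) * sin(runif(n, 0, 2 * pi)),
                runif(n, 0, 2 * pi))
  fwd <- af_density(s, t, p)
  rev <- af_density(reverse_edges(t), reverse_edges(s), p)
  expect_equal(rev, fwd, tolerance = 1e-12)

  a <- 1.234
  rot <- function(e) edge_tbl(cos(a) * e$x - sin(a) * e$y + 0.7,
                              sin(a) * e$x + cos(a) * e$y - 1.1,
                              e$theta + a)
  expect_equal(af_density(rot(s), rot(t), p), fwd, tolerance = 1e-12)
})

test_that("small-sigma AF approaches a product of Gaussians", {
  s <- 0.05
  p <- af_params(s, s, 3)
  # Gaussian limit in the decoupled coordinates (phi - dtheta/2, dtheta):
  # scales sigma/2 and sigma respectively
  pts <- expand.grid(phi = c(0, 0.02, -0.03), dth = c(0, 0.03, -0.04))
  for (i in seq_len(nrow(pts))) {
    phi <- pts$phi[i]; dth <- pts$dth[i]
    gauss <- stats::dnorm(phi - dth / 2, 0, s / 2) * stats::dnorm(dth, 0, s)
    expect_equal(af_angular_density(phi, dth, p), gauss, tolerance = 0.01)
  }
})

test_that("AF parameter objects validate and serialize", {
  expect_error(af_params(-1, 0.3), class = "afield_parameter_error")
  expect_error(ecc_params(1.2, 1), class = "afield_parameter_error")
  p <- af_params(0.1, 0.2, 5)
  expect_equal(af_from_list(af_to_list(p)), p)
})
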