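test_that("multi-pore flux reduces to the single-pore law and its mass", {
  p1 <- planar_pore_set(circular_pore(c(0, 0), 1))
  tt <- c(0.5, 2, 10, 50)
  J1 <- planar_multi_pore_flux(tt, c(0, 0, 5), p1)
  ref <- single_pore_flux_cdf(tt, R = 5)
  expect_equal(drop(J1), ref$J, tolerance = 1e-12)

  # time integral equals the capacitance mass C/R (self-correction cancels)
  mass <- integrate(function(t) planar_multi_pore_flux(t, c(0, 0, 5), p1),
                    0, Inf, rel.tol = 1e-10)$value
  expect_equal(mass, (2 / pi) / 5, tolerance = 1e-8)

  # two identical pores equidistant from the release point: equal fluxes
  pair <- planar_pore_set(list(circular_pore(c(-3, 0), 1),
                               circular_pore(c(3, 0), 1)))
  Jp <- planar_multi_pore_flux(tt, c(0, 0, 2), pair)
  expect_equal(Jp[, 1], Jp[, 2], tolerance = 1e-14)

  # essential singularity at t -> 0+
  expect_equal(drop(planar_multi_pore_flux(1e-4, c(0, 0, 5), pair)),
               c(0, 0))
})

test_that("single-pore CDF integrates its density and has capacitance mass", {
  sp <- single_pore_flux_cdf(c(1e12, 0), R = 5)
  expect_equal(sp$F[1], (2 / pi) / 5, tolerance = 1e-5)
  expect_equal(sp$F[2], 0)
  for (Tend in c(1, 10, 100)) {
    quad <- integrate(function(t) single_pore_flux_cdf(t, R = 5)$J, 0, Tend,
                      rel.tol = 1e-12)$value
    expect_lt(abs(quad - single_pore_flux_cdf(Tend, R = 5)$F), 1e-8)
  }
})

test_that("two-disc capacitance series has the right limits and terms", {
  expect_equal(strieder_capacitance(1e9), 4 / pi, tolerance = 1e-8)
  d <- seq(4, 100, length.out = 200)
  expect_true(all(diff(strieder_capacitance(d)) > 0))
  # term-by-term independent evaluation at d = 8
  d0 <- 8
  terms <- c(1, -2 / (pi * d0), 4 / (pi^2 * d0^2),
             -2 * (12 + pi^2) / (3 * pi^3 * d0^3),
             16 * (3 + pi^2) / (3 * pi^4 * d0^4),
             -4 * (120 + 70 * pi^2 + 3 * pi^4) / (15 * pi^5 * d0^5))
  expect_equal(strieder_capacitance(8), 4 / pi * sum(terms), tolerance = 1e-15)
  expect_error(strieder_capacitance(2), "d > 2")
})

test_that("planar splitting probabilities: reductions and the six-pore ratio", {
  p1 <- planar_pore_set(circular_pore(c(0, 0), 0.5))
  expect_equal(planar_splitting_probabilities(c(3, 0, 4), p1),
               (2 * 0.5 / pi) / 5)

  pair <- planar_pore_set(list(circular_pore(c(-3, 0), 1),
                               circular_pore(c(3, 0), 1)))
  Q <- planar_splitting_probabilities(c(0, 1, 2), pair)
  expect_equal(Q[1], Q[2], tolerance = 1e-14)

  # six-pore configuration: desk evaluation of the printed two-term formula
  six <- six_pore_set()
  Q6 <- planar_splitting_probabilities(c(0, 0, 0), six)
  # independent term-by-term arithmetic for the large pore
  cs <- 2 * six$radii / pi
  Rk <- sqrt(rowSums(six$centers^2))
  d <- as.matrix(dist(cbind(six$centers, 0)))
  q_large <- cs[6] / Rk[6] - sum(cs[1:5] * cs[6] / (d[1:5, 6] * Rk[1:5]))
  expect_equal(Q6[6], q_large, tolerance = 1e-14)
  expect_equal(Q6[6] / sum(Q6[1:5]), 1.326027, tolerance = 1e-6)
})

test_that("homogenized Robin constant behaves asymptotically", {
  a51 <- function(s) sqrt(4 * s / 51)
  expect_lt(homogenized_kappa(1e-6, a51(1e-6)), 1e-2)
  sig <- seq(0.01, 0.2, length.out = 40)
  kap <- vapply(sig, function(s) homogenized_kappa(s, a51(s)), numeric(1))
  expect_true(all(diff(kap) > 0))
  # frozen value from independent evaluation of the printed formula
  s <- 0.1; a <- a51(0.1)
  ref <- 4 * s / (pi * a) /
    (1 - 4 / pi * sqrt(s) + a / pi * log(4 * exp(-0.5) * sqrt(s)))
  expect_equal(homogenized_kappa(s, a), ref, tolerance = 1e-15)
  expect_equal(ref, 2.437192, tolerance = 1e-6)
})

test_that("homogenized sphere flux is consistent and stable at small t", {
  k <- homogenized_kappa(0.1, sqrt(0.4 / 51))
  hs <- homogenized_sphere_flux_cdf(c(0, 1e12), R = 2.5, D = 1, kappa = k)
  expect_equal(hs$F[1], 0)
  expect_equal(hs$J[1], 0)
  expect_equal(hs$total, 1 / ((1 + 1 / k) * 2.5))
  expect_equal(hs$F[2], hs$total, tolerance = 1e-5)
  # J integrates to F
  quad <- integrate(function(t) homogenized_sphere_flux_cdf(t, 2.5, 1, k)$J,
                    0, 50, rel.tol = 1e-11)$value
  expect_lt(abs(quad - homogenized_sphere_flux_cdf(50, 2.5, 1, k)$F), 1e-8)
  # kappa -> infinity reduces to the fully absorbing sphere
  tt <- seq(0.01, 50, length.out = 200)
  expect_lt(max(abs(homogenized_sphere_flux_cdf(tt, 2.5, 1, 1e8)$F -
                    sphere_arrival_cdf(tt, 2.5, 1))), 1e-6)
  # no overflow at very small times (large beta)
  expect_true(all(is.finite(homogenized_sphere_flux_cdf(10^seq(-8, 0), 2.5,
                                                        1, k)$J)))
})

test_that("equivalent-sphere CDF has the capacitance limit", {
  expect_equal(equivalent_sphere_cdf(1e10, C = 0.6607, R0 = 5),
               0.6607 / 5, tolerance = 1e-4)
  tt <- seq(0.01, 100, length.out = 100)
  expect_true(all(diff(equivalent_sphere_cdf(tt, 0.6607, 5)) > 0))
})

test_that("exterior-sphere Green's function: value, decay, symmetry", {
  val <- exterior_sphere_green(c(1 + 1e-9, 0, 0), c(0, 0, 1))
  expect_equal(val, (1 / (2 * pi)) * (1 / sqrt(2) - 0.5 * log(1 + sqrt(2))),
               tolerance = 1e-6)
  # decay along a ray
  g <- vapply(c(2, 10, 100, 1000), function(r) {
    exterior_sphere_green(r * c(0.6, 0, 0.8), c(0, 0, 1))
  }, numeric(1))
  expect_true(all(diff(g) < 0))
  expect_lt(g[4], 1e-3)
  # invariant under rotations fixing xi
  set.seed(20)
  xi <- c(0, 0, 1)
  x <- c(1.7, 0.4, 0.9)
  for (i in 1:10) {
    ang <- runif(1, 0, 2 * pi)
    Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
                c(0, 0, 1))
    expect_equal(exterior_sphere_green(drop(Rz %*% x), xi),
                 exterior_sphere_green(x, xi), tolerance = 1e-12)
  }
  expect_error(exterior_sphere_green(c(0.5, 0, 0), xi), "outside")
})

test_that("sphere splitting probabilities: symmetry and leading order", {
  a <- 0.05
  cen <- rbind(c(1, 0, 0), c(-1, 0, 0))
  Q <- sphere_splitting_probabilities(c(0, 0, 3), cen, a)
  expect_equal(Q[1], Q[2], tolerance = 1e-12)
  Q1 <- sphere_splitting_probabilities(c(0, 0, 3), cen, a, order = 1)
  expect_equal(Q1[1], 4 * a * exterior_sphere_green(c(0, 0, 3), c(1, 0, 0)),
               tolerance = 1e-12)
  # second-order shielding reduces each probability
  expect_true(all(Q < Q1 + 4 * a^2 / pi * (1.5 - log(2 * a)) *
                        Q1 / (4 * a) + 1e-12))
})

test_that("coefficient of variation follows binomial sampling theory", {
  expect_equal(coefficient_of_variation(0.5, 100), 0.1)
  expect_equal(coefficient_of_variation(0.2, 1000) /
                 coefficient_of_variation(0.2, 4000), 2)
  expect_lt(coefficient_of_variation(1 - 1e-12, 100), 1e-5)
})
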