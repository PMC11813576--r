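test_that("plane-impact sampler inverts the first-passage CDF", {
  # fixed draw: t* solves erfc(z0 / (2 sqrt(D t))) = nu
  root <- uniroot(function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE) - 0.5,
                  c(0.1, 2), tol = 1e-14)$root
  imp <- sample_plane_impact(1, 1, draws = c(0.5, 0.3, 0.7))
  expect_equal(imp$t, 1 / (4 * root^2), tolerance = 1e-12)

  set.seed(10)
  n <- 1e5
  nu <- runif(n)
  t_star <- 1 / (4 * erfcinv(nu)^2)  # z0 = 1, D = 1
  ks <- ks_distance(t_star, function(t) {
    2 * pnorm(1 / (2 * sqrt(t)) * sqrt(2), lower.tail = FALSE)
  })
  expect_lt(ks, 0.01)

  # lateral displacements: mean zero at fixed t*
  t_fix <- 0.37
  dx <- vapply(1:2e4, function(i) sample_plane_impact(1, 1)$dx, numeric(1))
  expect_lt(abs(mean(dx)), 4 * sd(dx) / sqrt(length(dx)))
})

test_that("hemisphere exit CDF is consistent across its two series", {
  expect_equal(hemisphere_exit_cdf(0), 0)
  expect_lt(abs(hemisphere_exit_cdf(30) - 1), 1e-12)
  # both series evaluated independently at the switch point
  tau <- 1
  small <- 2 * sqrt(pi / tau) * sum(exp(-pi^2 * ((0:50) + 0.5)^2 / tau))
  large <- 1 + 2 * sum((-1)^(1:50) * exp(-(1:50)^2 * tau))
  expect_lt(abs(small - large), 1e-12)
  expect_equal(hemisphere_exit_cdf(1), large, tolerance = 1e-12)
  # monotone on a grid
  grid <- hemisphere_exit_cdf(seq(0.01, 10, length.out = 500))
  expect_true(all(diff(grid) > 0))
})

test_that("hemisphere exit sampler reproduces its tabulated law", {
  set.seed(11)
  R <- 2.5
  n <- 4e4
  pts <- matrix(0, n, 3)
  tv <- numeric(n)
  tab <- hemisphere_exit_table()
  for (i in 1:n) {
    s <- sample_hemisphere_exit(R, 1, tab)
    pts[i, ] <- s$point
    tv[i] <- s$t
  }
  expect_equal(sqrt(rowSums(pts^2)), rep(R, n), tolerance = 1e-9)
  expect_true(all(pts[, 3] >= 0))
  # z/R uniform on (0,1) (isotropic exit)
  expect_lt(ks_distance(pts[, 3] / R, function(z) pmin(1, pmax(0, z))), 0.01)
  # exit times follow the tabulated CDF
  expect_lt(ks_distance(tv * pi^2 / R^2, hemisphere_exit_cdf), 0.01)
})

test_that("exterior-sphere arrival CDF has the right mass and limits", {
  expect_equal(sphere_arrival_cdf(0, R = 2), 0)
  expect_equal(sphere_arrival_cdf(1e12, R = 2), 0.5, tolerance = 1e-4)
  tt <- seq(0.01, 100, length.out = 300)
  expect_true(all(diff(sphere_arrival_cdf(tt, R = 3)) > 0))
})

test_that("reinsertion time sampler escapes with probability 1 - 1/R", {
  set.seed(12)
  mu <- runif(1e6)
  out <- sample_reinsertion_time(mu, R = 3)
  p_esc <- mean(out$escaped)
  se <- sqrt((2 / 3) * (1 / 3) / 1e6)
  expect_lt(abs(p_esc - 2 / 3), 3 * se)
  # t* decreases (logarithmically) to 0 as mu -> 0+
  tsm <- sample_reinsertion_time(c(1e-300, 1e-12, 1e-6, 1e-2), R = 3)$t
  expect_true(all(diff(tsm) > 0))
  expect_lt(tsm[1], 2e-3)
  # non-escape times follow the arrival CDF rescaled to a conditional law
  tns <- out$t[!out$escaped]
  expect_lt(ks_distance(tns, function(t) 3 * sphere_arrival_cdf(t, 3, 1)),
            0.01)
})

test_that("polar-angle CDF is a proper CDF with the uniform large-time limit", {
  th <- seq(0, pi, length.out = 101)
  p <- polar_angle_cdf(th, t = 0.5, R = 3)
  expect_equal(p[1], 0)
  expect_equal(p[101], 1, tolerance = 1e-9)
  expect_true(all(diff(p) >= -1e-9))
  expect_lt(max(abs(polar_angle_cdf(th, t = 1e7, R = 3) - (1 - cos(th)) / 2)),
            1e-6)
  expect_error(polar_angle_cdf(th, t = 1e-4, R = 3), "t")
})

test_that("flux modes: chi_0 equals the closed-form arrival density", {
  Jex <- function(t, R, D = 1) {
    (R - 1) / (2 * R * sqrt(pi * D) * t^1.5) * exp(-(R - 1)^2 / (4 * D * t))
  }
  for (t in c(0.1, 0.5, 2, 10)) {
    expect_equal(chi_n(t, 0, R = 3), Jex(t, 3), tolerance = 1e-7)
  }
  # diffusivity scaling: chi(t; D) = D chi(D t; 1)
  expect_equal(chi_n(2, 0:3, R = 3, D = 0.5), 0.5 * chi_n(1, 0:3, R = 3),
               tolerance = 1e-7)
})

test_that("reinsertion table is monotone and matches the harmonic measure", {
  tab <- fixture("reins_small", function() {
    build_reinsertion_table(R = 3, n_mu = 80, n_nu = 80, cache = FALSE)
  })
  expect_true(all(tab$t_star > 0))
  expect_true(all(diff(tab$t_star) > 0))  # t* increasing in mu
  expect_true(all(tab$theta_star > 0 & tab$theta_star < pi))
  expect_true(all(apply(tab$theta_star, 1, function(r) all(diff(r) >= 0))))

  # marginal over capture of theta* equals the exterior-sphere harmonic
  # measure (Poisson kernel), an independent closed form
  set.seed(13)
  n <- 2e5
  mu <- runif(n, 0, 1 / 3)
  nu <- runif(n)
  i <- pmin(80, floor(mu * 3 * 80) + 1)
  j <- pmin(80, floor(nu * 80) + 1)
  th <- tab$theta_star[cbind(i, j)]
  expect_lt(ks_distance(th, function(x) hit_angle_cdf(x, 3)), 0.02)
})

test_that("reinsertion step conserves probability and respects geometry", {
  tab <- fixture("reins_small", function() {
    build_reinsertion_table(R = 3, n_mu = 80, n_nu = 80, cache = FALSE)
  })
  set.seed(15)
  center <- c(1, -2, 0)
  n <- 5000
  land_r <- numeric(0)
  azim <- numeric(0)
  esc <- 0
  for (i in 1:n) {
    st <- list(position = center + c(0, 0, 6), time = 1, status = "bulk")
    st <- apply_reinsertion(st, tab, center, Ra_effective = 1.5, D = 1)
    if (st$status == "escaped") esc <- esc + 1 else {
      d <- st$position - center
      land_r <- c(land_r, sqrt(sum(d^2)))
      azim <- c(azim, atan2(d[2], d[1]))
      expect_gt(st$time, 1)
    }
  }
  expect_equal(esc + length(land_r), n)  # escape + capture exhaust the law
  expect_equal(land_r, rep(2, length(land_r)), tolerance = 1e-9)
  se <- sqrt((2 / 3) * (1 / 3) / n)
  expect_lt(abs(esc / n - 2 / 3), 4 * se)
  expect_lt(ks_distance((azim + pi) / (2 * pi) * 2 * pi,
                        function(x) x / (2 * pi)), 0.03)

  # half-space variant reflects below-plane landings to the image point
  set.seed(16)
  plane_center <- c(0, 0, 0)
  for (i in 1:500) {
    st <- list(position = c(8, 0, 0), time = 0, status = "bulk")
    st <- apply_reinsertion(st, tab, plane_center, Ra_effective = 2, D = 1,
                            halfspace = TRUE)
    if (st$status != "escaped") expect_gte(st$position[3], 0)
  }
  expect_error(apply_reinsertion(list(position = c(0, 0, 2), time = 0,
                                      status = "bulk"),
                                 tab, plane_center, Ra_effective = 2),
               "gating")
})

test_that("plane projection composes through an intermediate sphere exit", {
  # strong Markov property: stopping first on a sphere of radius r < z0 and
  # then projecting to the plane must reproduce the direct plane-impact law
  set.seed(17)
  n <- 1e5
  z0 <- 2; r <- 1; D <- 1
  tab <- hemisphere_exit_table()
  direct_t <- z0^2 / (4 * D * erfcinv(runif(n))^2)
  direct_x <- rnorm(n, 0, sqrt(2 * D * direct_t))

  # full-sphere exit: same radial law as the hemisphere propagator, with the
  # exit point isotropic on the whole sphere
  xi <- runif(n)
  tau <- ifelse(xi > 1 - 1e-3, log(2 / (1 - xi)),
                approx(tab$cdf, tab$tau, xout = xi, rule = 2,
                       ties = "ordered")$y)
  t1 <- r^2 * tau / (D * pi^2)
  zeta <- runif(n, -1, 1)
  eta <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - zeta^2)
  x1 <- r * s * cos(eta); z1 <- z0 + r * zeta
  t2 <- z1^2 / (4 * D * erfcinv(runif(n))^2)
  comp_t <- t1 + t2
  comp_x <- x1 + rnorm(n, 0, sqrt(2 * D * t2))

  ks_t <- suppressWarnings(ks.test(direct_t, comp_t)$statistic)
  ks_x <- suppressWarnings(ks.test(direct_x, comp_x)$statistic)
  expect_lt(ks_t, 0.02)
  expect_lt(ks_x, 0.02)
})
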