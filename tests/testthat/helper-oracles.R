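# Shared fixtures and independent oracles for the test suite.
# Expensive objects (meshes, tables) are built once per session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# six-pore benchmark configuration: five small pores on the unit circle plus
# one large distant pore
six_pore_set <- function() {
  fixture("six_pores", function() {
    th <- pi / 2 + (0:4) * pi / 4
    pores <- lapply(th, function(t) circular_pore(c(cos(t), sin(t)), 0.01))
    pores[[6]] <- circular_pore(c(15, 0), 1.0)
    planar_pore_set(pores)
  })
}

# closed-form harmonic measure (Poisson kernel) of the unit sphere seen from
# distance R: conditional-on-capture CDF of the polar angle of the hit point
hit_angle_cdf <- function(theta, R) {
  u <- cos(theta)
  f <- function(u) 1 / sqrt(R^2 - 2 * R * u + 1)
  (f(1) - f(u)) / (f(1) - f(-1))
}

# one-sample Kolmogorov-Smirnov distance against a CDF
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}

# brute-force signed distance to a planar pore set
brute_distance <- function(point, centers, radii) {
  min(sqrt((centers[, 1] - point[1])^2 + (centers[, 2] - point[2])^2) - radii)
}

# brute-force smallest enclosing ball radius of <= 10 points via subsets
brute_min_ball_radius <- function(pts) {
  n <- nrow(pts)
  best <- Inf
  contains <- function(c0, r) {
    all(sqrt(colSums((t(pts) - c0)^2)) <= r + 1e-9)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    c0 <- (pts[i, ] + pts[j, ]) / 2
    r <- sqrt(sum((pts[i, ] - c0)^2))
    if (contains(c0, r)) best <- min(best, r)
  }
  # spheres through 3 and 4 points, via least-squares circumcentres
  idx <- utils::combn(n, 3)
  for (k in seq_len(ncol(idx))) {
    tri <- pts[idx[, k], ]
    A <- 2 * rbind(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    # circumcentre constrained to the triangle plane
    nrm <- c(
      (tri[2, ] - tri[1, ])[2] * (tri[3, ] - tri[1, ])[3] - (tri[2, ] - tri[1, ])[3] * (tri[3, ] - tri[1, ])[2],
      (tri[2, ] - tri[1, ])[3] * (tri[3, ] - tri[1, ])[1] - (tri[2, ] - tri[1, ])[1] * (tri[3, ] - tri[1, ])[3],
      (tri[2, ] - tri[1, ])[1] * (tri[3, ] - tri[1, ])[2] - (tri[2, ] - tri[1, ])[2] * (tri[3, ] - tri[1, ])[1])
    M <- rbind(A, nrm)
    b <- c(sum(tri[2, ]^2) - sum(tri[1, ]^2), sum(tri[3, ]^2) - sum(tri[1, ]^2),
           sum(nrm * tri[1, ]))
    c0 <- tryCatch(solve(M, b), error = function(e) NULL)
    if (!is.null(c0)) {
      r <- sqrt(sum((tri[1, ] - c0)^2))
      if (contains(c0, r)) best <- min(best, r)
    }
  }
  if (n >= 4) {
    idx <- utils::combn(n, 4)
    for (k in seq_len(ncol(idx))) {
      qd <- pts[idx[, k], ]
      A <- 2 * rbind(qd[2, ] - qd[1, ], qd[3, ] - qd[1, ], qd[4, ] - qd[1, ])
      b <- c(sum(qd[2, ]^2) - sum(qd[1, ]^2), sum(qd[3, ]^2) - sum(qd[1, ]^2),
             sum(qd[4, ]^2) - sum(qd[1, ]^2))
      c0 <- tryCatch(solve(A, b), error = function(e) NULL)
      if (!is.null(c0)) {
        r <- sqrt(sum((qd[1, ] - c0)^2))
        if (contains(c0, r)) best <- min(best, r)
      }
    }
  }
  best
}

# random rotation matrix (uniform via QR of Gaussians)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
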