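test_that("signed distance to planar pore sets matches brute force", {
  p1 <- planar_pore_set(circular_pore(c(0, 0), 1))
  expect_equal(as.numeric(distance_to_absorbing_set(c(0, 0, 0), p1)), -1)
  expect_equal(as.numeric(distance_to_absorbing_set(c(2, 0, 0), p1)), 1)

  six <- six_pore_set()
  expect_equal(as.numeric(distance_to_absorbing_set(c(0, 0, 0), six)), 0.99)

  set.seed(1)
  for (i in 1:200) {
    pt <- runif(2, -20, 20)
    expect_equal(as.numeric(distance_to_absorbing_set(c(pt, 0), six)),
                 brute_distance(pt, six$centers, six$radii))
  }

  empty <- planar_pore_set(list(), dummy_disc_radius = 3)
  expect_error(distance_to_absorbing_set(c(0, 0, 0), empty), "no absorbers")
})

test_that("enclosing disc covers every pore and honors the scale factor", {
  p1 <- planar_pore_set(circular_pore(c(0, 0), 1))
  d <- enclosing_disc(p1, factor = 3)
  expect_equal(d$center, c(0, 0))
  expect_equal(d$radius, 3)

  pair <- planar_pore_set(list(circular_pore(c(-4, 0), 1),
                               circular_pore(c(4, 0), 1)))
  expect_equal(enclosing_disc(pair, 3)$radius, 3 * 5)

  six <- six_pore_set()
  d <- enclosing_disc(six, 1)
  reach <- sqrt((six$centers[, 1] - d$center[1])^2 +
                (six$centers[, 2] - d$center[2])^2) + six$radii
  expect_true(all(reach <= d$radius + 1e-9))
  # minimality: shrinking by any margin loses containment
  expect_false(all(reach <= d$radius * (1 - 1e-6)))
})

test_that("pore sets reject overlapping pores", {
  expect_error(planar_pore_set(list(circular_pore(c(0, 0), 1),
                                    circular_pore(c(1.5, 0), 1))),
               "overlap")
})

test_that("target face selection maximizes the signed distance", {
  cube <- build_cube(1)
  sel <- select_target_face(c(0, 0, 5), cube)
  expect_equal(sel$distance, 4.5)
  expect_equal(cube$normals[sel$face, ], c(0, 0, 1))

  # equidistant from two face planes: deterministic lowest-index tie-break
  sel_edge <- select_target_face(c(5, 0, 5), cube)
  sd <- drop(cube$normals %*% c(5, 0, 5)) - cube$offsets
  ties <- which(abs(sd - max(sd)) < 1e-12)
  expect_gte(length(ties), 2)
  expect_equal(sel_edge$face, min(ties))

  expect_error(select_target_face(c(0, 0, 0), cube), "inside")

  # exhaustive-scan oracle + separation property on random exterior points
  set.seed(2)
  ico <- build_sphere_mesh(0, n_vertices = 162)
  for (i in 1:100) {
    p <- rnorm(3)
    p <- p / sqrt(sum(p^2)) * runif(1, 1.05, 6)
    sel <- select_target_face(p, ico)
    sd <- drop(ico$normals %*% p) - ico$offsets
    expect_equal(sel$distance, max(sd))
    # the chosen plane separates the point from every vertex
    n <- ico$normals[sel$face, ]
    expect_true(all(ico$vertices %*% n - ico$offsets[sel$face] <= 1e-9))
    expect_gt(sum(n * p) - ico$offsets[sel$face], 0)
  }
})

test_that("polygon membership and inscribed radius are exact on faces", {
  cube <- build_cube(1)
  f <- select_target_face(c(0, 0, 5), cube)$face
  centroid <- colMeans(cube$vertices[cube$faces[[f]], ])
  expect_true(point_in_face(centroid, cube, f))
  expect_false(point_in_face(centroid + c(1, 0, 0), cube, f))
  # boundary (edge midpoint) counts as inside
  v <- cube$vertices[cube$faces[[f]], ]
  expect_true(point_in_face((v[1, ] + v[2, ]) / 2, cube, f))

  expect_equal(largest_inscribed_radius(centroid, cube, f), 0.5)
  expect_error(largest_inscribed_radius(centroid + c(1, 0, 0), cube, f),
               "outside")

  # equilateral triangle: centroid inradius s / (2 sqrt(3))
  s <- 2
  tri_v <- rbind(c(0, 0, 0), c(s, 0, 0), c(s / 2, s * sqrt(3) / 2, 0),
                 c(s / 2, s * sqrt(3) / 6, 1))
  tet <- convex_polyhedron(tri_v, list(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4),
                                       c(3, 1, 4)),
                           absorber = c(1L, 0L, 0L, 0L))
  cen <- colMeans(tri_v[1:3, ])
  expect_equal(largest_inscribed_radius(cen, tet, 1), s / (2 * sqrt(3)),
               tolerance = 1e-12)

  # random interior points: min point-segment distance over edges, and a
  # disc of the returned radius stays inside the face
  set.seed(3)
  for (i in 1:50) {
    w <- runif(4); w <- w / sum(w)
    p <- drop(w %*% cube$vertices[cube$faces[[f]], ])
    r <- largest_inscribed_radius(p, cube, f)
    edges <- cube$vertices[cube$faces[[f]], ]
    dref <- Inf
    for (k in 1:4) {
      a <- edges[k, ]; b <- edges[if (k == 4) 1 else k + 1, ]
      tt <- max(0, min(1, sum((p - a) * (b - a)) / sum((b - a)^2)))
      dref <- min(dref, sqrt(sum((p - a - tt * (b - a))^2)))
    }
    expect_equal(r, dref)
    for (ang in seq(0, 2 * pi, length.out = 13)) {
      q <- p + (r - 1e-12) * c(cos(ang), sin(ang), 0)
      expect_true(point_in_face(q, cube, f))
    }
  }
})

test_that("fibonacci sphere points are unit quasi-uniform vectors", {
  expect_equal(sqrt(sum(fibonacci_sphere_points(1)^2)), 1)
  pts <- fibonacci_sphere_points(51)
  expect_equal(sqrt(rowSums(pts^2)), rep(1, 51))
  d <- as.matrix(dist(pts)); diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_lt((max(nn) - min(nn)) / mean(nn), 0.25)
})

test_that("cube builder produces a watertight all-absorbing cube", {
  cube <- build_cube(1)
  expect_equal(length(cube$faces), 6)
  expect_equal(cube$enclosing_ball_radius, sqrt(3) / 2, tolerance = 1e-12)
  for (f in seq_len(6)) {
    fc <- colMeans(cube$vertices[cube$faces[[f]], ])
    expect_gt(sum(cube$normals[f, ] * fc), 0)  # outward
  }
  # watertightness is enforced by the constructor; removing a face breaks it
  expect_error(convex_polyhedron(cube$vertices, cube$faces[-1],
                                 cube$absorber[-1]),
               "watertight")
})

test_that("sphere meshes resolve the prescribed absorbing fraction", {
  sigma <- 0.1; N <- 51; a <- sqrt(4 * sigma / N)
  dev <- sapply(c(642, 2562, 10242), function(nv) {
    m <- fixture(paste0("sph51_", nv),
                 function() build_sphere_mesh(N, a, n_vertices = nv))
    abs(attr(m, "realized_sigma") - sigma)
  })
  expect_lt(dev[2], 0.15 * sigma)  # within 15 percent at ~2.5k vertices
  expect_true(dev[3] < dev[1])     # refinement shrinks the discrepancy
  expect_lt(dev[3], 0.05 * sigma)

  m <- fixture("sph51_2562", function() build_sphere_mesh(N, a, 2562))
  expect_equal(sort(unique(m$absorber[m$absorber > 0])), 1:51)
  expect_equal(length(m$faces), 5120)
  # all vertices on the unit sphere
  expect_equal(max(abs(sqrt(rowSums(m$vertices^2)) - 1)), 0, tolerance = 1e-12)

  refl <- build_sphere_mesh(0, n_vertices = 162)
  expect_true(all(refl$absorber == 0))
  expect_error(build_sphere_mesh(5, 1.2, 642), "overlap")
})

test_that("ellipsoid meshes span cylinder to oblate skirt", {
  cyl <- build_ellipsoid_mesh(1, n_azimuth = 32, n_rings = 7)
  r_lateral <- sqrt(cyl$vertices[, 1]^2 + cyl$vertices[, 2]^2)
  expect_equal(max(abs(r_lateral - 1)), 0, tolerance = 1e-12)
  expect_equal(range(cyl$vertices[, 3]), c(-1, 1))
  expect_equal(cyl$absorber_names, c("top", "bottom"))

  obl <- build_ellipsoid_mesh(8, n_azimuth = 32, n_rings = 7)
  expect_equal(max(sqrt(obl$vertices[, 1]^2 + obl$vertices[, 2]^2)), 8,
               tolerance = 1e-6)
  # symmetric under z -> -z
  v <- obl$vertices
  vflip <- cbind(v[, 1], v[, 2], -v[, 3])
  match_dist <- max(apply(vflip, 1, function(p) {
    min(sqrt(colSums((t(v) - p)^2)))
  }))
  expect_lt(match_dist, 1e-9)
  # pore discs at z = +-1 with unit radius, flagged top/bottom
  topf <- which(obl$absorber == 1L)
  expect_equal(length(topf), 1L)
  expect_equal(unique(obl$vertices[obl$faces[[topf]], 3]), 1)
  expect_error(build_ellipsoid_mesh(0.5), "at least 1")
})

test_that("smallest enclosing ball is exact against subset enumeration", {
  set.seed(4)
  for (i in 1:20) {
    pts <- matrix(rnorm(24), 8, 3)
    ball <- kmcapture:::cpp_min_ball(pts)
    expect_equal(ball[4], brute_min_ball_radius(pts), tolerance = 1e-7)
    expect_true(all(sqrt(colSums((t(pts) - ball[1:3])^2)) <= ball[4] + 1e-9))
  }
})

test_that("convexity validation names the violating vertex", {
  cube <- build_cube(1)
  v <- cube$vertices
  v[1, ] <- v[1, ] * 1.5  # dent outward
  expect_error(convex_polyhedron(v, cube$faces, cube$absorber),
               "planar|convex")
})

test_that("tangential relaxation keeps vertices on the sphere and spreads them", {
  set.seed(5)
  z <- runif(40, -1, 1); ph <- runif(40, 0, 2 * pi)
  v <- cbind(sqrt(1 - z^2) * cos(ph), sqrt(1 - z^2) * sin(ph), z)
  energy <- function(m) {
    d <- as.matrix(dist(m)); diag(d) <- Inf; sum(1 / d[upper.tri(d)])
  }
  vr <- relax_sphere_mesh(v, iterations = 200)
  expect_equal(max(abs(sqrt(rowSums(vr^2)) - 1)), 0, tolerance = 1e-12)
  expect_lt(energy(vr), energy(v))
  # fixed vertices do not move
  fixed <- c(rep(1L, 5), rep(0L, 35))
  vf <- relax_sphere_mesh(v, fixed = fixed, iterations = 50)
  expect_equal(vf[1:5, ], unname(v[1:5, ]))
})
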