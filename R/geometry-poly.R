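#' Convex polyhedron with absorbing and reflecting faces
#'
#' The exterior-domain simulator targets a closed convex polyhedron whose
#' planar faces are flagged absorbing (each with an absorber id, so splitting
#' probabilities can be resolved per receptor) or reflecting.  The
#' constructor validates coplanarity of each face, convexity of the body,
#' and watertightness (every edge shared by exactly two faces), orients all
#' normals outward, and precomputes the smallest ball `Ra` bounding the
#' absorbing faces together with the face-adjacency graph used by the
#' simulation core.
#'
#' @param vertices numeric matrix (V x 3) of vertex coordinates.
#' @param faces list of integer vectors, each an ordered ring of vertex
#'   indices (1-based) forming a planar convex polygon.
#' @param absorber integer vector, one entry per face: 0 for reflecting,
#'   k >= 1 for absorbing with absorber id k.
#' @param absorber_names optional character vector naming the absorber ids.
#' @param validate set to `FALSE` to skip the (O(V F)) validation checks for
#'   meshes produced by the package's own builders.
#' @return an object of class `convex_polyhedron`.
#' @export
convex_polyhedron <- function(vertices, faces, absorber,
                              absorber_names = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 3L, length(faces) == length(absorber))
  absorber <- as.integer(absorber)
  nf <- length(faces)
  ctr <- colMeans(vertices)
  diam <- 2 * sqrt(max(rowSums(sweep(vertices, 2, ctr)^2)))
  tol <- 1e-10 * diam

  normals <- matrix(0, nf, 3)
  offsets <- numeric(nf)
  for (f in seq_len(nf)) {
    idx <- faces[[f]]
    if (length(idx) < 3L) stop("face ", f, " has fewer than 3 vertices")
    v <- vertices[idx, , drop = FALSE]
    # Newell's method: robust polygon normal
    nxt <- v[c(2:nrow(v), 1L), , drop = FALSE]
    n <- c(sum((v[, 2] - nxt[, 2]) * (v[, 3] + nxt[, 3])),
           sum((v[, 3] - nxt[, 3]) * (v[, 1] + nxt[, 1])),
           sum((v[, 1] - nxt[, 1]) * (v[, 2] + nxt[, 2])))
    nn <- sqrt(sum(n^2))
    if (nn <= 0) stop("face ", f, " is degenerate")
    n <- n / nn
    fc <- colMeans(v)
    if (sum(n * (fc - ctr)) < 0) {  # orient outward, into the bulk
      faces[[f]] <- rev(idx)
      n <- -n
    }
    normals[f, ] <- n
    offsets[f] <- sum(n * fc)
    if (validate) {
      dev <- abs(v %*% n - offsets[f])
      if (max(dev) > tol) {
        stop("face ", f, " is not planar (deviation ", signif(max(dev), 3), ")")
      }
    }
  }

  if (validate) {
    # convexity: every vertex on the inner side of every face plane
    sd <- vertices %*% t(normals) - rep(offsets, each = nrow(vertices))
    if (max(sd) > tol) {
      bad <- which(sd == max(sd), arr.ind = TRUE)[1L, ]
      stop("body is not convex: vertex ", bad[1L],
           " lies outside the plane of face ", bad[2L])
    }
    # watertightness: each undirected edge in exactly two faces
    ecount <- edge_table(faces, nrow(vertices))
    if (any(ecount != 2L)) {
      stop("mesh is not watertight: ", sum(ecount != 2L),
           " edge(s) not shared by exactly two faces")
    }
  }

  adj <- face_adjacency(faces, nrow(vertices))
  abs_faces <- which(absorber > 0L)
  ball_pts <- if (length(abs_faces) > 0L) {
    vertices[unique(unlist(faces[abs_faces])), , drop = FALSE]
  } else {
    vertices
  }
  ball <- cpp_min_ball(ball_pts)

  # the reinsertion landing sphere must enclose the whole body, not just the
  # absorbing set, so the gate uses the larger of the two radii
  body_r <- sqrt(max(rowSums(sweep(vertices, 2, ball[1:3])^2)))
  structure(list(vertices = vertices, faces = faces, normals = normals,
                 offsets = offsets, absorber = absorber,
                 absorber_names = absorber_names,
                 adjacency = adj,
                 enclosing_ball_center = ball[1:3],
                 enclosing_ball_radius = ball[4L],
                 gating_ball_radius = max(ball[4L], body_r),
                 tol = tol),
            class = "convex_polyhedron")
}

#' @export
print.convex_polyhedron <- function(x, ...) {
  cat("convex_polyhedron:", nrow(x$vertices), "vertices,",
      length(x$faces), "faces (", sum(x$absorber > 0), "absorbing )\n")
  cat("  enclosing ball of absorbing set: radius",
      format(x$enclosing_ball_radius, digits = 6), "\n")
  invisible(x)
}

# undirected edge multiplicities
edge_table <- function(faces, nv) {
  a <- unlist(lapply(faces, function(idx) idx))
  b <- unlist(lapply(faces, function(idx) idx[c(2:length(idx), 1L)]))
  key <- pmin(a, b) * (nv + 1) + pmax(a, b)
  table(key)
}

# faces sharing an edge, as a list of integer vectors
face_adjacency <- function(faces, nv) {
  fid <- rep(seq_along(faces), lengths(faces))
  a <- unlist(lapply(faces, function(idx) idx))
  b <- unlist(lapply(faces, function(idx) idx[c(2:length(idx), 1L)]))
  key <- pmin(a, b) * (nv + 1) + pmax(a, b)
  o <- order(key)
  key <- key[o]; fid <- fid[o]
  # edges come in pairs after sorting
  first <- seq(1L, length(key), by = 2L)
  if (any(key[first] != key[first + 1L])) stop("edge pairing failed")
  f1 <- fid[first]; f2 <- fid[first + 1L]
  adj <- vector("list", length(faces))
  pairs <- split(c(f2, f1), c(f1, f2))
  for (nm in names(pairs)) adj[[as.integer(nm)]] <- sort(unique(pairs[[nm]]))
  adj
}

#' Select the target face plane for a bulk point
#'
#' Returns the face whose plane has the largest positive signed distance to
#' the point; this plane separates the point from the whole body, so the
#' planar propagator applied to it is exact.  Ties are broken toward the
#' lowest face index.
#'
#' @param point numeric length-3 position strictly outside the body.
#' @param poly a [convex_polyhedron()].
#' @return list with `face` (index) and `distance` (> 0).
#' @export
select_target_face <- function(point, poly) {
  stopifnot(inherits(poly, "convex_polyhedron"), length(point) == 3L)
  sd <- drop(poly$normals %*% point) - poly$offsets
  f <- which.max(sd)
  if (sd[f] <= 0) stop("point is inside or on the body: no separating face plane")
  list(face = f, distance = sd[f])
}

#' Convex polygon membership test for a point on a face plane
#'
#' The polygon boundary counts as inside, so a trajectory landing exactly on
#' an edge of an absorbing face terminates deterministically.
#'
#' @param point numeric length-3 point on the face's plane (within tolerance).
#' @param poly a [convex_polyhedron()].
#' @param face face index.
#' @return logical.
#' @export
point_in_face <- function(point, poly, face) {
  v <- poly$vertices[poly$faces[[face]], , drop = FALSE]
  n <- poly$normals[face, ]
  nv <- nrow(v)
  for (i in seq_len(nv)) {
    a <- v[i, ]; b <- v[if (i == nv) 1L else i + 1L, ]
    e <- b - a; w <- point - a
    cr <- c(e[2] * w[3] - e[3] * w[2], e[3] * w[1] - e[1] * w[3],
            e[1] * w[2] - e[2] * w[1])
    if (sum(cr * n) < -poly$tol) return(FALSE)
  }
  TRUE
}

#' Largest hemisphere base radius inside a face
#'
#' For a point strictly inside a face, the radius of the largest circle
#' centred at the point whose disc stays within the face: the minimum
#' distance from the point to the face's edges.
#'
#' @inheritParams point_in_face
#' @return positive length.
#' @export
largest_inscribed_radius <- function(point, poly, face) {
  if (!point_in_face(point, poly, face)) stop("point lies outside the face")
  v <- poly$vertices[poly$faces[[face]], , drop = FALSE]
  nv <- nrow(v)
  dmin <- Inf
  for (i in seq_len(nv)) {
    a <- v[i, ]; b <- v[if (i == nv) 1L else i + 1L, ]
    e <- b - a
    L2 <- sum(e^2)
    w <- if (L2 > 0) max(0, min(1, sum((point - a) * e) / L2)) else 0
    dmin <- min(dmin, sqrt(sum((point - (a + w * e))^2)))
  }
  dmin
}

#' Fibonacci spiral points on the unit sphere
#'
#' Deterministic quasi-uniform point set used to centre absorbing windows on
#' the sphere.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- (i - 1) * golden
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Unit cube target
#'
#' Axis-aligned cube centred at the origin with all six faces absorbing
#' (absorber ids 1..6), the standard capacitance benchmark geometry.
#'
#' @param side edge length.
#' @return a [convex_polyhedron()].
#' @export
build_cube <- function(side = 1) {
  stopifnot(side > 0)
  s <- side / 2
  v <- as.matrix(expand.grid(x = c(-s, s), y = c(-s, s), z = c(-s, s)))
  dimnames(v) <- NULL
  # rings ordered CCW seen from outside; constructor re-orients if needed
  faces <- list(c(1L, 3L, 4L, 2L),  # z = -s
                c(5L, 6L, 8L, 7L),  # z = +s
                c(1L, 2L, 6L, 5L),  # y = -s
                c(3L, 7L, 8L, 4L),  # y = +s
                c(1L, 5L, 7L, 3L),  # x = -s
                c(2L, 4L, 8L, 6L))  # x = +s
  convex_polyhedron(v, faces, absorber = 1:6)
}

# icosahedron subdivided `level` times, vertices projected to the unit sphere
icosphere <- function(level) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    nv <- nrow(v)
    key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
    e <- unique(c(key(f[, 1], f[, 2]), key(f[, 2], f[, 3]), key(f[, 3], f[, 1])))
    mid_of <- function(k) {
      a <- k %/% (nv + 1); b <- k %% (nv + 1)
      m <- v[a, , drop = FALSE] + v[b, , drop = FALSE]
      m / sqrt(rowSums(m^2))
    }
    mids <- mid_of(e)
    v <- rbind(v, mids)
    m12 <- nv + match(key(f[, 1], f[, 2]), e)
    m23 <- nv + match(key(f[, 2], f[, 3]), e)
    m31 <- nv + match(key(f[, 3], f[, 1]), e)
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  dimnames(f) <- NULL
  list(vertices = v, faces = f)
}

#' Triangulated sphere with circular absorbing windows
#'
#' Builds a convex triangulation of the unit sphere by icosahedral
#' subdivision (chosen to the requested vertex count) and flags each facet
#' absorbing when its centroid falls inside one of `n_pores` spherical caps
#' of angular radius `pore_radius` centred at the Fibonacci spiral points.
#' Optionally the vertices are first relaxed by projected gradient descent on
#' the repulsive reciprocal-pairwise-distance energy (see
#' [relax_sphere_mesh()]); the icosahedral vertex set is already
#' quasi-uniform, so relaxation defaults to off.
#'
#' @param n_pores number of circular windows (0 gives a fully reflecting
#'   sphere).
#' @param pore_radius common angular pore radius `a`; with area fraction
#'   `sigma = n_pores * a^2 / 4`, use `a = sqrt(4 * sigma / n_pores)`.
#' @param n_vertices requested mesh resolution; rounded up to the next
#'   icosahedral subdivision (10 * 4^k + 2 vertices).
#' @param seed unused by the deterministic construction; accepted for call
#'   compatibility with stochastic mesh generators.
#' @param relax_iterations iterations of tangential energy relaxation (0 to
#'   skip).
#' @return a [convex_polyhedron()] with attribute `realized_sigma`, the
#'   absorbing facet-area fraction actually achieved.
#' @export
build_sphere_mesh <- function(n_pores, pore_radius = NULL, n_vertices = 2562,
                              seed = NULL, relax_iterations = 0) {
  level <- max(1, ceiling(log((n_vertices - 2) / 10) / log(4)))
  ico <- icosphere(level)
  v <- ico$vertices
  centers <- NULL
  if (n_pores > 0) {
    stopifnot(pore_radius > 0)
    centers <- fibonacci_sphere_points(n_pores)
    if (n_pores > 1) {
      cosang <- tcrossprod(centers)
      diag(cosang) <- -1
      min_geodesic <- acos(max(pmin(1, pmax(-1, cosang))))
      if (min_geodesic <= 2 * pore_radius) {
        stop("pores overlap: pairwise geodesic centre distance must exceed 2 * pore_radius")
      }
    }
  }
  if (relax_iterations > 0) {
    v <- cpp_relax_sphere_mesh(v, integer(nrow(v)), as.integer(relax_iterations),
                               1 / nrow(v)^2)
  }
  f <- ico$faces
  cen <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  cen <- cen / sqrt(rowSums(cen^2))
  absorber <- integer(nrow(f))
  if (n_pores > 0) {
    theta <- acos(pmax(-1, pmin(1, cen[, 3])))
    psi <- atan2(cen[, 2], cen[, 1])
    thk <- acos(pmax(-1, pmin(1, centers[, 3])))
    psk <- atan2(centers[, 2], centers[, 1])
    for (k in seq_len(n_pores)) {
      dps <- (psi - psk[k] + pi) %% (2 * pi) - pi
      inside <- (theta - thk[k])^2 + sin(thk[k])^2 * dps^2 <= pore_radius^2
      absorber[inside & absorber == 0L] <- k
    }
  }
  poly <- convex_polyhedron(v, lapply(seq_len(nrow(f)), function(i) f[i, ]),
                            absorber, validate = FALSE)
  # realized absorbing area fraction
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  attr(poly, "realized_sigma") <- sum(area[absorber > 0]) / sum(area)
  attr(poly, "pore_centers") <- centers
  poly
}

#' Tangential relaxation of sphere-mesh vertices
#'
#' Projected gradient descent on the repulsive energy
#' \eqn{\sum_{i<j} 1/|x_i - x_j|}, with every step re-projected to the unit
#' sphere; vertices flagged `fixed` do not move.  A fixed iteration budget is
#' used (no line search).
#'
#' @param vertices V x 3 matrix of unit vectors.
#' @param fixed logical/integer vector of length V; nonzero entries are held.
#' @param iterations gradient steps (default 500).
#' @param step step size; defaults to `1 / V^2` so the net displacement per
#'   sweep is O(1) mesh spacings.
#' @return relaxed V x 3 matrix of unit vectors.
#' @export
relax_sphere_mesh <- function(vertices, fixed = integer(nrow(vertices)),
                              iterations = 500, step = 1 / nrow(vertices)^2) {
  cpp_relax_sphere_mesh(as.matrix(vertices), as.integer(fixed != 0),
                        as.integer(iterations), step)
}

#' Oblate ellipsoid with polar pores
#'
#' A family of convex bodies with two flat absorbing unit discs in the planes
#' z = +1 ("top", absorber 1) and z = -1 ("bottom", absorber 2) joined by a
#' reflecting skirt of equatorial radius `Req >= 1`.  At `Req = 1` the skirt
#' is a circular cylinder; for larger `Req` it is the oblate spheroid through
#' the pore rims, i.e. radius \eqn{r(z) = R_{eq}\sqrt{1 - z^2/c^2}} with
#' \eqn{c^2 = R_{eq}^2/(R_{eq}^2-1)}.  Each pore disc is a single polygonal
#' face; the skirt is a ring of planar trapezoids.
#'
#' @param Req equatorial (skirt) radius, at least 1.
#' @param n_azimuth azimuthal segments (polygon order of the pore discs).
#' @param n_rings interior latitude rings describing the skirt profile.
#' @return a [convex_polyhedron()] with `absorber_names = c("top", "bottom")`.
#' @export
build_ellipsoid_mesh <- function(Req, n_azimuth = 48, n_rings = 9) {
  if (n_rings %% 2 == 0) n_rings <- n_rings + 1L  # keep an equatorial ring at z = 0
  if (Req < 1) stop("Req must be at least 1 (pores have unit radius)")
  zs <- seq(1, -1, length.out = n_rings + 2)
  radius_at <- function(z) {
    if (Req == 1) rep(1, length(z)) else {
      c2 <- Req^2 / (Req^2 - 1)
      Req * sqrt(pmax(0, 1 - z^2 / c2))
    }
  }
  ang <- 2 * pi * (seq_len(n_azimuth) - 1) / n_azimuth
  verts <- NULL
  ring_idx <- list()
  for (j in seq_along(zs)) {
    r <- radius_at(zs[j])
    ring <- cbind(r * cos(ang), r * sin(ang), zs[j])
    ring_idx[[j]] <- nrow(verts %||% matrix(0, 0, 3)) + seq_len(n_azimuth)
    verts <- rbind(verts, ring)
  }
  faces <- list(ring_idx[[1L]], rev(ring_idx[[length(zs)]]))
  absorber <- c(1L, 2L)
  for (j in seq_len(length(zs) - 1L)) {
    top <- ring_idx[[j]]; bot <- ring_idx[[j + 1L]]
    for (i in seq_len(n_azimuth)) {
      i2 <- if (i == n_azimuth) 1L else i + 1L
      faces[[length(faces) + 1L]] <- c(top[i], top[i2], bot[i2], bot[i])
      absorber <- c(absorber, 0L)
    }
  }
  convex_polyhedron(verts, faces, absorber,
                    absorber_names = c("top", "bottom"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
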