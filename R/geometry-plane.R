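#' Circular absorbing pore on the plane z = 0
#'
#' A pore is a flat disc on the reflecting plane bounding the upper
#' half-space.  Its capacitance defaults to the known value for a disc,
#' `2 * radius / pi`, which is the quantity entering the asymptotic flux and
#' splitting-probability formulas.
#'
#' @param center numeric of length 2 or 3 (third coordinate must be 0);
#'   in-plane position of the pore centre.
#' @param radius positive pore radius.
#' @param capacitance electrostatic capacitance of the pore; defaults to
#'   `2 * radius / pi` (flat disc).
#' @return an object of class `circular_pore`.
#' @examples
#' circular_pore(c(0, 0), 1)
#' @export
circular_pore <- function(center, radius, capacitance = 2 * radius / pi) {
  if (length(center) == 2L) center <- c(center, 0)
  stopifnot(length(center) == 3L, is.finite(radius))
  if (radius <= 0) stop("pore radius must be positive")
  if (abs(center[3L]) > 1e-12 * max(1, radius)) {
    stop("pore centre must lie on the plane z = 0")
  }
  structure(list(center = as.numeric(center[1:2]), radius = as.numeric(radius),
                 capacitance = as.numeric(capacitance)),
            class = "circular_pore")
}

#' Set of circular pores with its reinsertion disc
#'
#' Bundles non-overlapping circular pores with the enclosing disc `Da` used
#' to gate the escape/reinsertion propagator.  The disc is the smallest disc
#' containing every pore, scaled by `reinsertion_factor` (default 3, matching
#' the launch/landing ratio of the reinsertion propagator).
#'
#' @param pores list of [circular_pore()] objects (a single pore may be given
#'   bare).  An empty list is allowed only together with an explicit
#'   `dummy_disc_radius` (a fully reflecting plane: every particle escapes).
#' @param reinsertion_factor scale applied to the smallest enclosing disc;
#'   must equal the reinsertion ratio used in simulation.
#' @param dummy_disc_radius reinsertion disc radius to use when `pores` is
#'   empty.
#' @return an object of class `planar_pore_set` with elements `pores`,
#'   `centers` (N x 2), `radii`, `capacitances`, `enclosing_disc_center`,
#'   `enclosing_disc_radius` and `reinsertion_factor`.
#' @export
planar_pore_set <- function(pores, reinsertion_factor = 3,
                            dummy_disc_radius = NULL) {
  if (inherits(pores, "circular_pore")) pores <- list(pores)
  if (length(pores) == 0L) {
    if (is.null(dummy_disc_radius)) {
      stop("pore set must contain at least one pore ",
           "(or give dummy_disc_radius for a fully reflecting plane)")
    }
    return(structure(list(pores = list(),
                          centers = matrix(0, 0, 2), radii = numeric(0),
                          capacitances = numeric(0),
                          enclosing_disc_center = c(0, 0),
                          enclosing_disc_radius = dummy_disc_radius,
                          reinsertion_factor = reinsertion_factor),
                     class = "planar_pore_set"))
  }
  stopifnot(all(vapply(pores, inherits, logical(1), "circular_pore")),
            reinsertion_factor >= 1)
  centers <- do.call(rbind, lapply(pores, `[[`, "center"))
  radii <- vapply(pores, `[[`, numeric(1), "radius")
  caps <- vapply(pores, `[[`, numeric(1), "capacitance")
  n <- length(radii)
  if (n > 1L) {
    dd <- as.matrix(stats::dist(centers))
    sep <- dd - outer(radii, radii, `+`)
    diag(sep) <- Inf
    if (any(sep < 0)) stop("pores overlap: pairwise separation must exceed the radius sum")
  }
  disc <- min_enclosing_disc(centers, radii)
  structure(list(pores = pores, centers = centers, radii = radii,
                 capacitances = caps,
                 enclosing_disc_center = disc$center,
                 enclosing_disc_radius = reinsertion_factor * disc$radius,
                 reinsertion_factor = reinsertion_factor),
            class = "planar_pore_set")
}

#' Signed distance from a point on the plane to the absorbing set
#'
#' Returns `min_k (|p - x_k| - r_k)`; non-positive values mean the point is
#' inside or on a pore.  The index of the nearest pore is attached as
#' attribute `"pore"`.
#'
#' @param point numeric of length 2 or 3 (third coordinate 0): query point on
#'   the plane.
#' @param pores a [planar_pore_set()].
#' @return signed distance (length), with attribute `pore`.
#' @export
distance_to_absorbing_set <- function(point, pores) {
  stopifnot(inherits(pores, "planar_pore_set"))
  if (length(pores$radii) == 0L) stop("pore set has no absorbers")
  if (length(point) == 3L) {
    if (abs(point[3L]) > 1e-9) stop("query point must lie on the plane z = 0")
    point <- point[1:2]
  }
  d <- sqrt((pores$centers[, 1] - point[1])^2 +
            (pores$centers[, 2] - point[2])^2) - pores$radii
  k <- which.min(d)
  structure(d[k], pore = k)
}

#' Enclosing disc of a pore set
#'
#' Smallest disc on the plane containing every pore entirely, with its radius
#' scaled by `factor`.  Used to build the reinsertion disc `Da` (factor 3).
#'
#' @param pores a [planar_pore_set()].
#' @param factor radius scale, at least 1.
#' @return list with `center` (length 2) and `radius`.
#' @export
enclosing_disc <- function(pores, factor = 3) {
  stopifnot(inherits(pores, "planar_pore_set"), factor >= 1)
  disc <- min_enclosing_disc(pores$centers, pores$radii)
  list(center = disc$center, radius = factor * disc$radius)
}

# Exact smallest disc containing a set of discs.  The minimiser is supported
# by at most three discs, so all singletons, pairs and (Apollonius) triples
# are enumerated; pore counts are small so the O(N^3) scan is immediate.
min_enclosing_disc <- function(centers, radii) {
  n <- length(radii)
  tol <- 1e-10 * max(1, max(radii), max(abs(centers)))
  contains_all <- function(c0, R) {
    all(sqrt((centers[, 1] - c0[1])^2 + (centers[, 2] - c0[2])^2) + radii <= R + tol)
  }
  best <- NULL
  consider <- function(c0, R) {
    if (is.finite(R) && contains_all(c0, R) &&
        (is.null(best) || R < best$radius)) {
      best <<- list(center = c0, radius = R)
    }
  }
  for (i in seq_len(n)) consider(centers[i, ], radii[i])
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- sqrt(sum((centers[j, ] - centers[i, ])^2))
        R <- (d + radii[i] + radii[j]) / 2
        c0 <- if (d > 0) {
          centers[i, ] + (R - radii[i]) * (centers[j, ] - centers[i, ]) / d
        } else centers[i, ]
        consider(c0, R)
      }
    }
  }
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      for (j in (i + 1L):(n - 1L)) {
        for (k in (j + 1L):n) {
          cand <- apollonius_disc(centers[c(i, j, k), ], radii[c(i, j, k)])
          for (cc in cand) consider(cc$center, cc$radius)
        }
      }
    }
  }
  if (is.null(best)) stop("failed to find enclosing disc")  # unreachable
  best
}

# Disc internally tangent to three discs: |c - x_i| = R - r_i.  Subtracting
# pairs gives c affine in R; substitution leaves a quadratic in R.
apollonius_disc <- function(x, r) {
  A <- 2 * rbind(x[2, ] - x[1, ], x[3, ] - x[1, ])
  if (abs(det(A)) < 1e-14) return(list())
  b0 <- c(sum(x[2, ]^2) - sum(x[1, ]^2) - (r[2]^2 - r[1]^2),
          sum(x[3, ]^2) - sum(x[1, ]^2) - (r[3]^2 - r[1]^2))
  b1 <- c(2 * (r[2] - r[1]), 2 * (r[3] - r[1]))
  P <- solve(A, b0)   # c = P + R * Q
  Q <- solve(A, b1)
  u <- P - x[1, ]
  a2 <- sum(Q^2) - 1
  a1 <- 2 * sum(u * Q) + 2 * r[1]
  a0 <- sum(u^2) - r[1]^2
  roots <- if (abs(a2) < 1e-14) {
    if (abs(a1) < 1e-14) numeric(0) else -a0 / a1
  } else {
    disc <- a1^2 - 4 * a2 * a0
    if (disc < 0) numeric(0) else (-a1 + c(-1, 1) * sqrt(disc)) / (2 * a2)
  }
  out <- list()
  for (R in roots) {
    if (is.finite(R) && R >= max(r) - 1e-12) {
      out[[length(out) + 1L]] <- list(center = P + R * Q, radius = R)
    }
  }
  out
}
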