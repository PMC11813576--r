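#' Simulation run configuration
#'
#' Collects the physical and numerical parameters of a batch of kinetic
#' Monte Carlo trajectories.
#'
#' @param M number of particles (>= 1).
#' @param release either a numeric length-3 release point, or the result of
#'   [release_spec()] describing a uniform release surface.
#' @param D diffusivity (length^2 / time).
#' @param seed RNG seed; `NULL` leaves the current RNG state untouched.
#' @param reinsertion_ratio launch/landing ratio of the escape/reinsertion
#'   propagator (default 3, so 2/3 of the particles reaching that stage
#'   escape).
#' @param safety_cap maximum propagator steps per particle; a trajectory
#'   exceeding it is recorded as `lost` (the stage machines terminate almost
#'   surely, so this only converts a hypothetical hang into a logged
#'   anomaly).
#' @return object of class `run_config`.
#' @export
run_config <- function(M, release, D = 1, seed = NULL,
                       reinsertion_ratio = 3, safety_cap = 1e6) {
  stopifnot(M >= 1, D > 0, reinsertion_ratio > 1)
  if (is.numeric(release) && length(release) == 3L) {
    release <- list(type = "point", point = release)
  }
  stopifnot(is.list(release), release$type %in% c("point", "hemisphere", "sphere"))
  structure(list(M = as.integer(M), release = release, D = D, seed = seed,
                 reinsertion_ratio = reinsertion_ratio,
                 safety_cap = safety_cap),
            class = "run_config")
}

#' Release surface specification
#'
#' @param surface `"sphere"` or `"hemisphere"` (upper half, z >= 0).
#' @param radius surface radius; must enclose the target geometry.
#' @return list consumed by [run_config()].
#' @export
release_spec <- function(surface = c("sphere", "hemisphere"), radius) {
  surface <- match.arg(surface)
  stopifnot(radius > 0)
  list(type = surface, radius = radius)
}

#' Area-uniform points on a sphere or upper hemisphere
#'
#' Uses the cylindrical-projection property: the height of a uniform point
#' on a sphere is uniform in `(-r, r)`.
#'
#' @param surface `"sphere"` or `"hemisphere"`.
#' @param radius surface radius.
#' @param n number of points.
#' @param seed optional RNG seed.
#' @return n x 3 matrix.
#' @export
release_uniform <- function(surface = c("sphere", "hemisphere"), radius, n,
                            seed = NULL) {
  surface <- match.arg(surface)
  if (!is.null(seed)) set.seed(seed)
  z <- if (surface == "sphere") runif(n, -1, 1) else runif(n, 0, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(s * cos(phi), s * sin(phi), z)
}

release_points <- function(cfg) {
  r <- cfg$release
  switch(r$type,
         point = matrix(r$point, cfg$M, 3, byrow = TRUE),
         sphere = release_uniform("sphere", r$radius, cfg$M),
         hemisphere = release_uniform("hemisphere", r$radius, cfg$M))
}

default_tables <- function(ratio) {
  list(hemi = hemisphere_exit_table(),
       reins = build_reinsertion_table(R = ratio))
}

records_from_matrix <- function(mat, absorber_names = NULL) {
  outcome <- factor(c("captured", "escaped", "lost")[mat[, 1]],
                    levels = c("captured", "escaped", "lost"))
  absorber <- ifelse(mat[, 1] == 1, mat[, 3], NA_integer_)
  rec <- data.frame(particle_id = seq_len(nrow(mat)),
                    outcome = outcome,
                    time = ifelse(mat[, 1] == 1, mat[, 2], NA_real_),
                    absorber_id = as.integer(absorber),
                    x = mat[, 4], y = mat[, 5], z = mat[, 6],
                    n_steps = as.integer(mat[, 7]))
  if (!is.null(absorber_names)) {
    attr(rec, "absorber_names") <- absorber_names
  }
  class(rec) <- c("capture_records", "data.frame")
  rec
}

#' Simulate capture by pores on the reflecting plane
#'
#' Runs the half-space stage machine for every particle: Projector I drops
#' the particle to the plane; an impact inside a pore is a capture; an impact
#' inside the reinsertion disc `Da` (but outside every pore) re-enters the
#' bulk through a hemisphere of radius equal to the distance to the absorbing
#' set; an impact outside `Da` either escapes to infinity or is reinserted
#' onto a hemisphere enclosing the absorbers (image-reflected into the upper
#' half-space).
#'
#' @param pores a [planar_pore_set()]; its `reinsertion_factor` must match
#'   the config's `reinsertion_ratio`.
#' @param cfg a [run_config()]; release points must have nonnegative height.
#' @return a `capture_records` data frame with one row per particle:
#'   `particle_id`, `outcome` (captured/escaped/lost), `time`, `absorber_id`
#'   (pore index), impact location `x`, `y`, `z`, and `n_steps`.
#' @export
simulate_halfspace <- function(pores, cfg) {
  stopifnot(inherits(pores, "planar_pore_set"), inherits(cfg, "run_config"))
  if (abs(pores$reinsertion_factor - cfg$reinsertion_ratio) > 1e-12) {
    stop("pore set reinsertion_factor must equal cfg$reinsertion_ratio")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tab <- default_tables(cfg$reinsertion_ratio)
  rel <- release_points(cfg)
  if (any(rel[, 3] < 0)) stop("release points must have nonnegative height")
  mat <- cpp_simulate_halfspace(rel,
                                cbind(pores$centers, pores$radii),
                                pores$enclosing_disc_center,
                                pores$enclosing_disc_radius,
                                cfg$reinsertion_ratio, cfg$D,
                                tab$hemi$tau, tab$hemi$cdf,
                                tab$reins$theta_star, cfg$safety_cap)
  records_from_matrix(mat)
}

#' Simulate capture by a convex polyhedron in the exterior domain
#'
#' Runs the polyhedron stage machine: outside the ball `Ba` (radius
#' `ratio * Ra` about the centre of the ball bounding the absorbing faces)
#' the particle escapes or is reinserted; otherwise the face plane with the
#' largest positive signed distance is targeted, the particle is dropped onto
#' it by Projector I, and on a hit it is absorbed (absorbing face) or bounced
#' through the largest in-face hemisphere and dropped onto the same face
#' plane again (reflecting face).
#'
#' @param poly a [convex_polyhedron()].
#' @param cfg a [run_config()]; release points must lie strictly outside the
#'   body.
#' @return a `capture_records` data frame (see [simulate_halfspace()]);
#'   `absorber_id` holds the face's absorber id and, when the polyhedron has
#'   `absorber_names`, the attribute of the same name maps ids to labels.
#' @export
simulate_polyhedron <- function(poly, cfg) {
  stopifnot(inherits(poly, "convex_polyhedron"), inherits(cfg, "run_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tab <- default_tables(cfg$reinsertion_ratio)
  rel <- release_points(cfg)
  if (cfg$release$type == "point") {
    sd <- drop(poly$normals %*% rel[1L, ]) - poly$offsets
    if (max(sd) <= 0) stop("release point must lie strictly outside the body")
  } else {
    if (cfg$release$radius <= sqrt(max(rowSums(poly$vertices^2)))) {
      stop("release surface must enclose the body")
    }
  }
  flat <- flatten_poly(poly)
  mat <- cpp_simulate_polyhedron(rel, poly$vertices,
                                 flat$face_idx, flat$face_off,
                                 poly$normals, poly$offsets,
                                 as.integer(poly$absorber),
                                 flat$adj_idx, flat$adj_off,
                                 poly$enclosing_ball_center,
                                 poly$gating_ball_radius,
                                 cfg$reinsertion_ratio, cfg$D,
                                 tab$hemi$tau, tab$hemi$cdf,
                                 tab$reins$theta_star, cfg$safety_cap)
  records_from_matrix(mat, absorber_names = poly$absorber_names)
}

# 0-based flattened face rings and adjacency lists for the C++ core
flatten_poly <- function(poly) {
  lens <- lengths(poly$faces)
  list(face_idx = as.integer(unlist(poly$faces) - 1L),
       face_off = as.integer(cumsum(c(0L, lens))),
       adj_idx = as.integer(unlist(poly$adjacency) - 1L),
       adj_off = as.integer(cumsum(c(0L, lengths(poly$adjacency)))))
}
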