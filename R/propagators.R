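#' @useDynLib kmcapture, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif qnorm approx dist setNames
NULL

# package-session cache for sampler tables
.kmc_env <- new.env(parent = emptyenv())

#' Inverse complementary error function
#'
#' Solves `erfc(x) = v` for `x`, the workhorse of the inverse-CDF hitting
#' time samplers.
#'
#' @param v value in (0, 2).
#' @return numeric.
#' @export
erfcinv <- function(v) qnorm(v / 2, lower.tail = FALSE) / sqrt(2)

erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# scaled complementary error function erfc(x) exp(x^2) for x >= 0,
# asymptotic series beyond the range where the direct product is safe
erfcx <- function(x) {
  out <- numeric(length(x))
  small <- x < 5
  out[small] <- erfc(x[small]) * exp(x[small]^2)
  if (any(!small)) {
    z <- x[!small]
    s <- 1
    term <- rep(1, length(z))
    for (k in 1:9) {
      term <- term * -(2 * k - 1) / (2 * z^2)
      s <- s + term
    }
    out[!small] <- s / (z * sqrt(pi))
  }
  out
}

#' First-passage impact on the bounding plane (Projector I)
#'
#' Samples the first impact of a Brownian particle released at height `z0`
#' above a fully absorbing plane: the hitting time has CDF
#' `erfc(z0 / (2 sqrt(D t)))`, inverted as
#' `t* = z0^2 / (4 D erfcinv(nu)^2)`, and the lateral displacements at the
#' impact time are independent N(0, 2 D t*) draws.
#'
#' @param z0 release height (> 0).
#' @param D diffusivity.
#' @param draws optional numeric length-3 vector in (0,1)^3 (the inverse-CDF
#'   uniform and two probability draws mapped through `qnorm`); when `NULL`,
#'   fresh random numbers are used.
#' @return list with `t`, `dx`, `dy`.
#' @export
sample_plane_impact <- function(z0, D, draws = NULL) {
  stopifnot(z0 > 0, D > 0)
  if (is.null(draws)) {
    nu <- runif_open(1)
    t_star <- z0^2 / (4 * D * erfcinv(nu)^2)
    s <- sqrt(2 * D * t_star)
    list(t = t_star, dx = rnorm(1, 0, s), dy = rnorm(1, 0, s))
  } else {
    stopifnot(length(draws) == 3, all(draws > 0), all(draws < 1))
    t_star <- z0^2 / (4 * D * erfcinv(draws[1])^2)
    s <- sqrt(2 * D * t_star)
    list(t = t_star, dx = s * qnorm(draws[2]), dy = s * qnorm(draws[3]))
  }
}

runif_open <- function(n) {
  u <- runif(n)
  while (any(bad <- u <= 0 | u >= 1)) u[bad] <- runif(sum(bad))
  u
}

#' Hemisphere exit-time CDF (Projector II)
#'
#' CDF of the dimensionless exit time `tau = pi^2 D t / R^2` for a particle
#' starting at the centre of the base of a hemisphere of radius `R` with
#' reflecting base and absorbing shell.  Two complementary series are used:
#' a theta-function form that converges rapidly for `tau < 1` and the
#' alternating exponential series for `tau >= 1`; both are truncated when the
#' next term falls below 1e-16.
#'
#' @param tau nonnegative dimensionless time(s).
#' @return probability vector.
#' @export
hemisphere_exit_cdf <- function(tau) {
  stopifnot(all(tau >= 0))
  out <- numeric(length(tau))
  small <- tau < 1 & tau > 0
  if (any(small)) {
    tt <- tau[small]
    s <- 0
    for (n in 0:60) {
      term <- exp(-pi^2 * (n + 0.5)^2 / tt)
      s <- s + term
      if (all(term < 1e-16)) break
    }
    out[small] <- 2 * sqrt(pi / tt) * s
  }
  large <- tau >= 1
  if (any(large)) {
    tt <- tau[large]
    s <- 0
    for (n in 1:60) {
      term <- (-1)^n * exp(-n^2 * tt)
      s <- s + term
      if (all(abs(term) < 1e-16)) break
    }
    out[large] <- 1 + 2 * s
  }
  pmin(1, pmax(0, out))
}

#' Precompute the hemisphere exit-time table
#'
#' Log-spaced grid of `tau` with the exit CDF, used for fast inverse
#' interpolation in the samplers (linear interpolation; a logarithmic tail
#' asymptotic `tau ~ log(2 / (1 - xi))` covers `xi > 1 - 1e-3`).
#'
#' @param n grid size.
#' @param tau_min,tau_max grid extent.
#' @return list with `tau` and `cdf`, both increasing.
#' @export
hemisphere_exit_table <- function(n = 4096, tau_min = 1e-6, tau_max = 30) {
  key <- paste0("hemi_", n, "_", tau_min, "_", tau_max)
  if (!is.null(.kmc_env[[key]])) return(.kmc_env[[key]])
  tau <- exp(seq(log(tau_min), log(tau_max), length.out = n))
  tab <- list(tau = tau, cdf = hemisphere_exit_cdf(tau))
  .kmc_env[[key]] <- tab
  tab
}

#' Sample an exit time and point from a hemisphere (Projector II)
#'
#' Draws the exit time by inverse interpolation of the tabulated CDF and an
#' exit point isotropically on the upper hemisphere (the polar coordinate of
#' a uniform point on the sphere is uniform in its cosine).
#'
#' @param R hemisphere radius.
#' @param D diffusivity.
#' @param table result of [hemisphere_exit_table()].
#' @return list with `t` and `point` (length 3, pole along +z, norm `R`,
#'   nonnegative third component).
#' @export
sample_hemisphere_exit <- function(R, D, table = hemisphere_exit_table()) {
  stopifnot(R > 0, D > 0)
  xi <- runif_open(1)
  tau <- if (xi > 1 - 1e-3) log(2 / (1 - xi)) else {
    approx(table$cdf, table$tau, xout = xi, rule = 2, ties = "ordered")$y
  }
  eta <- 2 * pi * runif(1)
  zeta <- runif_open(1)
  s <- sqrt(1 - zeta^2)
  list(t = R^2 * tau / (D * pi^2),
       point = R * c(s * cos(eta), s * sin(eta), zeta))
}

#' Arrival-time CDF on a sphere from an exterior point (Projector III)
#'
#' For a particle at distance `R > 1` (in units of the landing sphere's
#' radius) the probability of arrival on the sphere by time `t` is
#' `(1/R) erfc((R - 1) / (2 sqrt(D t)))`; the total mass `1/R` is the capture
#' probability, the remaining `1 - 1/R` escapes to infinity.
#'
#' @param t time(s), nonnegative.
#' @param R launch/landing radius ratio, > 1.
#' @param D diffusivity.
#' @return probability vector.
#' @export
sphere_arrival_cdf <- function(t, R, D = 1) {
  stopifnot(R > 1, all(t >= 0), D > 0)
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- erfc((R - 1) / (2 * sqrt(D * t[pos]))) / R
  out
}

#' Escape test and arrival time for the reinsertion propagator
#'
#' Given a uniform draw `mu`, the particle escapes to infinity when
#' `mu >= 1/R`; otherwise the arrival time on the unit landing sphere is the
#' inverse of the arrival CDF, `t* = (R-1)^2 / (4 D erfcinv(R mu)^2)`.
#'
#' @param mu uniform draw(s) in (0, 1).
#' @param R launch/landing radius ratio, > 1.
#' @param D diffusivity.
#' @return list with logical `escaped` and `t` (NA where escaped).
#' @export
sample_reinsertion_time <- function(mu, R = 3, D = 1) {
  stopifnot(R > 1, all(mu > 0), all(mu < 1))
  escaped <- mu >= 1 / R
  t <- rep(NA_real_, length(mu))
  t[!escaped] <- (R - 1)^2 / (4 * D * erfcinv(R * mu[!escaped])^2)
  list(escaped = escaped, t = t)
}

# ---- polar-angle distribution of the reinsertion landing point ------------

# Laplace-domain Legendre-mode amplitudes of the flux onto the unit sphere
# from a source at distance R:
#   chi_hat_n(s) = (1/R) exp(-alpha (R-1)) * B_n(alpha R) / B_n(alpha),
# alpha = sqrt(s/D), where B_n(z) = k_n(z)/k_0(z) satisfies the modified
# spherical Bessel recurrence B_{n+1} = B_{n-1} + (2n+1)/z B_n, B_0 = 1,
# B_1 = 1 + 1/z.  Returns a matrix: rows = s values, cols = n = 0..n_max.
chi_hat_modes <- function(s, R, D, n_max) {
  alpha <- sqrt(s / D)
  ns <- length(s)
  out <- matrix(0i, ns, n_max + 1)
  base <- exp(-alpha * (R - 1)) / R
  u_prev <- rep(1 + 0i, ns); v_prev <- rep(1 + 0i, ns)   # B_0
  u_cur <- 1 + 1 / (alpha * R); v_cur <- 1 + 1 / alpha   # B_1
  out[, 1] <- base
  if (n_max >= 1) out[, 2] <- base * u_cur / v_cur
  if (n_max >= 2) {
    for (n in 1:(n_max - 1)) {
      u_nxt <- u_prev + (2 * n + 1) / (alpha * R) * u_cur
      v_nxt <- v_prev + (2 * n + 1) / alpha * v_cur
      big <- Mod(v_nxt) > 1e120
      if (any(big)) {  # joint rescale: only the ratio matters
        sc <- 1e-120
        u_nxt[big] <- u_nxt[big] * sc; v_nxt[big] <- v_nxt[big] * sc
        u_cur[big] <- u_cur[big] * sc; v_cur[big] <- v_cur[big] * sc
      }
      out[, n + 2] <- base * u_nxt / v_nxt
      u_prev <- u_cur; v_prev <- v_cur
      u_cur <- u_nxt; v_cur <- v_nxt
    }
  }
  out
}

# fixed-Talbot inverse Laplace transform of all modes at one time t;
# returns chi_n(t) for n = 0..n_max
chi_modes <- function(t, R, D = 1, n_max, M = 48) {
  k <- 1:(M - 1)
  theta <- k * pi / M
  r <- 2 * M / (5 * t)
  s <- c(r, r * theta * (1 / tan(theta) + 1i))
  sigma <- c(0, theta + (theta / tan(theta) - 1) / tan(theta))
  Fs <- chi_hat_modes(s, R, D, n_max)
  w <- exp(t * s) * (1 + 1i * sigma)
  w[1] <- 0.5 * w[1]
  Re(colSums(w * Fs)) * r / M
}

#' Flux mode amplitude of the exterior-sphere arrival problem
#'
#' The Legendre-mode amplitudes `chi_n(t)` of the first-arrival flux density
#' on the unit sphere for a particle released at distance `R` on the polar
#' axis: `chi_0(t)` is the total flux density `J(t)` and the ratios
#' `chi_n/chi_0` are the Legendre coefficients of the arrival-angle
#' distribution.  Computed by fixed-Talbot numerical inversion of the
#' modal Laplace-domain solution.
#'
#' @param t time (> 0), scalar.
#' @param n mode indices (vector allowed).
#' @param R launch/landing radius ratio, > 1.
#' @param D diffusivity.
#' @return numeric vector of `chi_n(t)`.
#' @export
chi_n <- function(t, n, R = 3, D = 1) {
  stopifnot(t > 0, all(n >= 0))
  chi_modes(t, R, D, max(n))[n + 1]
}

#' Conditional polar-angle CDF of the reinsertion landing point
#'
#' Distribution of the polar angle (declination from the launch direction) of
#' the landing point on the unit sphere, conditioned on the arrival time `t`:
#' \deqn{P_\Theta(\theta; t) = \tfrac12(1 - \cos\theta) + \tfrac12
#'   \sum_{n\ge1} \frac{\chi_n(t)}{J(t)}
#'   [P_{n-1}(\cos\theta) - P_{n+1}(\cos\theta)],}
#' which tends to the uniform-sphere law \eqn{(1-\cos\theta)/2} as
#' \eqn{t \to \infty}.  The Legendre series is truncated adaptively; an error
#' is raised if it has not converged by `n_max` modes (very small `t`).
#'
#' @param theta polar angle(s) in `[0, pi]`.
#' @param t arrival time (> 0), scalar.
#' @param R launch/landing radius ratio, > 1.
#' @param D diffusivity.
#' @param n_max mode cap for the adaptive truncation.
#' @return CDF values in `[0, 1]`, nondecreasing in `theta`.
#' @export
polar_angle_cdf <- function(theta, t, R = 3, D = 1, n_max = 400) {
  stopifnot(all(theta >= -1e-12), all(theta <= pi + 1e-12), t > 0, R > 1)
  coef <- polar_angle_coefficients(t, R, D, n_max)
  polar_cdf_from_coefficients(theta, coef)
}

# chi_n(t)/J(t) for n >= 1, truncated where the coefficients become
# negligible; errors out if the series is still live at n_max
polar_angle_coefficients <- function(t, R, D, n_max = 400) {
  chi <- chi_modes(t, R, D, n_max)
  J <- chi[1]
  if (!is.finite(J) || J <= 0) {
    stop("flux density vanished at t = ", t,
         ": time too small for a reliable mode series")
  }
  coef <- chi[-1] / J
  # the absolute quadrature noise of the inversion tracks the transform
  # scale, not J(t); when J is algebraically small (large t) coefficients
  # below the noise floor are zeroed so the law degrades to the exact
  # uniform limit instead of accumulating noise
  floor_c <- max(1e-10, 1e-13 / J)
  coef[abs(coef) < floor_c] <- 0
  small <- abs(coef) < floor_c
  cut <- which(small & c(small[-1], TRUE) & c(small[-(1:2)], TRUE, TRUE))
  if (length(cut) == 0) {
    stop("Legendre mode series not converged by n = ", n_max,
         " (t = ", t, " too small); smallest reliable t is larger")
  }
  coef[seq_len(cut[1])]
}

polar_cdf_from_coefficients <- function(theta, coef) {
  x <- cos(theta)
  out <- 0.5 * (1 - x)
  p_prev <- rep(1, length(x))  # P_0
  p_cur <- x                    # P_1
  for (n in seq_along(coef)) {
    p_nxt <- ((2 * n + 1) * x * p_cur - n * p_prev) / (n + 1)
    out <- out + 0.5 * coef[n] * (p_prev - p_nxt)
    p_prev <- p_cur
    p_cur <- p_nxt
  }
  pmin(1, pmax(0, out))
}

#' Build the reinsertion time-angle lookup table
#'
#' Tabulates the reinsertion propagator on an equally spaced grid of the
#' uniform draws: `mu` on (0, 1/R) determines the arrival time
#' `t*(mu)` (closed form, unit landing sphere, unit diffusivity) and `nu` on
#' (0, 1) determines the polar angle `theta*(mu, nu)` by inverting the
#' conditional CDF [polar_angle_cdf()] at `t*(mu)`.  Grid midpoints are used
#' so no entry sits on a singular boundary.  The table is cached in the
#' session and, when possible, on disk keyed by `(R, n_mu, n_nu)`.
#'
#' @param R launch/landing radius ratio (default 3).
#' @param n_mu,n_nu grid sizes (default 400 x 400).
#' @param cache try to reuse/persist a disk cache under
#'   `tools::R_user_dir("kmcapture", "cache")`.
#' @return object of class `reinsertion_table`: list with `ratio`, `mu`,
#'   `nu`, `t_star` (length `n_mu`) and `theta_star` (`n_mu` x `n_nu`).
#' @export
build_reinsertion_table <- function(R = 3, n_mu = 400, n_nu = 400,
                                    cache = TRUE) {
  stopifnot(R > 1, n_mu >= 2, n_nu >= 2)
  key <- paste0("reins_", format(R, digits = 12), "_", n_mu, "_", n_nu)
  if (!is.null(.kmc_env[[key]])) return(.kmc_env[[key]])
  if (cache) {
    path <- try(file.path(tools::R_user_dir("kmcapture", "cache"),
                          paste0(key, "_v1.rds")), silent = TRUE)
    if (!inherits(path, "try-error") && file.exists(path)) {
      tab <- try(readRDS(path), silent = TRUE)
      if (!inherits(tab, "try-error")) {
        .kmc_env[[key]] <- tab
        return(tab)
      }
    }
  }
  mu <- (seq_len(n_mu) - 0.5) / (n_mu * R)
  nu <- (seq_len(n_nu) - 0.5) / n_nu
  t_star <- (R - 1)^2 / (4 * erfcinv(R * mu)^2)
  theta_grid <- seq(0, pi, length.out = 4001)
  theta_star <- matrix(0, n_mu, n_nu)
  for (i in seq_len(n_mu)) {
    coef <- polar_angle_coefficients(t_star[i], R, D = 1)
    cdf <- cummax(polar_cdf_from_coefficients(theta_grid, coef))
    theta_star[i, ] <- approx(cdf, theta_grid, xout = nu, rule = 2,
                              ties = "ordered")$y
  }
  tab <- structure(list(ratio = R, mu = mu, nu = nu, t_star = t_star,
                        theta_star = theta_star),
                   class = "reinsertion_table")
  .kmc_env[[key]] <- tab
  if (cache && !inherits(path, "try-error")) {
    ok <- try({
      dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
      saveRDS(tab, path)
    }, silent = TRUE)
  }
  tab
}

#' One escape-or-reinsertion step (Projector III)
#'
#' Applies the reinsertion propagator to a particle outside the gating sphere
#' of radius `ratio * Ra_effective` about `center`: with probability
#' `1 - 1/ratio` the particle escapes to infinity; otherwise it lands on the
#' sphere of radius `|x - center| / ratio` at the tabulated polar angle from
#' the launch direction (azimuth uniform) and its clock advances by the
#' tabulated unit-sphere time rescaled by (landing radius)^2 / D.  With
#' `halfspace = TRUE` a landing point below the plane z = 0 is reflected to
#' its image.
#'
#' @param state list with `position` (length 3), `time`, `status`.
#' @param table a [build_reinsertion_table()] result.
#' @param center centre of the gating sphere (length 3).
#' @param Ra_effective radius of the ball/disc bounding the absorbing set.
#' @param D diffusivity.
#' @param halfspace reflect landings below z = 0 to the upper half-space.
#' @return updated state: `status` becomes `"escaped"` or stays `"bulk"` with
#'   a new `position` and incremented `time`.
#' @export
apply_reinsertion <- function(state, table, center, Ra_effective, D = 1,
                              halfspace = FALSE) {
  stopifnot(inherits(table, "reinsertion_table"))
  R <- table$ratio
  p <- state$position - center
  r0 <- sqrt(sum(p^2))
  if (r0 <= R * Ra_effective) {
    stop("particle is inside the reinsertion gating sphere; ",
         "reinsertion applies only beyond ratio * Ra")
  }
  mu <- runif_open(1)
  if (mu >= 1 / R) {
    state$status <- "escaped"
    return(state)
  }
  t_unit <- (R - 1)^2 / (4 * erfcinv(R * mu)^2)
  i <- min(length(table$mu), max(1L, floor(mu * R * length(table$mu)) + 1L))
  nu <- runif(1)
  j <- min(length(table$nu), max(1L, floor(nu * length(table$nu)) + 1L))
  theta <- table$theta_star[i, j]
  phi <- 2 * pi * runif(1)
  u <- p / r0
  a <- if (abs(u[1]) < 0.5) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(u[2] * a[3] - u[3] * a[2], u[3] * a[1] - u[1] * a[3],
          u[1] * a[2] - u[2] * a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  Rl <- r0 / R
  pos <- center + Rl * (cos(theta) * u +
                        sin(theta) * (cos(phi) * e1 + sin(phi) * e2))
  if (halfspace && pos[3] < 0) pos[3] <- -pos[3]
  state$position <- pos
  state$time <- state$time + t_unit * Rl^2 / D
  state$status <- "bulk"
  state
}
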