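#' Two-term asymptotic flux densities to well-separated planar pores
#'
#' For N small, well-separated pores on the reflecting plane and a release
#' point `x0`, the flux density into pore k is, with \eqn{C_k} the pore
#' capacitance, \eqn{R_k = |x_0 - x_k|} and \eqn{d_{jk} = |x_j - x_k|},
#' \deqn{J_k(t) = \frac{C_k}{\sqrt{4\pi D t^3}} e^{-R_k^2/4Dt}
#'   \Big[1 - C_k\big(\tfrac{1}{R_k} - \tfrac{R_k}{2Dt}\big)
#'   - \sum_{j\ne k} C_j e^{[R_k^2 - (R_j+d_{jk})^2]/4Dt}
#'     \big(\tfrac{1}{R_j} + \tfrac{1}{d_{jk}}\big)\Big].}
#' The self-correction integrates to zero, so \eqn{\int_0^\infty J_k =
#' C_k/R_k - \sum_{j\ne k} C_jC_k/(d_{jk}R_j)}, the two-term splitting
#' probability.  The cross-pore (shielding) term carries a minus sign, fixed
#' by that integral identity.
#'
#' @param t positive time(s).
#' @param x0 release point (length 3, nonnegative height).
#' @param pores a [planar_pore_set()].
#' @param D diffusivity.
#' @return matrix `length(t)` x N of flux densities.
#' @export
planar_multi_pore_flux <- function(t, x0, pores, D = 1) {
  stopifnot(inherits(pores, "planar_pore_set"), all(t > 0))
  ctr <- cbind(pores$centers, 0)
  caps <- pores$capacitances
  N <- nrow(ctr)
  Rk <- sqrt(colSums((t(ctr) - x0)^2))
  if (any(Rk == 0)) stop("release point coincides with a pore centre")
  d <- as.matrix(dist(ctr))
  if (N > 1 && any(d[upper.tri(d)] == 0)) stop("coincident pore centres")
  out <- matrix(0, length(t), N)
  for (k in seq_len(N)) {
    pref <- caps[k] / sqrt(4 * pi * D * t^3) * exp(-Rk[k]^2 / (4 * D * t))
    bracket <- 1 - caps[k] * (1 / Rk[k] - Rk[k] / (2 * D * t))
    for (j in seq_len(N)[-k]) {
      bracket <- bracket - caps[j] *
        exp((Rk[k]^2 - (Rk[j] + d[j, k])^2) / (4 * D * t)) *
        (1 / Rk[j] + 1 / d[j, k])
    }
    out[, k] <- pref * bracket
  }
  out
}

#' Single-pore arrival flux and CDF
#'
#' Asymptotic arrival-time density and CDF for one circular pore of unit
#' radius (capacitance `2/pi`) and a release point at distance `R` much
#' larger than the pore:
#' \deqn{J(t) = \frac{C}{\sqrt{4\pi D t^3}} e^{-R^2/4Dt}
#'              [1 - C(\tfrac1R - \tfrac{R}{2Dt})], \quad
#'   F(t) = \frac{C}{R}\,\mathrm{erfc}\Big(\frac{R}{2\sqrt{Dt}}\Big)
#'        + \frac{C^2}{R}\frac{e^{-R^2/4Dt}}{\sqrt{\pi D t}},}
#' with `C = 2/pi`; `F` is the exact time integral of `J` and
#' `F(Inf) = C/R` (capacitance mass).
#'
#' @param t nonnegative time(s).
#' @param R release distance.
#' @param D diffusivity.
#' @param capacitance pore capacitance (default `2/pi`, the unit disc).
#' @return list with vectors `J` and `F`.
#' @export
single_pore_flux_cdf <- function(t, R, D = 1, capacitance = 2 / pi) {
  stopifnot(R > 0, all(t >= 0))
  C <- capacitance
  J <- F <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  ex <- exp(-R^2 / (4 * D * tp))
  J[pos] <- C / sqrt(4 * pi * D * tp^3) * ex *
    (1 - C * (1 / R - R / (2 * D * tp)))
  F[pos] <- C / R * erfc(R / (2 * sqrt(D * tp))) +
    C^2 / R * ex / sqrt(pi * D * tp)
  list(J = J, F = F)
}

#' Capacitance of two coplanar unit discs (Strieder series)
#'
#' Large-separation series for the capacitance of two circular pores of unit
#' radius at centre distance `d`:
#' \deqn{C(d) = \frac{4}{\pi}\Big[1 - \frac{2}{\pi d} + \frac{4}{\pi^2 d^2}
#'  - \frac{2(12+\pi^2)}{3\pi^3 d^3} + \frac{16(3+\pi^2)}{3\pi^4 d^4}
#'  - \frac{4(120+70\pi^2+3\pi^4)}{15\pi^5 d^5}\Big] + O(d^{-6}).}
#' As `d` grows it increases to `4/pi`, twice the single-disc value.
#'
#' @param d centre separation, > 2 (discs must not touch).
#' @return capacitance.
#' @export
strieder_capacitance <- function(d) {
  if (any(d <= 2)) stop("series requires non-touching pores: d > 2")
  4 / pi * (1 - 2 / (pi * d) + 4 / (pi^2 * d^2)
            - 2 * (12 + pi^2) / (3 * pi^3 * d^3)
            + 16 * (3 + pi^2) / (3 * pi^4 * d^4)
            - 4 * (120 + 70 * pi^2 + 3 * pi^4) / (15 * pi^5 * d^5))
}

#' Two-term splitting probabilities for planar pores
#'
#' Probability that a particle released at `x0` is eventually captured by
#' pore k rather than any other pore or escaping:
#' \deqn{Q_k = \frac{C_k}{|x_0-x_k|} -
#'   \sum_{j\ne k}\frac{C_j C_k}{|x_j-x_k|\,|x_0-x_j|},}
#' with \eqn{C_k = 2 r_k/\pi} for circular pores.
#'
#' @param x0 release point (length 3).
#' @param pores a [planar_pore_set()].
#' @return numeric vector of per-pore probabilities.
#' @export
planar_splitting_probabilities <- function(x0, pores) {
  stopifnot(inherits(pores, "planar_pore_set"))
  ctr <- cbind(pores$centers, 0)
  caps <- pores$capacitances
  Rk <- sqrt(colSums((t(ctr) - x0)^2))
  if (any(Rk == 0)) stop("release point coincides with a pore centre")
  d <- as.matrix(dist(ctr))
  N <- nrow(ctr)
  Q <- caps / Rk
  for (k in seq_len(N)) {
    for (j in seq_len(N)[-k]) {
      Q[k] <- Q[k] - caps[j] * caps[k] / (d[j, k] * Rk[j])
    }
  }
  Q
}

#' Homogenized Robin constant for a patchy sphere
#'
#' Effective leakage constant replacing N circular pores of common radius `a`
#' (area fraction `sigma = N a^2 / 4`) on the unit sphere by the Robin
#' condition \eqn{D\,\partial_n p = \kappa p}:
#' \deqn{\kappa = \frac{4 D \sigma}{\pi a}\Big[1 - \frac{4}{\pi}\sqrt\sigma
#'   + \frac{a}{\pi}\log\big(4 e^{-1/2}\sqrt\sigma\big)\Big]^{-1}.}
#' Valid for dilute pores; an error is raised when the bracket is not
#' positive (parameters outside the asymptotic regime).
#'
#' @param sigma absorbing area fraction in (0, 1).
#' @param a pore radius.
#' @param D diffusivity.
#' @return kappa (length/time).
#' @export
homogenized_kappa <- function(sigma, a, D = 1) {
  stopifnot(sigma > 0, sigma < 1, a > 0, D > 0)
  bracket <- 1 - 4 / pi * sqrt(sigma) +
    a / pi * log(4 * exp(-0.5) * sqrt(sigma))
  if (bracket <= 0) {
    stop("homogenization bracket non-positive: sigma/a outside validity")
  }
  4 * D * sigma / (pi * a) / bracket
}

#' Arrival-time density and CDF for the homogenized (Robin) sphere
#'
#' Flux density and cumulative capture fraction for a particle released at
#' distance `R` from a unit sphere with Robin constant `kappa`:
#' \deqn{J(t) = \frac{\kappa}{R} e^{-(R-1)^2/4Dt}\Big[\frac{1}{\sqrt{\pi D t}}
#'   - \mathrm{erfc}(\beta)e^{\beta^2}(\kappa/D + 1)\Big],\qquad
#'   \beta = \frac{R-1}{2\sqrt{Dt}} + (\kappa/D+1)\sqrt{Dt},}
#' \deqn{F(t) = \frac{1}{(1 + D/\kappa)R}\Big[
#'   \mathrm{erfc}\Big(\frac{R-1}{2\sqrt{Dt}}\Big)
#'   - \mathrm{erfc}(\beta)e^{\beta^2} e^{-(R-1)^2/4Dt}\Big].}
#' `erfc(beta) exp(beta^2)` is evaluated through the scaled complementary
#' error function, so small `t` (large `beta`) does not overflow.  The total
#' capture probability is `1 / ((1 + D/kappa) R)`.
#'
#' @param t nonnegative time(s).
#' @param R release distance (> 1).
#' @param D diffusivity.
#' @param kappa Robin constant (> 0).
#' @return list with `J`, `F` and scalar `total`.
#' @export
homogenized_sphere_flux_cdf <- function(t, R, D = 1, kappa) {
  stopifnot(R > 1, all(t >= 0), kappa > 0, D > 0)
  J <- F <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  sq <- sqrt(D * tp)
  beta <- (R - 1) / (2 * sq) + (kappa / D + 1) * sq
  ex <- exp(-(R - 1)^2 / (4 * D * tp))
  ecx <- erfcx(beta)
  J[pos] <- kappa / R * ex * (1 / sqrt(pi * D * tp) - ecx * (kappa / D + 1))
  F[pos] <- 1 / ((1 + D / kappa) * R) *
    (erfc((R - 1) / (2 * sq)) - ecx * ex)
  list(J = J, F = F, total = 1 / ((1 + D / kappa) * R))
}

#' Arrival CDF for the capacitance-equivalent sphere
#'
#' Replaces a compact absorbing body of capacitance `C` by the sphere of
#' radius `C`: the cumulative capture fraction from release distance `R0` is
#' `F(t) = (C/R0) erfc((R0 - C) / (2 sqrt(D t)))`.
#'
#' @param t nonnegative time(s).
#' @param C body capacitance (equivalent sphere radius).
#' @param R0 release distance (> C).
#' @param D diffusivity.
#' @return CDF vector.
#' @export
equivalent_sphere_cdf <- function(t, C, R0, D = 1) {
  stopifnot(R0 > C, C > 0, all(t >= 0))
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- C / R0 * erfc((R0 - C) / (2 * sqrt(D * t[pos])))
  out
}

#' Green's function of the Laplacian exterior to the unit sphere
#'
#' For a surface source at the unit vector `xi` and a field point `x` with
#' `|x| > 1`:
#' \deqn{G(x;\xi) = \frac{1}{2\pi}\Big[\frac{1}{|x-\xi|} - \frac12
#'   \log\frac{1 - x\cdot\xi + |x-\xi|}{|x| - x\cdot\xi}\Big].}
#'
#' @param x field point (length 3, `|x| > 1`).
#' @param xi unit vector (source point on the sphere).
#' @return numeric value.
#' @export
exterior_sphere_green <- function(x, xi) {
  stopifnot(length(x) == 3, length(xi) == 3)
  if (abs(sqrt(sum(xi^2)) - 1) > 1e-9) stop("xi must be a unit vector")
  r <- sqrt(sum(x^2))
  if (r <= 1) stop("field point must lie outside the unit sphere")
  dxx <- sqrt(sum((x - xi)^2))
  if (dxx == 0) stop("coincident arguments")
  xdotxi <- sum(x * xi)
  1 / (2 * pi) * (1 / dxx - 0.5 * log((1 - xdotxi + dxx) / (r - xdotxi)))
}

#' Two-term splitting probabilities for circular patches on the sphere
#'
#' Probability that a particle from `x` (exterior to the unit sphere) is
#' first captured at the circular patch of radius `a` centred at the unit
#' vector `x_k`:
#' \deqn{Q_k(x) = 4aG(x,x_k) + \frac{4a^2}{\pi}\Big[
#'   \big(\tfrac32 - \log 2a\big)G(x,x_k)
#'   - 4\pi\sum_{j\ne k}G(x_j,x_k)\,G(x,x_j)\Big],}
#' with `G` the exterior-sphere Green's function.
#'
#' @param x release point (length 3, `|x| > 1`).
#' @param centres N x 3 matrix of unit vectors (patch centres).
#' @param a common patch radius (small; asymptotic validity).
#' @param order 1 for the leading term only, 2 (default) for the two-term
#'   expansion.
#' @return numeric vector of per-patch probabilities.
#' @export
sphere_splitting_probabilities <- function(x, centres, a, order = 2) {
  centres <- as.matrix(centres)
  N <- nrow(centres)
  Gx <- vapply(seq_len(N), function(k) exterior_sphere_green(x, centres[k, ]),
               numeric(1))
  Q <- 4 * a * Gx
  if (order >= 2) {
    for (k in seq_len(N)) {
      inter <- 0
      for (j in seq_len(N)[-k]) {
        # surface-to-surface Green's function: evaluate just off the surface
        Gjk <- exterior_sphere_green((1 + 1e-9) * centres[j, ], centres[k, ])
        inter <- inter + Gjk * Gx[j]
      }
      Q[k] <- Q[k] + 4 * a^2 / pi *
        ((1.5 - log(2 * a)) * Gx[k] - 4 * pi * inter)
    }
  }
  Q
}

#' Coefficient of variation of a binomial capture estimate
#'
#' The relative Monte Carlo error of an estimated capture probability `p*`
#' from `M` independent trajectories: `CV = sqrt((1 - p*) / (p* M))`,
#' the O(M^-1/2) error scale of the method.
#'
#' @param p_star capture probability in (0, 1].
#' @param M number of trajectories.
#' @return CV.
#' @export
coefficient_of_variation <- function(p_star, M) {
  stopifnot(all(p_star > 0), all(p_star <= 1), all(M >= 1))
  sqrt((1 - p_star) / (p_star * M))
}
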