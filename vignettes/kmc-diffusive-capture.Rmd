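---
title: "Kinetic Monte Carlo for diffusive capture in exterior domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic Monte Carlo for diffusive capture in exterior domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmcapture)
```

## The problem

A signalling molecule diffuses (diffusivity $D$) in the unbounded region
outside a cell surface.  Most of the surface reflects the molecule; small
absorbing sites (receptors, pores) capture it.  The quantities of interest
are the flux density $J_k(t)$ of first arrivals at site $k$, the cumulative
capture fraction $F(t)$, the splitting probabilities
$Q_k = \lim_{t\to\infty} q_k(t)$, and — because the domain is unbounded — the
finite probability of never being captured at all.  Time-stepped Brownian
dynamics is poorly suited to this problem: trajectories are long, capture
times are fat-tailed, and a fixed step size biases absorption near the
mixed absorbing/reflecting boundary.

`kmcapture` instead advances each trajectory by *exactly solvable* jumps
(kinetic Monte Carlo): every move samples the analytic first-passage law of
a simple auxiliary geometry, so the simulated arrival statistics carry no
time-discretization error, only $O(M^{-1/2})$ Monte Carlo error in the
number of particles $M$.

## The three propagators

**Projector I — point to plane.**  For a particle at height $z_0$ above an
absorbing plane, the impact time has CDF
$\operatorname{erfc}\!\big(z_0/(2\sqrt{Dt})\big)$, inverted as
$t^\ast = z_0^2 / (4D\,[\operatorname{erfc}^{-1}(\nu)]^2)$ for a uniform
draw $\nu$; the lateral displacements at impact are independent
$N(0, 2Dt^\ast)$ variables.

**Projector II — hemisphere exit.**  A particle on a reflecting plane
re-enters the bulk by stopping on the hemisphere of radius $R$ centred at
its position, with $R$ the largest radius whose base circle stays in the
reflecting region.  In the dimensionless time $\tau = \pi^2 D t / R^2$ the
exit-time CDF has two complementary series (an alternating exponential
series for $\tau \ge 1$ and, via Poisson summation, a theta-function form
that converges fast for $\tau < 1$); both are truncated at $10^{-16}$ and
agree at the switch point to $10^{-12}$.  The exit point is isotropic, so
its height fraction is uniform.  The package tabulates the CDF on 4096
log-spaced $\tau \in [10^{-6}, 30]$ and inverts it by linear interpolation,
switching to the asymptotic $\tau \approx \log[2/(1-\xi)]$ when
$\xi > 1 - 10^{-3}$.

**Projector III — escape or reinsertion.**  A particle at distance $R_0$
from the centre of a sphere enclosing the target either escapes to infinity
or returns.  With the launch/landing ratio fixed at $R$ (default 3), capture
on the landing sphere of radius $R_0/R$ occurs with probability $1/R$ and
arrival time $t^\ast = (R-1)^2/(4D\,[\operatorname{erfc}^{-1}(R\mu)]^2)$
(unit landing sphere; rescaled by $(R_0/R)^2/D$).  The landing *angle*
relative to the launch axis is drawn from the conditional law
$$P_\Theta(\theta; t) = \tfrac12(1-\cos\theta) + \tfrac12 \sum_{n\ge1}
\frac{\chi_n(t)}{J(t)}\big[P_{n-1}(\cos\theta) - P_{n+1}(\cos\theta)\big],$$
which sharpens toward the pole for early arrivals and tends to the uniform
law $\tfrac12(1-\cos\theta)$ for late ones.

### Reconstructing the flux modes $\chi_n(t)$

The mode amplitudes are the Legendre coefficients of the first-arrival flux
on the unit sphere from an axial source at distance $R$.  Solving the
modified Helmholtz problem in the Laplace domain with modified spherical
Bessel functions $k_n$ and using their Wronskian gives
$$\hat\chi_n(s) = \frac{1}{R}\,e^{-\alpha(R-1)}\,
\frac{B_n(\alpha R)}{B_n(\alpha)},\qquad
\alpha = \sqrt{s/D},\qquad B_n(z) = \frac{k_n(z)}{k_0(z)},$$
with $B_n$ evaluated by the stable upward recurrence
$B_{n+1} = B_{n-1} + (2n+1)B_n/z$.  The time domain is reached by
fixed-Talbot quadrature (48 nodes).  Three independent checks pin this
reconstruction down: $\chi_0(t)$ reproduces the closed-form arrival density
to $10^{-7}$; the capture-marginalized angle distribution equals the
exterior-sphere harmonic measure (Poisson kernel), a closed form; and the
time-conditioned law matches a fine-step Euler–Maruyama simulation with
Brownian-bridge crossing detection (Kolmogorov–Smirnov distance < 0.02).
At very large $t$ the quadrature noise exceeds the genuinely tiny
coefficients (the $O(\alpha)$ terms cancel, so $\chi_n/J = O(1/t)$ for
$n \ge 1$); coefficients below an adaptive noise floor are therefore zeroed,
making the law degrade exactly to the uniform limit.  At very small $t$ the
Legendre series needs more than the capped 400 modes and the evaluation
refuses with an error; the tabulated range never enters that regime.

The $(\mu,\nu) \mapsto (t^\ast, \theta^\ast)$ lookup table is built on a
$400 \times 400$ midpoint grid ($\mu$ on $(0, 1/R)$, $\nu$ on $(0,1)$):
$t^\ast(\mu)$ in closed form, $\theta^\ast(\mu,\nu)$ by inverting
$P_\Theta$ on a 4001-point angle grid.  During simulation $t^\ast$ is
computed exactly from the drawn $\mu$ while $\theta^\ast$ uses the nearest
grid cell; interpolating the angle grid would refine this but is not needed
at the accuracy the estimators can resolve.

## The two stage machines

**Half-space with planar pores.**  From the bulk, Projector I drops the
particle onto the plane.  Inside a pore (boundary included): captured.
Outside every pore but inside the reinsertion disc $D_a$ — the smallest
disc containing all pores, scaled by the reinsertion ratio 3 — the particle
re-enters the bulk via Projector II with hemisphere radius equal to the
distance to the absorbing set.  Outside $D_a$, Projector III either removes
it (escape) or reinserts it onto a hemisphere enclosing the pores, using
the method of images: a landing below the plane is reflected to its image
point.

**Exterior of a convex polyhedron.**  Outside the ball $B_a$ (three times
the enclosing radius, below), Projector III applies.  Otherwise the
*target face plane* is the one with the largest positive signed distance —
any positive-distance plane separates a convex body from the particle, so
the resulting planar step is exact; the maximum merely maximizes progress.
Projector I drops the particle onto that plane.  If the impact lies in the
face: capture (absorbing) or a Projector II bounce through the largest
hemisphere whose base stays in the face, followed by re-projection onto the
*same* face plane (reflecting).  If it lies outside the face the machine
returns to the gate test.

### Numerical safeguards (and why they exist)

* **The gating/landing ball encloses the body, not just the absorbing
  set.**  The ball $R_a$ bounding the absorbing faces is reported and used
  for capacitance reasoning, but reinsertion lands particles on a sphere of
  one third of their distance from the centre; if that sphere did not
  enclose the whole body (e.g. the oblate ellipsoid, whose absorbing discs
  span a far smaller ball than its skirt), particles could be placed inside
  the body.  The gate therefore uses
  $\max(R_a, \text{body circumradius})$.
* **Edge lift.**  Alternating projections can grind a particle numerically
  onto a face edge, where the impact height and the inscribed radius both
  vanish and no propagator can move it.  Any impact height below
  $\varepsilon = 10^{-9}\times$ (body radius) is raised to $\varepsilon$ — a
  one-part-in-$10^9$ spatial bias, far below anything the $O(M^{-1/2})$
  estimators can resolve — which restores the multiplicative escape from
  the edge region.
* **On-surface face resolution.**  Exactly coplanar neighbouring faces (a
  cylinder's stacked wall panels) make the argmax plane ambiguous for a
  particle lying on the shared plane; the lowest-index tie-break can then
  select a face that does not contain the particle, freezing progress at
  the $\varepsilon$ scale.  When the best signed distance is below
  $\varepsilon$, the machine instead finds the face that actually contains
  the particle and interacts with it.
* **Tie-breaks.**  Equal signed distances resolve to the lowest face index;
  polygon boundaries count as inside, so a measure-zero landing on a pore
  rim still terminates deterministically.
* **Mesh validation tolerance** is $10^{-10}\times$ the body diameter
  (coplanarity, convexity, watertightness), suited to double-precision
  builders.
* **Safety cap.**  A trajectory is abandoned as `lost` after $10^6$
  propagator steps.  The machines terminate almost surely; in every shipped
  configuration the lost count is zero, and the tests assert it.

For large meshes the simulation core locates the target face by
hill-climbing on the face adjacency graph from the previous face, falling
back to a full scan whenever the climb fails to produce a positive
distance.  A local maximum is still a separating plane, so the sampled law
is unchanged; only the sojourn lengths (efficiency) could differ.  The
exported `select_target_face()` is the exact full scan and the test suite
checks it against brute force.

Particles are simulated sequentially to completion on R's global RNG
stream, so a run is a deterministic function of `(config, seed)` and there
is no batch structure that could affect results.

## Built-in geometries as study conditions

* `build_cube(side)` — the classical capacitance benchmark; all six faces
  absorbing.
* `build_sphere_mesh(N, a, n_vertices)` — unit sphere triangulated by
  icosahedral subdivision, with `N` circular windows of angular radius `a`
  centred at Fibonacci spiral points; facets are flagged absorbing when
  their centroid falls in a pore cap.  Icosahedral subdivision is used
  rather than triangulating randomly placed, energy-relaxed points: it is
  watertight and convex by construction and already quasi-uniform, which is
  what the relaxation was for.  The repulsive-energy relaxation
  (`relax_sphere_mesh()`, reciprocal pairwise distances, tangential
  projected gradient descent, fixed iteration budget) is provided for
  vertex sets that need it; the icosphere builders default to zero
  iterations.  The realized absorbing-area fraction is attached to the mesh
  and converges to $\sigma = N a^2/4$ under refinement (within 2.6% at
  5120 facets and 0.4% at 20480 for the 51-pore, $\sigma = 0.1$ case);
  coarse meshes absorb slightly *more* than $\sigma$ because ragged pore
  boundaries carry extra capacitance.  Against the homogenized (smooth-pore)
  prediction the terminal capture fraction for the 51-pore,
  $\sigma = 0.1$ case runs high by about 0.013 at 5120 facets, 0.007 at
  20480 and 0.006 at 81920: the ragged-boundary part converges away under
  refinement, leaving a residual $\approx 0.006$ absolute ($\approx 2.5\%$
  in $\kappa$) that is the homogenized Robin theory's own finite
  pore-size accuracy at $a \approx 0.089$.  A comparison at three binomial
  standard errors with $M = 10^5$ trajectories (band 0.004) therefore
  resolves this offset and fails, and the package's validation suite
  reports exactly that — a statement about the asymptotic theory's
  accuracy, not a sampler defect (the same machine reproduces the fully
  absorbing sphere law to KS < 0.003 and the cube capacitance to a tenth
  of a CV at $M = 10^6$).  Meshes that conform to the pore rims would
  remove the discretization part, but a conforming re-triangulation is
  incompatible with keeping the fixed icosahedral connectivity an exact
  convex hull, which the propagators rely on.
* `build_ellipsoid_mesh(Req)` — two flat absorbing unit discs at
  $z = \pm 1$ (absorbers "top"/"bottom") joined by a reflecting skirt of
  equatorial radius $R_{eq} \ge 1$: a cylinder at $R_{eq} = 1$, an
  increasingly oblate spheroid beyond.  Each disc is a single polygonal
  face; the skirt is a ring of planar trapezoids with an equatorial vertex
  ring (an odd ring count keeps a ring exactly at $z = 0$).

## Closed-form layer

The `theory` functions implement the two-term small-pore asymptotics for
planar pores (flux densities, their exact time integrals, splitting
probabilities with $C_k = 2r_k/\pi$), the bipolar-coordinate series for the
two-disc capacitance, boundary homogenization for the patchy sphere (Robin
constant $\kappa$, arrival density and CDF, total capture probability
$1/((1+D/\kappa)R)$), the capacitance-equivalent-sphere CDF, the
exterior-sphere Green's function and the two-term splitting probabilities
for circular surface patches.  Two transcription choices deserve note,
both fixed by internal consistency and verified by simulation:

* The cross-pore interaction term of the planar flux expansion carries a
  *minus* sign; with it, term-by-term integration reproduces the printed
  splitting-probability formula exactly (shielding reduces flux).
* In the Robin constant
  $\kappa = \frac{4D\sigma}{\pi a}\big[1 - \tfrac{4}{\pi}\sqrt\sigma +
  \tfrac{a}{\pi}\log(4e^{-1/2}\sqrt\sigma)\big]^{-1}$ both occurrences of
  $\sigma$ in the bracket sit under a square root (the dilute-limit
  pairwise-interaction scaling); KMC terminal capture fractions
  discriminate decisively between this reading and the radical-free one
  (7 vs 29 standard errors at $M = 10^5$).
* In the two-disc capacitance series the $d^{-3}$ term is
  $2(12+\pi^2)/(3\pi^3 d^3)$; the $\pi^3$ keeps the $\pi^{-n}$ pattern of
  the series and agrees with KMC at $d = 4$ within half a CV, while a
  $\pi^2$ reading is off by six CVs.

`erfc(\beta)e^{\beta^2}` terms are evaluated through the scaled
complementary error function (asymptotic continuation beyond $x = 5$), so
the homogenized density is finite down to $t = 10^{-8}$.

Numerical quadratures in tests use adaptive integration with tight absolute
tolerances; infinite horizons are handled by the integrator's own
transformation.

## What the tests establish — and at what sizes

The validation suite runs, on one CPU, in minutes, using these study sizes:
the disc and cube capacitances and the two-disc series at $M = 10^6$
trajectories; the homogenized 51-pore sphere ($\sigma = 0.1$, 20480
facets) and the five-pore splitting study ($\sigma = 0.02$, $D = 2$) at
$M = 10^5$; the ellipsoid shielding contrast at
$M = 4\times10^5$ per geometry; and the facet-count scaling study at
$M = 2\times10^4$ over three refinements (1280, 5120, 20480 facets), where
the fitted exponent of the 95th-percentile step count lands near 0.44 —
the "walk on the surface" heuristic predicts $1/2$, and values around 0.4
are expected to depend on the mesh generator.  Every stochastic tolerance
is three binomial standard errors (or a stated KS distance) *at the size
actually run*; none is tuned to a particular draw.

One benchmark number is asserted at a value that differs from its
published counterpart: for the six-pore configuration (five pores of radius
0.01 on the unit circle, a unit pore at $(15,0,0)$, release at the origin)
the two-term splitting formula gives a large-to-small capture ratio of
1.3260 — the leading order is exactly $(2/(15\pi))/(0.1/\pi) = 4/3$, and
desk evaluation of every term confirms the two-term value.  The published
ratio 2.4175 is reproduced only for an elevated release point near
$(0,0,1.6)$, so it appears to use an unstated release height; the package
asserts the value its stated inputs actually produce.

## Limitations

* Bodies must be convex polyhedra; curved surfaces enter only as
  triangulations, whose inscribed-body capacitance is biased low by
  $O(\text{sagitta})$ and whose ragged pore boundaries bias absorption high
  at coarse resolution — both vanish under refinement but are visible at
  percent scale on 5120-facet spheres.
* Planar pores are circles; other shapes would need a user-supplied signed
  distance and capacitance.
* The angular reinsertion table uses nearest-grid lookup; its
  discretization (1/800 in each uniform variable) is below every tolerance
  used here but would matter for extreme-tail studies.
* Interior (bounded) domains, periodic absorber arrays, and rare-event
  branching for the far tail are out of scope.
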