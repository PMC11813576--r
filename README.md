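# kmcapture

Kinetic Monte Carlo (KMC) simulation of diffusive capture in exterior
domains: Brownian particles (diffusivity *D*) wandering in the unbounded
region above a reflecting plane with absorbing circular pores, or outside a
convex polyhedron whose faces are absorbing or reflecting.  The package
targets the first-passage quantities that matter in chemoreception and
directional-sensing models: per-receptor flux densities *J<sub>k</sub>(t)*,
cumulative capture fractions, splitting probabilities
*Q<sub>k</sub>(x<sub>0</sub>)*, capacitances, and the ratiometric
differential signal Ξ(t) between opposing receptors.

Instead of time-stepping, every move of a trajectory samples the exact
first-passage law of a solvable auxiliary problem:

1. **Plane impact** — from height *z₀*, the hitting time CDF is
   erfc(*z₀*/2√(*Dt*)), inverted in closed form; lateral displacements are
   Gaussian with variance 2*Dt*\*.
2. **Hemisphere exit** — from a reflecting patch, exit through a hemisphere
   whose base stays in the patch; the exit-time CDF is a rapidly convergent
   pair of series in τ = π²*Dt*/*R*², the exit point isotropic.
3. **Escape/reinsertion** — far from the target, a particle escapes to
   infinity with probability 1 − 1/*R* (*R* = 3 by default) or re-enters on
   an enclosing sphere at a tabulated time and polar angle; the angular law
   interpolates between pole-focused (early arrivals) and uniform (late
   arrivals) via a Legendre mode expansion of the exterior-sphere flux.

Arrival statistics therefore carry no discretization error — only binomial
Monte Carlo error with coefficient of variation √((1−p)/(pM)).

A closed-form theory layer (two-term matched asymptotics for well-separated
planar pores, the Strieder two-disc capacitance series, boundary
homogenization with Robin constant κ for patchy spheres, exterior-sphere
Green's-function splitting probabilities) provides the predictions the
simulations are validated against, and vice versa.

## Worked example

Estimate the capacitance of the unit cube (a classical benchmark with
reference value 0.66067815…) from a million trajectories released uniformly
on a sphere of radius 5:

```r
library(kmcapture)

cube <- build_cube(1)
cfg  <- run_config(M = 1e6, release = release_spec("sphere", 5), seed = 42)
rec  <- simulate_polyhedron(cube, cfg)

table(rec$outcome)
#> captured  escaped     lost
#>   132130   867870        0

est <- capacitance_estimate(rec, release_radius = 5)
est$C_hat
#> [1] 0.66065
est$CV
#> [1] 0.002563
```

The capture probability from radius 5 is *C*/5, so `C_hat = 5 × 0.13213 =
0.66065`, within a fiftieth of a coefficient of variation (0.26%) of the
reference value.  The same records feed `log_histogram()` (log-binned arrival times
with theory overlays), `empirical_cdf()` (per-receptor cumulative capture
fractions, whose terminal values are the splitting probabilities), and
`differential_flux_ratio()` (the Ξ(t) directional signal).

A command-line driver (`inst/exec/kmcapture`) exposes
`simulate-plane`, `simulate-polyhedron`, `build-mesh`, `build-tables`,
`theory` and `stats` subcommands over YAML configs, writing records as
tab-separated text with full provenance (seed, config hash) in the header.

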