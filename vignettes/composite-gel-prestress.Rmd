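---
title: "Modeling prestress in composite polymer gels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling prestress in composite polymer gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical picture

Articular cartilage bears compressive load through a composite architecture:
a stiff collagen network encloses aggrecan proteoglycan complexes that are
osmotically swollen but cannot leave the mesh.  The trapped particles inflate
the network, so even an unloaded gel carries internal stress — *prestress* —
which gives the tissue its resistance to compression.  `gelpress` implements
a minimal coarse-grained model of this material: a periodic bead-spring
star-polymer matrix (the network) with small self-associating star particles
(the trapped complexes) in implicit solvent.

Three osmotic pressures organize the analysis.  The composite gel's swelling
pressure decomposes as

$$\Pi_{com} = \Pi_{mix} + \Pi_{el},$$

a Flory–Huggins mixing part plus the elastic pressure of the cross-links,
and the equilibrium swelling state satisfies $\Pi_{com} = 0$.  The prestress
is defined against the osmotic pressure a solution of the embedded particles
would exert at the same swelling,

$$P_{el} = \Pi_{emb} - \Pi_{com},$$

so at equilibrium $P_{el,eq} \approx \Pi_{emb}$: the prestress is carried by
the particles.  All three pressures are measured in simulation from the
virial, $\Pi = \rho k_BT + W/(3V)$ with $W = \sum_{ij} \mathbf r_{ij} \cdot
\mathbf f_{ij}$ (we accumulate the standard three-dimensional pairwise
virial; the factor 1/3 makes the ideal-gas and barostat-consistency limits
exact, and bonded pairs contribute like any other force-carrying pair).

## The interaction model

All beads share one mass $m$, size $\sigma$, and energy scale $\varepsilon$
(reduced units, time unit $\tau = \sigma\sqrt{m/\varepsilon}$).  Non-bonded
pairs interact through three terms: a WCA core (Lennard-Jones cut and
shifted at its minimum $r_{min} = 2^{1/6}\sigma$), a square well of depth
$\lambda\varepsilon$ on $(0, r_{min}]$, and a cosine smoothing tail
$\tfrac12\lambda\varepsilon[\cos(\alpha r^2 + \beta) - 1]$ on
$(r_{min}, r_{cut}]$ with $\alpha r_{min}^2 + \beta = \pi$ and
$\alpha r_{cut}^2 + \beta = 2\pi$, which carries the potential continuously
to zero with zero slope at $r_{cut} = 3\sigma/2$.  The well depth is exactly
$-\lambda\varepsilon$ at $r_{min}$.  $\lambda \in [0,1]$ is the solvent
quality: 0 is an athermal good solvent, 1 a poor one, and linear chains show
ideal scaling at $\lambda = 0.646$.  Species-resolved values
$\lambda_{mtx}$, $\lambda_{emb}$, $\lambda_{cr}$ apply to matrix–matrix,
embedded–embedded, and cross pairs; the pair's own $\lambda$ is used directly
(no combining rule).  The matrix is athermal ($\lambda_{mtx} = 0$) and the
cross interaction defaults to zero, so self-association of the particles is
the single attractive knob, as in the cartilage-mimicking picture.

Bonded neighbors interact through a stiff harmonic spring $V_H = k(r-l_0)^2$
(literally, without a 1/2) with $k = 1000\,\varepsilon/\sigma^2$ and $l_0 =
0.99\sigma$, and are excluded from the non-bonded potential: the defining
property of a bonded pair at rest length is zero net force, which would not
hold if the WCA core (about $29\,\varepsilon/\sigma$ at $l_0$) also acted.

```{r}
library(gelpress)
head(potential_table(lambda_ = 1))   # r, V(r), F(r) for plotting
```

## Topology construction

The matrix is built of $N_b^3$ four-arm star polymers on a cubic lattice,
each arm an $M$-bead chain; arm tips bond tip-to-tip with the neighboring
star across each bridge, and bridges through the periodic boundary are
allowed.  Counts are exact: $n_{mtx} = N_b^3 (f_{mtx} M + 1)$ matrix beads,
$N_b^3 f_{mtx} M$ intra-star bonds, $N_b^3 f_{mtx}/2$ tip–tip bonds.

Which 4 of the 6 lattice neighbors each star bridges is not dictated by the
model, only that every star uses all four arms and the network spans all
three periodic directions.  We use an *axis-alternating* pattern: every site
bridges $+x$; sites in even-$i$ lattice planes bridge $+y$, odd-$i$ planes
bridge $+z$.  Every site then has exactly two $x$-bridges and two $y$- or
$z$-bridges, the graph is 4-regular and connected, and it winds all three
directions for any $N_b \ge 2$ (even or odd).  We chose this over parity
rules on $i+j$ (which are not 4-regular at the boundary for odd $N_b$); the
pattern function is pluggable in `build_matrix()` for users who want a
different wiring.  Bridge beads are laid evenly spaced along the bridge
axis — spacing fixed-length segments from both ends can overlap in the
middle when the bridge is shorter than $2Ml_0$ — and the stiff springs
relax either way within a few $\tau$.

Embedded particles are 4-arm stars with $M_{emb} = 3$ beads per arm
($M_{w,emb} = 13$), spherically symmetric at this size.  They are inserted
at uniformly random positions and orientations, rejecting any trial with a
non-bonded minimum-image distance under $\sigma$ ("without overlaps" for
beads of size $\sigma$).  The default composition matches embedded to
matrix segments, $n_{emb}/n_{mtx} = 1$.  The initial box is sized from a
configured volume fraction (default $\phi = 0.05$); the barostat owns the
density from there on, so this choice only affects equilibration time.

```{r}
ms <- matrix_spec(Nb = 3, M = 2)
topo <- build_matrix(ms)
topo <- insert_embedded(topo, embedded_spec(embedded_count_for_composition(ms)),
                        seed = 1)
composition(topo)      # ~1.02: 19 particles of mass 13 vs 243 matrix beads
network_span(topo)     # connected, winds x, y, z
```

## Integration and ensembles

The engine (compiled, linked-cell neighbor search with a direct-sum fallback
for sparse boxes) integrates velocity-Verlet at $\Delta t = 0.005\tau$.
Temperature is controlled by a Nosé–Hoover chain of length 3 (relaxation
$100\,\Delta t$); pressure by an isotropic Martyna–Tobias–Klein barostat
with its own chain (relaxation $1000\,\Delta t$; for targets near
$10^{-3}\,\varepsilon/\sigma^3$ raise `baro_damp` to about $4000\,\Delta t$
to avoid slow volume ringing).  Initial velocities are Maxwell–Boltzmann at
$k_BT$ with the net momentum removed, seeded.  Every run is deterministic
for a given seed, and sweep cells derive their seeds from a master seed
through a documented integer hash (`derive_seed()`).

Isolated single chains are the one place Nosé–Hoover is inappropriate (a
chain thermostat on a handful of degrees of freedom is not ergodic), so
chain-calibration runs use a Langevin (BAOAB) thermostat with friction
$1/\tau$.

Validation is built into the test suite: exact agreement of the cell-list
force/virial path with a direct $O(N^2)$ summation and with an independent
R-level oracle; ideal-gas density $\rho = P/k_BT$ under the barostat;
secular NVE energy drift below $10^{-4}$ over $10^4$ steps for a WCA fluid
at moderate density (at liquid-like densities the steep core makes the
drift of velocity-Verlet at this timestep approach $10^{-3}$ — a known
property of the integrator, not of the implementation); and agreement of
the finite-difference and volume-fluctuation compressibility estimators.

## Solvent-quality calibration

The theta point is located by scanning $\lambda$ and measuring, for every
chain-length doubling $(N, 2N)$, the local scaling exponent
$\nu = \tfrac12\log_2[\langle R_g^2\rangle(2N)/\langle R_g^2\rangle(N)]$ of
isolated chains, interpolating each to its $\nu = 1/2$ crossing.  Chain
sizes are sampled by an exact Metropolis Monte Carlo of the full
Hamiltonian (`sample_chain_rg()`: single-bead displacements for the bond
degrees of freedom plus pivot rotations for the global conformation), which
decorrelates $R_g$ orders of magnitude faster than dynamics near the
collapse transition; its agreement with the Langevin engine is asserted in
the test suite.

Finite chains cross $\nu = 1/2$ at a *stronger* attraction than the
asymptotic theta point (the finite-chain shift of the theta temperature):
the measured crossings fall from about 0.88 at mean pair length 14 to about
0.64 at mean pair length 79, and the sequence does not yet follow the
asymptotic $\lambda_\theta + a/\sqrt N$ law over accessible lengths — a
linear fit in $1/\sqrt N$ is unstable and overshoots, and chains beyond
$N \approx 112$ cannot be equilibrated at desk scale even by the pivot
sampler.  `theta_point_lambda()` therefore reports the *direct* crossing of
the largest doubling, $(56, 112)$, measured on a bracketing $\lambda$ grid,
and returns the smaller-pair crossings so the finite-size trend — and with
it a bias bound of order the sequence's last decrement — stays visible.
Consistently, the monomer-level theta condition $B_2(\lambda) = 0$ falls at
$\lambda = 0.625$ for this potential.  The small-$N$ crossover also means
absolute effective exponents are high (about 0.68 at $\lambda = 0$ for
$N \le 40$, versus the asymptotic 0.588): desk-scale chains measure the
crossover, not the asymptotic regime.

## Measuring prestress

`pressure_sweep()` runs one NPT simulation per imposed pressure for a system
kind (composite gel, particle solution, bare gel) and records mean inverse
volume fraction $1/\phi$ — with $\phi = (n_{emb}+n_{mtx})(\pi/6)\sigma^3 /
\langle v\rangle$ — against pressure, with block-averaged errors (10 blocks).
`compute_prestress()` interpolates the composite and particle curves onto a
common $1/\phi$ grid with a monotone piecewise-cubic interpolant (restricted
to the overlap of the two ranges, so nothing is extrapolated silently) and
subtracts.  The equilibrium swelling $\Pi_{com} = 0$ cannot be simulated
directly — a barostat at zero pressure against vacuum has no restoring
force — so it is obtained by root-finding on the interpolant when the curve
brackets zero and otherwise by linear extrapolation of the two
lowest-pressure points, flagged as extrapolated in the result.  The particle
solution is simulated as the same number of embedded stars in their own
periodic box over the same pressure grid.

```{r}
par04 <- model_parameters(lambda_emb = 0.4)
com <- pressure_sweep("composite", ms, pressures = c(0.005, 0.02, 0.08, 0.3),
                      params = par04, master_seed = 1)
emb <- pressure_sweep("particles", ms, pressures = c(0.005, 0.02, 0.08, 0.3),
                      params = par04, master_seed = 2)
pre <- compute_prestress(com, emb)
pre$P_el_eq      # prestress at equilibrium swelling
```

## Continuum fits

`fit_composite()` fits $\Pi_{com}(\phi) = \Pi_{mix} + \Pi_{el}$ with
$\Pi_{mix} = -A[\ln(1-\phi) + \phi + \chi_0\phi^2 + \chi_1\phi^3]$ and
$\Pi_{el} = K_1\phi^{1/3} + K_2\phi^{4/3}$.  In reduced units the molar
scale $RT/V_1$ is not separately identifiable, so a single prefactor $A$
stands for it and is fixed at 1 by default.  The fit is bounded
($\chi_0 \in [0,2]$, $\chi_1 \in [-1,1]$, $K_1 \in [-10,0]$,
$K_2 \in [0,10]$ — the elastic term must pull at high swelling and push
under compression), weighted by $1/\text{stderr}^2$ when point errors exist,
and multi-started from 8 seeded points with best-of selection, which makes
it independent of point order.  Since no reference parameter values exist
for these curves, the fit is validated by recovery of known parameters from
synthetic data with 1% and 5% noise.  The particle solution follows the
osmotic virial law $M_{w,emb}\Pi_{emb}/\rho = 1 + B_2\rho + B_3\rho^2$,
ideal in the dilute limit.

## Problem sizes and what the tests show

The reference-scale systems ($N_b = 13$, production $150{,}000\tau$; a
ready-made long-running preset ships at
`inst/configs/reference_scale.yaml`) are far beyond an interactive session,
so the shipped experiments use desk-scale defaults chosen once: $N_b = 3$ ($N_b = 2$ for $M = 8$), composition grid
$\{0, 0.5, 1\}$, four pressures per curve in $[5\times10^{-3}, 0.3]$,
$150\tau$ equilibration and $300\tau$ production per pressure.  At this
scale the *trends* of the reference results are reproduced and asserted as
rank tests — composite gels swell monotonically with decreasing pressure;
smaller mesh ($M = 2$ vs 4) moves the $\Pi_{com} = 0$ crossing to smaller
$1/\phi$; loading inflates the gel ($v/v_0$ grows with composition, faster
for longer $M$); $\phi/\phi_0$ rises with loading at $M = 2$, stays near 1
at $M = 4$, falls at $M = 8$; self-association ($\lambda_{emb} = 0.4$)
depresses $\Pi_{emb}$ faster than $\Pi_{com}$ and creates an interior
maximum of $P_{el}$ over $1/\phi$ that purely repulsive systems lack; and
the bulk modulus rises with branch density and with particle inclusion —
while absolute reference-scale curve values are not targeted.  Desk-scale curves are
noisier and more finite-size-affected than the reference scale,
and the experimental PVA/PAA concavity of prestress curves is explicitly
outside what this neutral, implicit-solvent model reproduces.

## Known limitations

No charges, salt, explicit solvent, hydration, or entanglements; polymer
matrices other than the 4-arm cubic wiring are out of scope (the pattern
hook exists but only the default is validated).  Fluctuation-based moduli
need long runs to converge and are provided as a cross-check, not the
primary estimator.  Sample streams are kept as in-memory data frames and
CSV; trajectories as extended-XYZ.
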