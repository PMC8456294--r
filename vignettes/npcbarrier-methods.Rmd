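---
title: "Methods: the Gaussian-chain entropic-barrier model of the NPC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Gaussian-chain entropic-barrier model of the NPC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`npcbarrier` computes equilibrium free energies of FG-nucleoporins
(FG-Nups) inside the nuclear pore complex (NPC), treated with the field
theory of ideal continuous Gaussian chains.  The central channel is a
cylinder (diameter $D_\mathrm{pore}$, height $h_\mathrm{pore}$, axis = $z$,
$z \in [0, h_\mathrm{pore}]$); a cargo is a hard sphere of diameter
$d_\mathrm{cargo}$.  Each of the $n$ chains has Kuhn length $b$, contour
length $l$, reduced length $N = l/b$, and is anchored at a tether point
placed 1 nm radially inward from the wall.

All chain statistics are carried by the end-integrated propagator
$\tilde q(\mathbf r, s)$, the solution of the modified diffusion equation
(MDE)

$$\Big[\frac{\partial}{\partial s} - \frac{b^2}{6}\nabla^2
  + \beta V(\mathbf r)\Big] q(\mathbf r, s) = 0,
  \qquad \tilde q(\mathbf r, 0) = 1,$$

with $\tilde q = 0$ on the pore wall and cargo surface (hard surfaces
absorb chain conformations) and zero normal flux on the two open ends
(conformations may fold back through the pore mouths).  The free energy is
$F = -\ln\prod_i \tilde q(\mathbf r_{\perp,i}, N)$ in units of
$k_\mathrm B T$, and everything of interest is a difference
$\Delta F = F_\mathrm{cargo} - F_\mathrm{empty}$.

Key assumptions, inherited from the underlying model class:

* **Ideal chains.** No excluded volume and no chain–chain cohesion; the
  barrier is purely conformational-entropic plus (optionally) the
  adsorption energy.  Systems dominated by FG-Nup cross-linking (selective
  phase behaviour) are outside this model's scope.
* **Continuum validity above the Kuhn length.**  Spatial features smaller
  than $b = 0.86$ nm are not meaningful; discretization scales are chosen
  to match, not exceed, this resolution.
* **Equilibrium only.**  No translocation kinetics, rates, or friction.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `pore_diameter_nm` | 40 | nm | channel diameter (yeast NPC reference; 60 for the dilated pore) |
| `pore_height_nm` | 40 | nm | channel height |
| `chain_kuhn_nm` (b) | 0.86 | nm | Kuhn length; sets chain flexibility and the MDE diffusivity $b^2/6$ |
| `chain_contour_nm` (l) | 180 | nm | FG-Nup contour length; $N = l/b \approx 209.3$ |
| `chain_count` (n) | 80 | — | number of FG-Nups |
| `gamma_kBT` | 1.0 | $k_\mathrm B T$ | adsorption well depth; reference range 0.9–1.2 |
| `r_cutoff_nm` | 0.86 | nm | adsorption range around each binding spot (one Kuhn length) |
| `ds` | 0.4 | — | contour step; $b\,\Delta s < b$ keeps contour resolution below the Kuhn length |
| `vertex_density` | 1 | nm⁻² | cargo-surface vertex density (≈ one vertex per Kuhn-length square) |

The critical diameter $d^*$ is the linear-interpolation crossing of
$\Delta F = 1\,k_\mathrm B T$ on the 2–38 nm diameter grid (2-nm steps);
if the curve crosses more than once the final upward crossing is used and
a warning is emitted.

## Numerical scheme

**Contour stepping.** Backward Euler.  The requested step `ds` is adjusted
to $\Delta s_\mathrm{eff} = N/\lceil N/\Delta s\rceil \le \Delta s$ so the
endpoint $s = N$ is hit exactly with *uniform* steps.  Uniform steps keep
the per-step operator constant (a single sparse Cholesky factorization per
solve) and make the contour grid symmetric under $s \mapsto N - s$, so the
density integrand $q_c(\cdot, s_k)\,\tilde q(\cdot, N - s_k)$ falls on
stored slices exactly.

**Spatial discretization.**  Symmetric finite volumes:

* *Axisymmetric path* — an $(r, z)$ grid (default spacing 0.4 nm) used for
  centred inert cargoes, where the problem has no azimuthal dependence.
  The wall radius is an exact grid line; the sphere is a nodal mask.
* *3-D path* — a Cartesian grid (default spacing $b$) used for off-axis
  cargoes and whenever an adsorption potential is present (binding spots
  break axisymmetry).  Cylinder and sphere boundaries are staircase node
  masks.

Both operators are volume-weighted and exactly symmetric, which gives
three structural guarantees verified in the test suite: a flux-free domain
preserves the constant solution to machine precision, point-source
propagation obeys Green-function reciprocity, and the discrete density
normalization $\int\rho = nN$ holds to machine precision (the $q_c$ source
at a tether carries weight $1/\tilde q(\mathrm{node}, N)$ evaluated at the
*source node*, which closes the discrete Chapman–Kolmogorov identity
exactly; $\ln Z$ itself uses bilinear/trilinear interpolation at the exact
tether coordinates).

**Matched-resolution differencing.**  $F_\mathrm{cargo}$ and
$F_\mathrm{empty}$ are always computed on grids built from the same
parameters and of the same representation (axisymmetric with axisymmetric,
3-D with 3-D), so the dominant discretization bias — the wall boundary
layer — cancels in $\Delta F$.  The residual error from the staircase
cargo surface converges first order in the spacing; the built-in
validation suite checks that a 2× refinement moves a representative
$\Delta F$ by less than 15%.

**Linear solves.**  Each backward-Euler step is an SPD solve done by
CHOLMOD sparse Cholesky; a direct-residual guard rejects solutions with
relative residual above $10^{-10}$.  With the default grids the
19-diameter reference scan completes in a few seconds; the 3-D reference
grid (~10⁵ nodes) takes a few minutes per propagator solve.

**Accuracy control.**  The half-space problem with an absorbing plane has
the closed form $\tilde q(z, s) = \mathrm{erf}\big(z\sqrt{3/(2b^2s)}\big)$;
`error_ratio_control()` reproduces it with the production machinery and
reports the maximal relative error over nodes at least one Kuhn length
from the wall (~$8\times10^{-4}$ at reference settings, far below the 5%
admissibility bound, supporting the $|\Delta F| \ge 0.1\,k_\mathrm B T$
reliability floor).

## Tether layout

The reconstructed NPC tether coordinates used to pose the original
problem come from an external structural model and are not redistributable,
so the package ships a deterministic synthetic stand-in: two rings of 40
tethers at heights $h/3$ and $2h/3$, radius $D_\mathrm{pore}/2 - 1$ nm,
equal angular spacing, consecutive rings staggered by half a spacing.  Any
other layout can be supplied as a CSV (`x_nm,y_nm,z_nm`); points are
projected radially onto the 1-nm-inward shell.  Free energies are mildly
sensitive to the layout; the critical-diameter checks therefore carry
layout-freedom bands (4–8 nm at reference, 16–24 nm for the dilated pore)
rather than point targets.

## Binding spots and the Kent distribution

The cargo surface is discretized into
$N_\mathrm{all} = \mathrm{round}(\sigma_v \pi d_\mathrm{cargo}^2)$ unit
directions on a deterministic Fibonacci lattice ($\sigma_v = 1$/nm², so
the vertex spacing matches the model's Kuhn-scale resolution).  Binding
spots are either

* a **uniform cap**: all vertices below the latitude whose spherical-cap
  area fraction equals the requested coverage, centred on the cargo-frame
  $-z$ pole (the classical "NTR on one side" picture), or
* **Kent-distributed**: $N_\mathrm{bind}$ vertices sampled without
  replacement with weight proportional to the Kent density
  $f(\mathbf x) \propto \exp\{\kappa \gamma^{(1)T}\mathbf x +
  \beta[(\gamma^{(2)T}\mathbf x)^2 - (\gamma^{(3)T}\mathbf x)^2]\}$ with
  $\beta = 0$ (von Mises–Fisher) throughout.  Selection is explicitly
  seeded and the seed is recorded in outputs.

The binding area is $S = (N_\mathrm{bind}/N_\mathrm{all})\,\pi
d_\mathrm{cargo}^2$, reported relative to $S^* = \pi(20\,\mathrm{nm})^2$.
When a scan holds the absolute $S$ fixed across cargo sizes, a cargo too
small to host it has its coverage clamped at 1 with a warning (the
geometric demand is unsatisfiable).  Orientation averaging uses the
$20\times11$ grid $\theta = p\pi/5$, $\varphi = m\pi/10$ and the
*arithmetic mean of free energies* (not a Boltzmann average of partition
functions), matching the averaged-free-energy convention.

### A caution on attractive-cargo magnitudes

With $\sigma_v = 1$/nm² and $r_\mathrm{cutoff} = b$ the cutoff balls of
neighbouring spots overlap into a contiguous attractive shell.  For
$\gamma$ in the reference range this shell supports a bound state of the
MDE operator (ideal-chain adsorption is supercritical), so each chain that
reaches the cargo gains free energy proportional to $\lambda N$ — at
reference scale, orientation-averaged $\bar{\Delta F}$ values of order
$-10^3\ldots-10^4\,k_\mathrm B T$.  The *trends* — $\bar{\Delta F}$
decreasing in $\gamma$, approximately linear in $S$, and lower for
clustered ($\kappa = 2$) than scattered ($\kappa = 0.5$) layouts at equal
$S$ — are robust to this and are what the test suite asserts; absolute
attractive magnitudes depend sharply on the unpublished spot sparsity and
should not be read quantitatively.

## Validation oracles

* **Closed form**: the half-space erf solution (above).
* **Monte Carlo**: discrete Gaussian-step chains (per-coordinate step
  variance $b^2\Delta s/3$, the exact match to the MDE diffusivity) grown
  from each tether; absorption on walls and cargo with locally planar
  Brownian-bridge crossing corrections, which remove the
  $O(\sqrt{\Delta s})$ survival bias of naive discrete-position checks;
  reflection at the open ends realizes the zero-flux condition; adsorption
  enters as $\exp(\gamma\,\Delta s\,\#\{\text{steps in range}\})$.  The
  standard error uses the delta method for the log of a mean.  The sampler
  exists to validate the PDE solver on small instances (3-standard-error
  agreement on a 10 nm pore with a 4 nm cargo), not to compute
  production-scale results.

## Design choices made where the design was open

* **Source normalization** of $q_c$: the tether delta carries weight
  $1/\tilde q(\mathbf r_\perp, N)$ (division), the only reading that makes
  the density integrate to $nN$; this is enforced as a machine-precision
  test, not a tolerance test.
* **Uniform contour steps** rather than one shortened final step (see
  above).
* **Coordinate convention**: pore axis = $z$, cargo "centre of the NPC" =
  $(0, 0, h/2)$.
* **Temperature** enters only in the pN conversion
  (1 $k_\mathrm B T$/nm = 4.114 pN at 298 K); all internal energies are in
  $k_\mathrm B T$.
* **Mean insertion force**: reported as insertion work over path length
  along the axial mouth-to-centre path (2-nm sampling), i.e. a true mean
  force; the pointwise central-difference profile $-\mathrm d\Delta
  F/\mathrm dz$ is also returned.  The local slope at $d = 38$ nm (a 1-nm
  wall gap, at the model's resolution limit) exceeds the mean by several
  fold and is not the headline statistic.
* **Convexity diagnostics**: $\Delta F$ versus free volume
  $v = \pi D^2 h/4 - \pi d^3/6$ is checked for convexity in the barrier
  regime $d \ge 8$ nm.  For smaller cargoes $\Delta F$ scales with $d$
  (absorbing-obstacle capacitance) while $v - v_\mathrm{empty} \sim -d^3$,
  which makes $\Delta F(v)$ concave near $v_\mathrm{empty}$ in the exact
  model too; this is a property of the model, not a numerical artifact
  (verified at 0.4/0.2/0.1 nm spacings).

## What the test problems do and do not show

Unit and property tests run on scaled-down systems (pores of 10–20 nm,
chains of $N \approx 25$–70, 8–16 tethers, four-orientation subsets) so
the suite completes in minutes; the acceptance-level checks (critical
diameters, insertion force) run at the full reference conditions via the
axisymmetric path.  The scaled-down attractive systems sit in the deeply
adsorbed regime (cargo close to the tethers), so they exercise the trend
properties, not paper-scale magnitudes.  The synthetic tether layout
reproduces wall-tethering and the 1-nm inward shift but not the
azimuthal/vertical irregularity of the reconstructed NPC; passing tests
demonstrate correctness of the solver and the model's qualitative
selectivity behaviour, not agreement with any specific structural model of
the NPC.

## Known limitations

* No excluded volume or cohesion between chains; no self-consistent field
  iteration.  The model is linear in each chain.
* Staircase cargo boundary on the 3-D grid: first-order spatial
  convergence of $\Delta F$; near-wall gaps below ~1 nm (e.g. $d = 38$ nm
  in the 40-nm pore) are at the resolution limit.
* Orientation averaging at reference scale costs 220 3-D solves per
  diameter; plan accordingly (the inert/axisymmetric path does not have
  this cost).
* Absolute attractive free energies are supercritical-adsorption dominated
  at the default vertex density (see the caution above).
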