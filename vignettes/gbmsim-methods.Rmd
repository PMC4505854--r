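---
title: "gbmsim: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gbmsim: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmsim)
```

## The model

Glioblastoma multiforme infiltrates diffusely, without a sharp host/tumor
interface, and preferentially along white-matter fiber bundles. `gbmsim`
describes the lesion and its environment as a saturated, incompressible
binary mixture: a tumor-cell phase with volume fraction $\phi$ and a
liquid/host phase $1-\phi$, both with the true density of water. Mass
balances of the two phases, a Ginzburg--Landau free energy for the cell-cell
interactions, and a Rayleigh dissipation principle for the viscous
interphase friction yield a fourth-order Cahn--Hilliard-type equation for
$\phi$, coupled to a reaction--diffusion equation for the oxygen
concentration $n$:

$$
\frac{\partial \phi}{\partial t}
 = \nabla\cdot\!\Big(\frac{\phi(1-\phi)^2}{M}\nabla\Sigma\Big)
 + \nu\,\phi\Big(\frac{n}{n_s}-\delta\Big)(1-\phi)
 - \nabla\cdot\big(k_n\,\phi\,\mathbf{T}\nabla n\big),
\qquad
\Sigma = f(\phi) - \epsilon^2\Delta\phi,
$$

$$
\frac{\partial n}{\partial t}
 = \nabla\cdot(\mathbf{D}\nabla n) + S_n(n_s - n) - \delta_n\,\phi\,n .
$$

The ingredients, each a pure function in the `model_core` layer:

* **Bulk pressure** $f(\phi)=E\,\phi^2(\phi-\phi_e)/(1-\phi)$
  (`bulkPressureDerivative()`): cells attract below the equilibrium
  fraction $\phi_e$ ($f<0$), exert no force at $\phi\in\{0,\phi_e\}$, and
  repel with diverging pressure as $\phi\to 1$. $\Sigma$ is the excess
  pressure the cells exert; its gradient drives a Darcy-like drift with
  degenerate motility $K(\phi)=(1-\phi)^2/M$ (`motility()`), the inverse of
  the interphase friction, vanishing at cell-contact saturation.
* **Proliferation** $\Gamma/\gamma=\nu\phi(n/n_s-\delta)(1-\phi)$
  (`netProliferation()`): oxygen-limited logistic growth that switches to
  hypoxic death where $n$ falls below the fraction $\delta$ of its
  physiological level $n_s$, with contact inhibition as $\phi \to 1$.
* **Fiber-guided chemotaxis** $J = k_n\phi\,\mathbf{T}\nabla n$
  (`chemotacticFlux()`): a Keller--Segel drift up the oxygen gradient,
  biased by the dimensionless tensor of preferential directions
  $\mathbf{T} = \mathbf{D}/D_n$ with $D_n = \tfrac13\mathrm{tr}\,\mathbf{D}$
  (`preferentialDirections()`, `meanDiffusivity()`). By construction
  $\mathrm{tr}\,\mathbf{T}=3$ wherever $D_n>0$: $\mathbf{T}$ encodes the
  *direction* of anisotropy and not its magnitude. In isotropic tissue
  $\mathbf{T}=\mathbf{I}$ recovers classical Keller--Segel drift; in a
  coherent fiber bundle the drift is confined to the bundle axis.

Boundary conditions: $\phi = 0$ and $\nabla\phi\cdot\hat n = 0$ on the
domain boundary, and $n = n_s$ (the vasculature maintains physiological
oxygen far from the lesion). The initial lesion is a Gaussian
$\phi_0 = A\exp(-|x-c|^2/2\sigma^2)$ with peak slightly above $\phi_e$
(diffuse interface from the start), and $n_0$ solves the stationary oxygen
balance for $\phi_0$ (`initialNutrient()`), equal to $n_s$ away from the
lesion and dipping toward the core.

## Parameters

All computations use (mm, day, mM, Pa). `modelParameters()` defaults are
literature estimates for human brain / GBM:

| parameter | default | meaning / provenance |
|---|---|---|
| $\nu_c$ | 0.3 /day | proliferation; in-vitro doubling 1--2 day, lower in vivo. Sensitivity sweeps use 1/day, the comparison run 0.25/day |
| $\delta_c$ | 0.3 | hypoxic-death threshold (range 0.28--0.5) |
| $n_s$ | 0.07 mM | physiological oxygen (range 0.07--0.28 mM) |
| $k_n$ | 100 mm$^2$ mM$^{-1}$ day$^{-1}$ | chemotactic coefficient (bacterial-chemotaxis estimate 1296) |
| $M$ | 5000 mm$^{-2}$ Pa day | interphase friction (inverse hydraulic conductivity 1377.9--4286.7; 5000 in the comparison setting) |
| $E$ | 694 Pa | Young's modulus of brain matter |
| $\phi_e$ | 0.389 | equilibrium cell fraction |
| $S_n$ | $10^4$ /day | blood--tissue oxygen transfer |
| $\delta_n$ | 8640 /day | uptake, $=D_n/l_n^2$ (`deriveUptakeRate()`; admissible 8640--15650) |
| $D_n$ | 86.4 mm$^2$/day | oxygen diffusivity (86.4--156.5) |
| $\chi$ | 900 Pa | interstitial fluid pressure scale (106.64 healthy, ~960 tumor) |
| $l_n$ | 0.1 mm | oxygen penetration length |
| $\epsilon$ | 0.45 | interface coefficient, see below |

**The $\epsilon$ convention.** The literature bookkeeping for $\epsilon$
(a cell-scale interaction distance $\epsilon/\chi$ of 10--20 µm, but a bare
number 0.02 in the comparison setting) cannot be made dimensionally
consistent. The package therefore accepts `eps` directly as a number whose
square multiplies $\Delta\phi$ to give Pa, and documents one consistent
reconstruction $\epsilon = \sqrt{\chi}\,\ell_{cell}$
(`deriveInterfaceCoefficient()`, default $\sqrt{900}\times 0.015 = 0.45$).
At desk-scale mesh resolution both values put the interface width below the
cell size of the mesh, so the $\epsilon^2$ term acts as a small
regularization; the dynamics are dominated by growth, degenerate-mobility
transport and chemotaxis, which is also the regime of the published
simulations. The true density $\gamma$ cancels analytically from the phase
equation and is never stored.

## Discretization

The fourth-order equation is rephrased as a mixed second-order system in
$(\phi, \Sigma)$ and discretized with linear tetrahedral (P1) elements;
reaction terms use a lumped mass matrix, flux coefficients are evaluated at
cell barycenters. Time stepping is Crank--Nicolson (trapezoidal) in both
equations; the nonlinear $(\phi,\Sigma)$ system is solved by Newton
iteration with the analytic Jacobian of $f$, of the degenerate mobility and
of the chemotaxis coefficient.

**Coupling order.** Each step solves the oxygen equation first and then the
$(\phi, \Sigma)$ system against the new oxygen field, which keeps the
chemotaxis term linear inside the Newton solve. A naive lag of $\phi$ in
the oxygen consumption term would degrade the splitting to first order, so
the consumption coefficient is frozen at the second-order midpoint
extrapolation $\phi_{1/2} = \tfrac32\phi^k - \tfrac12\phi^{k-1}$ (the first
step, and the substeps after a time-step halving, use one
predictor--corrector pass instead). The observed convergence order against
a high-accuracy ODE oracle on uniform fields is ~1.9.

**Boundary reconciliation.** The two boundary conditions on $\phi$ are
imposed as: $\phi = 0$ essential in the $\phi$-equation rows, and
$\nabla\phi\cdot\hat n = 0$ as the natural condition of the weak
$\Sigma$-equation; no-flux of the $\Sigma$- and chemotactic fluxes is the
natural condition of the $\phi$-equation on the remaining test space. A
separate pure-natural harness (`no_flux = TRUE` in `solverConfig()`) exists
solely for conservation and ODE-limit studies: there, with $\nu = k_n = 0$,
the discrete total cell volume $\int\phi$ is conserved to round-off because
the stiffness matrices annihilate constants exactly.

**Linear algebra.** The oxygen systems are symmetric positive definite
(also with degenerate anisotropic $\mathbf{D}$ such as
$\mathrm{diag}(D_n,0,0)$, because the $S_n$ reaction term adds a positive
diagonal) and are solved with a cached sparse Cholesky factorization whose
symbolic pattern is reused across steps. In the Newton system the
$(\Sigma,\Sigma)$ block is the lumped mass, so $\Sigma$ is eliminated
exactly and the Schur complement — strongly diagonally dominant through the
$M_L/\Delta t$ diagonal — is solved matrix-free with Jacobi-preconditioned
BiCGSTAB (tolerance $10^{-10}$), with a direct sparse-LU fallback on
stagnation.

**Guards and diagnostics.** Constitutive laws are evaluated on $\phi$
clipped to $[0, 1-10^{-6}]$ (`clip_eta`); clip events are counted in the
trajectory diagnostics, as are Newton iterations, time-step halvings
(automatic, up to 3 per step) and any excursions of $\phi$ outside
$[-10^{-3}, 1+10^{-3}]$. A step that leaves $[-10^{-2}, 1+10^{-2}]$ aborts
with advice to reduce `dt`. Default `dt` is 0.05 day; the desk-scale runs
below use 0.1 day, well inside the stability and accuracy range of the
scheme for growth rates of order 1/day.

## Domains, tensor fields and phantoms

`boxMesh()` tessellates a box into hexahedra split into six tetrahedra each
(Kuhn subdivision, conforming across hexahedra); `refineRegion()` performs
local red (1-to-8) refinement with a conforming green closure (bisection,
opposite-edge and face templates; cells whose marked-edge pattern fits no
template are promoted to red). Externally prepared labeled tetrahedral
meshes are read from Gmsh MSH v2.2 or legacy VTK (`readMesh()`); snapshots
are written as legacy VTK with $\phi$, $\Sigma$, $n$ and $n/n_s$ as point
data.

Because no patient DTI data are distributed, synthetic phantoms emulate the
three situations of interest: `isotropicPhantom()` ($\mathbf{D} = D_n
\mathbf{I}$, the control), `axisAlignedPhantom()` ($D_{xx} = D_n$, all other
components zero — the sensitivity-analysis construction, whose $\mathbf{T} =
\mathrm{diag}(3,0,0)$ confines drift to the $x$-axis), and
`fiberBundlePhantom()` (a curved tract: principal eigenvector tangent to a
polyline centerline, eigenvalues (parallel, perp, perp), isotropic at the
eigenvalue mean outside the bundle). Real tensor volumes enter through six
NIfTI component maps (`readTensorVolumes()`, axis-aligned grids only;
general affines are rejected), are cleaned with `regularizeTensors()`
(eigenvalue clamping; background voxels with zero mean diffusivity receive
a masked identity fallback rather than a division by zero), and transfer to
mesh cells by nearest-voxel lookup at the cell barycenter
(`sampleToMesh()`), mirroring the voxel-to-tetrahedron assignment used with
registered patient data. What the phantoms do *not* emulate: tissue
heterogeneity (white/grey/CSF contrasts), registration error, imaging
noise, and curved anatomy at brain scale — conclusions from phantom runs
are therefore trend-level, not patient-level.

## Shape metrics

The tumor region is $\Omega_t=\{\phi \ge \epsilon_t\}$ evaluated at cell
barycenters (`tumorRegion()`). The model only requires $\epsilon_t > 0$;
the package default is 0.05, config-exposed, and all reported metrics carry
the $\epsilon_t$ they used. Semi-axes $(\Delta x, \Delta y, \Delta z)$ are
measured along the coordinate axes through the region centroid as half the
distance between the outermost threshold crossings of a finely sampled line
(linear interpolation between samples; `semiAxes()`) — axis-aligned by
design, matching how the published figures measure the grown ellipsoid; a
PCA variant is out of scope. On a Gaussian profile the $\epsilon_t$ level
set is a ball of radius $\sigma\sqrt{2\ln(A/\epsilon_t)}$, recovered within
one cell diameter; `summarizeGrowth()` reports the standard ratios
$\phi^M/\phi^M_0$, $V/V_0$, $\Delta x/\Delta y$, $\Delta x/\Delta z$.

## Experiments and desk-scale study conditions

The experiment drivers reproduce the published computational experiments at
desk scale (the whole-brain mesh and patient DTI are unavailable, and the
conclusions under test are trend-level):

* **Sweeps** (`sensitivityMKn()`, `sensitivitySnDeltan()`): 40 mm box at
  $12^3$ resolution, dt 0.1 day, axis-aligned phantom, $2\times2$ grids;
  horizons 6 day ($M$--$k_n$, with $\nu = 1$/day, $S_n = 10^4$,
  $\delta_n = 8640$) and 9 day ($S_n$--$\delta_n$, with $M = 2000$,
  $k_n = 100$). Grids: $M \in \{2000, 5000\}$, $k_n \in \{1, 100\}$,
  $S_n \in \{2000, 10^4\}$, $\delta_n \in \{1000, 4000\}$. The checked
  trends (2% tolerance on ratios, absorbing discretization noise):
  $\phi^M/\phi^M_0$ non-decreasing in $M$ (friction suppresses the
  pressure-driven spreading, cells accumulate); $\Delta x/\Delta y$ and
  volume non-decreasing in $k_n$ (chemotaxis elongates along the fiber
  axis; at $k_n = 1$ the tumor is near-spherical); $\phi^M$ non-decreasing
  and volume non-increasing in $S_n$; volume non-decreasing in $\delta_n$.
  The $S_n$--$\delta_n$ grid is restricted to the oxygenated-growth regime
  (worst-corner $n_{\min} \approx 0.47\,n_s$, comfortably above
  $\delta_c$): when supply is so low that the lesion regresses
  ($n_{\min}$ near $\delta_c\,n_s$, $\phi^M$ falling), the volume-trend
  mechanism — steeper gradients, more chemotactic spreading, larger region
  — no longer applies, and the published panels all show growing tumors.
* **Comparison** (`compareAnisotropicIsotropic()`): 48 mm box at $16^3$,
  dt 0.1 day, 25-day horizon, comparison parameter set ($M = 5000$,
  $S_n = 10^4$, $\delta_n = 1000$, $\nu = 0.25$, $k_n = 100$,
  $\epsilon = 0.02$); the control replaces $(\mathbf{D}, \mathbf{T})$ by
  $(D_n\mathbf{I}, \mathbf{I})$ on the same mesh and seed. The anisotropic
  run elongates strongly along the fiber axis ($\Delta x > \Delta y,
  \Delta z$; larger major axis than the control) and reaches a higher
  $\phi^M$. One published finding does **not** transfer to uniform
  phantoms: the anisotropic run's *total* (thresholded) volume is smaller,
  not larger, than the isotropic control's. This is structural: both
  $\mathbf{T}$ fields have trace 3, so the two runs share the same
  chemotactic drift budget, and an equal split across axes maximizes the
  covered volume (kinematically, $(r_0+vt)^3$ versus
  $(x_0+3vt)\,r_0^2$). The reported volume excess of anisotropic growth
  arises from the heterogeneous patient tensor field — a lesion seeded in a
  high-$T_{xx}$ corridor of structured tissue — which no uniform phantom
  reproduces. The comparison driver reports both volumes and the
  difference.

Runs are configured by a single TOML file (sections `[domain]`,
`[tensors]`, `[model]`, `[initial]`, `[solver]`, `[output]`; a minimal TOML
subset is parsed in-package since no installed package provides the
format), are deterministic given the configuration (seed included), and
write VTK snapshots, a summary CSV row and a JSON manifest carrying an md5
digest of the re-serialized configuration. The `gbmsim` script in
`inst/scripts` exposes `run`, `sweep-mkn`, `sweep-sn-dn`, `compare` and
`phantom` subcommands over these functions.

## Numerical choices, degenerate inputs, known limitations

* Coefficients at barycenters + mass lumping keep the assembly exact for
  the uniform-field reductions used by the oracle tests, and make the
  Newton Jacobian blocks cheap and sparse.
* Degenerate mobility and chemotaxis coefficients use
  $\max(\phi, 0)$ and the $[0, 1-10^{-6}]$ clip inside the coefficients
  only; stored fields are never altered.
* Degenerate $\mathbf{D}$ (zero eigenvalues) is permitted throughout; no
  solver assumes strict ellipticity of the diffusion block alone.
* The discrete oxygen maximum principle is not guaranteed by the P1
  stiffness on anisotropic tensors, but the dominant lumped reaction term
  keeps $n \in [0, n_s(1+10^{-6})]$ in practice; every snapshot is checked.
* Mesh resolution in the published runs is unstated; resolution here is a
  config knob, and the metrics module's convergence is property-tested
  (observed order $\ge 1$ for level-set volumes under refinement).
* Out of scope: DTI estimation and preprocessing, registration, image
  segmentation and brain-surface meshing, angiogenesis, therapy and
  resection, and the patient case study's absolute numbers (its DTI volume
  and initial condition are not available).

## A small run

```{r example, eval = FALSE}
p <- modelParameters(nu_c = 1, S_n = 1e4, delta_n = 8640, k_n = 100, M = 2000)
mesh <- boxMesh(c(40, 40, 40), c(16, 16, 16))
grid <- phantomGrid(c(16, 16, 16), spacing = 2.5, origin = rep(1.25, 3))
D <- sampleToMesh(axisAlignedPhantom(grid, p@D_n), mesh)
T_f <- preferentialDirections(D)
phi0 <- gaussianInitialCondition(mesh, c(20, 20, 20), sigma_mm = 2, params = p)
traj <- runSimulation(mesh, D, T_f, p, solverConfig(dt = 0.1, t_end = 6), phi0)
summarizeGrowth(trajectoryStates(traj)[[1]], finalState(traj), mesh)
```
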