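---
title: "A porous-media model of bone-cement injection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A porous-media model of bone-cement injection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vertebropm)
```

## The model

`vertebropm` simulates the injection of acrylic bone cement into a fluid-filled
porous solid — the situation of vertebroplasty, where cement is pushed through
a cannula into the trabecular interior of a vertebra — as a three-phase
continuum in the Theory of Porous Media. Every material point carries a solid
skeleton $\varphi^S$ and two immiscible pore fluids, cement $\varphi^C$ and
marrow (or air) $\varphi^M$, described by volume fractions $n^\alpha$ with
$\sum_\alpha n^\alpha = 1$ and pore saturations $s^\beta = n^\beta / n^F$.
All constituents are materially incompressible, processes are quasi-static and
isothermal, and capillary pressure between the fluids is neglected (the
capillary number of cement injection is large), so both fluids share one pore
pressure $p$.

The governing equations are the solid volume balance (integrated analytically
to $n^S = n^S_{0S}/\det F_S$, linearized here to
$n^S = n^S_{0S}/(1 + \operatorname{div} u_S)$ for the small strains that
occur), the two fluid volume balances

$$(n^\beta)'_S + \operatorname{div}(n^\beta w_\beta)
  + n^\beta \operatorname{div} \dot u_S = 0 , \qquad \beta \in \{C, M\},$$

the overall momentum balance $\operatorname{div}(\sigma_E^S - p I) = 0$ with a
linear Hookean solid extra stress, and Darcy laws for the seepage velocities

$$n^\beta w_\beta = -\frac{\kappa_r^\beta K^S}{\mu^{\beta R}}
  \operatorname{grad} p ,$$

with scalar intrinsic permeability $K^S$, Brooks–Corey relative
permeabilities

$$\kappa_r^C = (1-s^M)^2\big[1-(s^M)^{(2+\lambda_{bc})/\lambda_{bc}}\big],
\qquad \kappa_r^M = (s^M)^{(2+3\lambda_{bc})/\lambda_{bc}},$$

and effective dynamic viscosities $\mu^{\beta R}$ obtained by upscaling the
pore-scale Carreau rheology

$$\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)
  \big[1+(\lambda_{rh}\dot\gamma)^2\big]^{(n_{rh}-1)/2}.$$

The primary unknowns are the solid displacement $u_S$, the pore pressure $p$
and the marrow saturation $s^M$; using the saturation (rather than a second
pressure) keeps the formulation independent of any capillary
pressure–saturation closure.

### Viscosity upscaling

The pore-scale viscosity cannot be used directly in the Darcy laws because the
shear rate varies across the pore space. Three interchangeable upscaling
models are provided (`upscaling_choice()`):

* **Cannella** and **Hirasaki–Pope** (semi-empirical capillary-bundle
  models): an effective shear rate
  $\dot\gamma_{eff} = \mathbb{C}\,[\tfrac{3n+1}{4n}]^{n/(n-1)}\,
  4|w_\beta|\sqrt{n^\beta/(8\kappa_r K^S)}$
  is inserted into the Carreau law, with $\mathbb{C} = 6.0$ (Cannella) or
  $0.69$ (Hirasaki–Pope). The relative permeability inside the square root is
  floored at `mobility_floor` ($10^{-6}$ by default) because the expression
  diverges as a phase becomes immobile while its flux simultaneously
  vanishes; the flux mobilities themselves are not floored.
* **Average viscosity** (semi-analytical): laminar Carreau flow through a
  representative pore channel of characteristic radius $R_{char}$ is solved
  for the pressure gradient that produces the local mean velocity, and the
  cross-section **area average** of the local viscosity is returned. Area
  weighting is the simplest member of the possible weightings (flux weighting
  would be an alternative); it is exact in the Newtonian limit and is
  isolated behind one function (`average_viscosity()`) so the weight can be
  swapped. Inside the solver this curve is tabulated once on a logarithmic
  velocity grid and interpolated with a monotone Hermite spline (relative
  error below $10^{-5}$, endpoints exact).

In the Darcy flux the upscaled viscosity is evaluated with the seepage-velocity
magnitude $|w_\beta|$, the only fluid velocity measure the model defines; the
same magnitude serves as the channel mean velocity of the average-viscosity
model.

## Discretization

The equations are discretized on trilinear (8-noded) hexahedra. The momentum
balance uses Bubnov–Galerkin finite elements with $2^3$ Gauss quadrature. The
two fluid balances use the vertex-centered finite-volume **Box** scheme:
every cell is split at edge midpoints, face centroids and the cell centroid
into eight sub-control volumes (SCV), one per vertex; fluxes cross the twelve
internal sub-control-volume faces (SCVF) with midpoint integration, the
pressure gradient from the trilinear shape functions, and **fully-upwind**
mobilities $\kappa_r/\mu$ taken at the upstream vertex of each face (upstream
decided by the sign of $-\operatorname{grad} p \cdot \hat n$ at the
integration point; both phases share one pressure and hence one direction).
Storage terms are mass-lumped — each vertex carries its SCV volume, computed
as the exact octant integral of the trilinear Jacobian so the SCVs partition
every cell to machine precision. Time integration is implicit Euler. The
system is solved monolithically by Newton's method.

### The local viscosity fixed point

The effective viscosity depends on the seepage velocity, which itself depends
on the viscosity. At every SCVF this closes into a scalar fixed point
$\mu = V(X/\mu)$ in which the whole state dependence enters through one
parameter $X$ (the seepage-velocity–viscosity product, rescaled by the model
constants). For Carreau fluids
$|\mathrm{d}\log\mu/\mathrm{d}\log w| \le 1-n_{rh} < 1$, so the root is
unique; it is tabulated once per phase by vectorized bisection on a wide
logarithmic grid and interpolated monotonically. Evaluating the viscosity
*locally at each integration point* — rather than lagging a nodal viscosity
field to the previous iterate — puts the full shear-thinning feedback into
the finite-difference Jacobian. This mattered in practice: bone cement thins
by three orders of magnitude across an injection front, and a lagged
(Picard-in-Newton) viscosity caused the two iterations to oscillate against
each other at the front, while the local formulation converges in a handful
of Newton steps.

### Newton solver

* **Jacobian**: the fluid block is assembled cell-locally by finite
  differences (16 local perturbations, vectorized over all cells); the solid
  stiffness and pressure-coupling blocks are exact and constant; the
  dilatation coupling from displacement into the fluid storage terms is added
  analytically.
* **Linear solve**: the solid block (constant) is factored once per run; the
  fluid block is factored per Jacobian refresh; the weak two-way coupling is
  resolved by two block Gauss–Seidel sweeps inside each linear solve, which
  is exact to far below the Newton tolerance at these parameters
  (displacements are nanometres).
* **Convergence** is a backward-error criterion per equation block: the
  residual norm must fall below `newton_tol` ($10^{-8}$) times the norm of
  the summed absolute magnitudes of the terms composing each row (Dirichlet
  rows excluded). This makes one tolerance meaningful across equations whose
  natural scales differ by many orders (GPa stiffness vs. m³/s balances).
* **Globalization**: a trust cap on the pressure update (the viscosity can
  drop by orders of magnitude within one step, so the pressure scale is let
  grow progressively) plus a backtracking line search.
* **Time stepping**: base step `dt` (0.25 s by default), halved on a failed
  step (up to `max_halvings`) and ramped in from `dt/8` on a cold start —
  the very first increments drive the displacement front through the inlet
  control volumes, the stiffest moment of the whole run. Saturations are
  clamped to $[0,1]$ after every update; excursions beyond $\pm10^{-8}$ are
  counted and reported in the time series.

### Boundary conditions

The benchmark geometry (a 40 mm × 30 mm cylinder with a cannula bore removed
to mid-height) is meshed as a staircase voxel approximation on a graded
tensor grid whose central cell columns match the bore half-width; at the
default resolution it has exactly 2540 hexahedral cells, and its volume is
within 1.4 % of the exact cylinder-minus-bore volume. Boundary facets carry
tags `inlet` (bore tip), `cannula_wall` (bore sides) and `outer_wall`.

* **Inlet**: the injection is a prescribed cement influx, flow rate divided
  by the summed tagged facet area, entering the cement balance as a Neumann
  source; the marrow sees a natural zero-flux condition there. (Constraining
  the inlet saturation instead would demand an instantaneous storage jump
  $n^F V/\Delta t$ that no flux can supply and breaks the first time step.)
  The inlet saturation reaches its injected value within the first few steps
  on its own.
* **Outer walls**: Dirichlet $p = 0$, and the marrow saturation is held at
  its far-field initial value — the standard treatment of a fully-Dirichlet
  outflow boundary in vertex-centered schemes; it is valid while the cement
  front remains interior, which holds for the 2-ml injections on this
  geometry.
* **Cannula walls**: zero fluid flux (natural) and clamped solid; the solid
  is additionally fixed on the bottom face to remove rigid-body modes.

## Scenarios, parameters and defaults

`benchmark_scenario()` reproduces the validation experiment: 2 ml of cement
(Carreau $\mu_0 = 1930$, $\mu_\infty = 1.93$ Pa s, $\lambda_{rh} = 1.38$ s,
$n_{rh} = 0.30$) injected at 0.1 or 0.4 ml/s into air-filled
($1.8\times10^{-5}$ Pa s) aluminium foam (Lamé 28.2 / 54.7 GPa, porosity
0.92, $K^S = 2.1\times10^{-9}$ m², $\lambda_{bc} = 3$,
$R_{char} = 0.32$ mm). `clinical_scenario()` swaps in trabecular-bone
elasticity (3.85 / 5.77 GPa) and a marrow-filled pore space, Newtonian or
Carreau with plateau ratio $\mu_0/\mu_\infty = 10$, $\lambda_{rh} = 1$ s,
$n_{rh} = 0.5$.

The cement relaxation time and flow index are identified from two
(flow rate, pressure) observations on the syringe–nozzle–cannula assembly by
`fit_carreau_exponents()`, built on the shear-stress-integral formulation of
generalized-Newtonian pipe flow: with wall stress $\tau_w = \Delta p R/(2L)$,
$Q = (\pi R^3/\tau_w^3)\int_0^{\tau_w}\tau^2\dot\gamma(\tau)\,d\tau$, where
$\dot\gamma(\tau)$ inverts the monotone stress–shear relation. This is
mathematically equivalent to the closed-form (hypergeometric) solution but
avoids special-function edge cases; it reproduces Hagen–Poiseuille to
$10^{-10}$ and the power-law closed form to better than 1 %. The default
assembly geometry — 9.7 mm syringe barrel bore, a short taper-equivalent
nozzle, 3.2 mm × 100 mm cannula — is a documented, fully overridable stand-in
for dimensions that are only available as a drawing.

Cement curing is deliberately not modelled: over the few seconds of an
injection the curing-induced viscosity rise is negligible compared with
shear-thinning. Temperature effects, capillary pressure and fluid extra
stresses are likewise out of scope.

## Diagnostics

* **Injection force**: $F = (p_{in} + \Delta p_{assembly})\,\pi (d/2)^2$ with
  the plunger diameter $d$ defaulting to 9.7 mm; the assembly term can be
  excluded (`injection_force_foam` column) to isolate the porous-medium
  contribution.
* **Bulk effective viscosity**: volume-weighted median of the nodal effective
  viscosity over the region where the phase majority-occupies the pores
  ($s^C > 0.5$ for cement), excluding vertices within one cell of any
  boundary. Because this region keeps growing during an injection, its later
  readings are increasingly dominated by already-injected, quasi-stagnant
  cement relaxing to its zero-shear plateau; the post-thinning viscosity of
  the cement actually being driven through the pores is therefore read at
  the *onset of steady injection* — the earliest step at which the
  diagnostic region exists (`steady_bulk_viscosity()`). On the coarse
  benchmark-geometry mesh the cement diagnostic climbs from about 6 Pa s at
  onset to about 19 Pa s at the end of a clinical run for exactly this
  reason.
* **Front profile**: cement saturation along the horizontal line through the
  injection point, with a front-sharpness scalar (distance between the 0.9
  and 0.1 crossings; when a diffuse profile never reaches 0.9 the thresholds
  fall back to fractions of the profile maximum).

## What the scaled-down runs show — and what they do not

The shipped test suite and the acceptance script run the full physics on
reduced problem sizes chosen once: the graded benchmark mesh at 688 cells
(presets: 2540 "full", 688 "coarse", 200 "tiny"), base dt 0.25 s, complete
2-ml injections; resolved 100-cell columns for the one-dimensional oracles.
On these sizes the suite verifies exact constitutive identities, the tube-flow
limits, a $10^{-8}$-exact Darcy column, a Buckley–Leverett front within 5 %,
discrete mass conservation of the injected 2 ml to better than 0.5 %, and the
qualitative marrow-viscosity dichotomy: thin marrow gives a compact, fully
saturated front and a gradually rising force; marrow more viscous than the
shear-thinned cement gives an early force peak with subsequent decline, a
diffuse far-spreading front, and a front shape that becomes sensitive to the
pore-size uniformity $\lambda_{bc}$. A staircase mesh at these resolutions
cannot capture boundary-layer detail near the cannula or the fingering
instability itself (a macro-scale model has no pore-scale perturbations to
amplify), and passing these tests does not validate the model against
*in vivo* conditions — blood-vessel outflow, curing, temperature and
patient-specific geometry are all outside the model.

Two quantitative observations from the model are worth recording. First, the
computed maximum solid displacements (about $3\times10^{-9}$ m for the
aluminium benchmark and $2\times10^{-7}$ m for bone at the clinical
parameters) are self-consistent with the computed inlet pressures acting
against the skeleton stiffnesses, and confirm that the skeleton deformation
has no back-effect on the flow (a hundredfold stiffer skeleton changes the
fluid solution by well under 0.1 %); reported values of order $10^{-10}$ to
$10^{-9}$ m would require either far smaller pressures than the forces imply
or a pressure coupling scaled by the solid fraction. Second, the effective
cement viscosity is spatially uniform only where the cement is actively
flowing; the semi-empirical upscaling laws make it rise wherever the cement
stagnates, which is why the bulk diagnostic is defined at steady-injection
onset.

## A worked example

```{r example}
library(vertebropm)

cfg <- benchmark_scenario(flow_rate = 0.4, resolution = "coarse")
run <- run_scenario(cfg)
glance(run)        # one-row summary: final force, volumes, viscosities
tidy(run)          # full time series
autoplot(run)      # injection-force history

clin <- run_scenario(clinical_scenario(marrow = carreau_params(1000, 100, 1, 0.5)))
steady_bulk_viscosity(clin, "cement")
autoplot(front_profile(clin))
```
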