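---
title: "Modelling multi-probe cryoablation: bioheat transfer, phase change and damage kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multi-probe cryoablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryosim)
```

## The physical model

cryosim simulates the freezing of soft tissue around one or more needle
cryoprobes. The temperature field obeys the Pennes bioheat equation

$$\rho c \,\frac{\partial T}{\partial t}
  = \nabla\!\cdot\!\left(k \nabla T\right)
  + w_b \rho_b c_b \,(T_b - T) + Q_m ,$$

where $w_b \rho_b c_b (T_b - T)$ models heat exchange with arterial blood
and $Q_m$ is metabolic heat generation. An advection term
$\rho c\,\mathbf{u}\!\cdot\!\nabla T$ belongs to the general energy balance
but the bulk tissue velocity $\mathbf{u}$ is identically zero here (no
tissue motion, no flow field), so the term is inert.

Freezing is handled with the **effective heat capacity method**: instead of
tracking a sharp front, the latent heat $Q_{lf}$ of the water–ice transition
is spread over a *mushy* temperature interval $[T_{ml}, T_{mu}]$ in which
tissue is a solid–liquid mixture. All three thermophysical properties are
piecewise in temperature, with three branches (liquid above $T_{mu}$, solid
below $T_{ml}$, mushy between, endpoints inclusive to the mushy branch):

$$k(T) = \begin{cases} k_u & T > T_{mu}\\
 (k_u + k_f)/2 & T_{ml} \le T \le T_{mu}\\
 k_f & T < T_{ml}\end{cases}
 \qquad
 \rho c\,(T) = \begin{cases} \rho_u c_u \\
 \bar\rho\,\bar c + \dfrac{Q_{lf}}{T_{mu} - T_{ml}} \\
 \rho_f c_f \end{cases}$$

with $\bar\rho = (\rho_u+\rho_f)/2$, $\bar c = (c_u+c_f)/2$. The solver
works in *volumetric* heat capacity $\rho c$ (J m$^{-3}$ K$^{-1}$)
throughout, because the latent heat is tabulated volumetrically
(MJ m$^{-3}$); this sidesteps any per-mass/per-volume ambiguity, and
integrating the capacity across the mushy interval recovers the sensible
heat plus exactly $Q_{lf}$ (a unit test asserts this to machine precision).

The solid (frozen) fraction is a linear ramp across the mushy interval.
Only the interval itself is physically prescribed; the linear shape is the
one consistent with a constant effective capacity across the interval.

**Damage kinetics.** Injury is tracked by a raw accumulator $\alpha$ that
grows at rate $1/t_{dc}$ wherever $T < T_{dc}$, and the damage fraction is
$\theta_d = \min(\alpha, 1)$: a cell held continuously below the damage
threshold is fully damaged after exactly $t_{dc}$ seconds. Defaults:
$T_{dc} = -20$ °C, $t_{dc} = 60$ s, necrosis temperature
$T_{nc} = -50$ °C, damage enthalpy $L_{dc} = 250$ kJ kg$^{-1}$.

Two framework terms are represented but disabled by default, and the
reasons are worth recording:

* *Damage enthalpy source* ($\rho L_{dc}\,\partial\theta_d/\partial t$).
  Numerically $L_{dc} \times \rho \approx Q_{lf}$: enabling it alongside
  the effective-capacity latent heat would release the same latent heat
  twice. It is exposed as `apply_damage_enthalpy` for experimentation but
  latent heat enters once, through the capacity, by default.
* *Damage-weighted property mixing*
  ($k_{eff} = \theta_d k_d + (1-\theta_d)k$, likewise for $\rho C_p$).
  The damaged-phase constants $k_d, \rho_d, C_{p,d}$ are not tabulated
  anywhere in the source material, and in frozen tissue $\theta_d \to 1$
  regions are already assigned the frozen property column, so the mixing
  would be a no-op wherever it is well defined. Phase-based properties
  govern heat transfer; $\theta_d$ is bookkeeping. This keeps the model
  free of invented constants.

**Boundary conditions.** The actively cooled distal segment of each probe
is a hard Dirichlet boundary following a shared *load curve*; the outer
domain boundary and any non-cooled probe shaft are thermally insulated
(zero flux). Probe construction constants (nitinol, polyurethane) are
packaged as `probe_material_params()` for completeness, but shaft cells are
insulated rather than thermally resolved — the insulated treatment is the
one the source protocol states, and for the default geometry the whole
inserted segment is active so no shaft cells exist.

**Load curve.** The probe surface temperature is a three-segment
piecewise-linear cycle: ramp from `start_C` to `plateau_C` over `ramp_s`,
hold until `freeze_s`, thaw linearly to `thaw_C` over `thaw_s`. Defaults:
60 s ramp, −150 °C plateau, 900 s freeze. The plateau value is the single
most uncertain input of the whole model: it is taken from the typical
behaviour of 17-gauge argon Joule–Thomson probes, not from a printed
number, and every reproduction report in this package flags it. The ice
ball the model grows at −150 °C over 900 s is substantially larger than
bench measurements on tissue phantoms with comparable insertion depth
(about 2.9 cm axially × 3.4 cm transversally versus a reported
2.5 × 1.2 cm); a quasi-steady estimate of conduction through the frozen
shell shows the measured sizes imply a much weaker effective cold surface
than a full 2 cm segment at −150 °C. Because the plateau is a declared
study condition, it is *not* adjusted to fit; the discrepancy is reported
as-is wherever dimensions are compared.

## Discretization and the nonlinear solver

Space is discretized by a cell-centered finite-volume method on a uniform
grid — fully 3-D Cartesian, or axisymmetric $(r, z)$ for a single on-axis
probe (the axisymmetric geometry enters only through per-cell volumes
$2\pi r\,h^2$ and per-face area factors, so both modes share one kernel).
Face conductances use the harmonic mean of the adjacent cell
conductivities. Default spacing is 1 mm, finer than the mesh-independence
threshold established for the original finite-element model (2.4 mm),
because a finite-volume grid must also resolve the 0.85 mm probe radius.

Time stepping is backward Euler (default $\Delta t = 0.5$ s). Each step
solves the nonlinear enthalpy balance

$$\frac{V_i}{\Delta t}\left(H(T_i) - H(T_i^n)\right)
 = \sum_{f} G_f (T_j - T_i) + V_i\, s_i(T_i),$$

with $H$ the piecewise-linear volumetric enthalpy, by a damped Picard
iteration in *enthalpy-residual form*: the iteration matrix uses a
capacity $C^\star = \max(\text{chord}, \text{apparent})$, but the residual
keeps $H(T^{(m)}) - H(T^n)$ explicitly, so the fixpoint is the exact
nonlinear solution for any positive $C^\star$. Three safeguards matter in
practice, all prompted by the narrow-mushy-interval stress test against
the Stefan solution:

1. the chord capacity $(H(T^{(m)}) - H(T^n))/(T^{(m)} - T^n)$ conserves
   latent heat when a cell crosses the whole mushy interval in one step;
2. cells whose update direction alternates (bouncing across the interval)
   get persistent per-cell under-relaxation (halving);
3. after the loop, any cell still violating its own scalar enthalpy
   balance is finished by solving that balance *exactly* (it is monotone
   piecewise-linear in $T$, so the valid branch is found directly); such
   cells sit at the phase-change kink and are strongly diagonally
   dominant, which makes the lagged-neighbor scalar solve safe.

The linear systems are symmetric positive definite and are solved
matrix-free by Jacobi-preconditioned conjugate gradients (relative
tolerance $10^{-8}$). Because conductivity is piecewise constant, face
conductances are cached and rebuilt only when some cell changes phase
branch. The production path is compiled (Rcpp); a pure-R implementation of
the identical scheme ships as `method = "reference"` and the test suite
asserts the two agree to microkelvins. An explicit forward-Euler mode
(`method = "explicit"`, point capacity) exists for cross-checking and
refuses to run above its stability limit — with millimetre cells the limit
is milliseconds, which is why the implicit path is the default.

Picard stops when the iterate moves less than $10^{-3}$ °C (max-norm,
at most 40 iterations). An energy audit runs every step: the free-domain
enthalpy change is compared against the perfusion/metabolic source and the
heat extracted through probe-adjacent faces, normalised by the gross
energy turnover of the step. Insulated source-free configurations close
this budget at the linear-solver tolerance; probe-driven freezing runs
close it within the Picard truncation budget (≤ 1 %).

Perfusion and metabolism are scaled by the *unfrozen* fraction by default
(`frozen_shutdown`): frozen tissue neither perfuses nor metabolises. The
unscaled strict form is available for comparison. The perfusion term is
treated implicitly (it adds to the diagonal), which is unconditionally
stable.

## Verification oracles

Because the original model was verified against third-party curves that
are not printed anywhere re-usable, verification here is *analytic*:

* **Two-phase Neumann/Stefan front.** For 1-D freezing of a half-space
  from a cold wall, the front position is $x(t) = 2\lambda\sqrt{\kappa_f t}$
  with $\lambda$ the root of the classical transcendental equation; the
  root is found by bracketed `uniroot` to $10^{-10}$ and independently
  confirmed by a residual sign-scan in the tests. The solver, run pseudo-1-D
  with the mushy interval collapsed to 0.2 °C and perfusion off, must land
  within 2 % of the analytic front at $t = 600$ s (it does, at −1.5 %,
  and the error is grid-stable between 1.0 and 0.5 mm spacing).
* **Lumped perfusion relaxation.** With $k \to 0$ the Pennes equation is a
  scalar ODE with exact solution
  $T(t) = T_{ss} + (T_0 - T_{ss})e^{-w_b\rho_b c_b t/\rho c}$,
  $T_{ss} = T_b + Q_m/(w_b \rho_b c_b) \approx 39.33$ °C for the packaged
  constants. The solver tracks it within 0.05 °C at all output times.
* **Grid convergence.** `run_grid_convergence()` reruns a reduced
  single-probe scenario across a descending spacing ladder
  (2.4 → 1.2 → 0.6 mm) and reports the temperature 5 mm axially beyond the
  probe tip; successive refinement differences must shrink monotonically.
  For this study the probe radius must be resolvable at the *coarsest*
  spacing (the packaged check uses 2.5 mm): a sub-cell probe is rasterized
  to a different effective radius on every grid, and the monitor then sees
  geometry changes rather than discretization error — the finite-element
  analogue refines a fixed body-fitted geometry, which a voxel grid can
  only imitate when the cylinder spans at least one cell.
  The monitor sits axially beyond the tip (the in-plane alternative is not
  distinguishable from the source description; the axial convention is
  fixed and documented here).

## Morphometrics

The *ice ball* is the region at or below 0 °C (the explicit reporting
convention of the study; the mushy-zone onset −1 °C is also available as a
level). The *lethal zone* is reported at −40 °C — the threshold the
results section uses — while the methods define necrosis at −50 °C; the
package computes metrics at 0, −20, −40 and −50 °C by default precisely to
expose that internal inconsistency rather than hide it.

The isotherm surface is represented by sub-cell crossing points obtained
by linear interpolation along grid lines (the vertex set a marching-cubes
triangulation would use). Extents are caliper-style: the longitudinal
extent is the span of the largest 6-connected component along the probe
axis; the transverse extent is the maximum support-function width over all
perpendicular directions (computed from the 2-D convex hull of the
projected surface points). Volumes are integrated column-wise with
sub-cell interpolation; a voxel-count volume is reported alongside.
Components touching the domain boundary are flagged `boundary_clipped`
(for probes inserted through the top surface the flag is routinely set by
the entry plane itself).

The *warm zone* — tissue inside the composite ice ball that stays above
the lethal threshold, the clinically dangerous pocket of a multi-probe
array — is measured inside the convex hull of the 0 °C region taken
slice-by-slice perpendicular to the probe axis. For parallel vertical
probes every interstitial pocket lies in-slice, so the slice-wise hull is
an exact reduction of the 3-D construction while remaining dependency-free
and robust; it additionally counts the sub-lethal peripheral shell
(between the −40 °C and 0 °C surfaces) that any hull-based definition
includes.

With the default −150 °C plateau held for 900 s, interstitial pockets are
erased within minutes of fusion and the warm-zone volume becomes
shell-dominated — it then *grows* with probe count because larger
composite balls have larger peripheral shells. The qualitative layout
ranking reported for weaker effective probes (warm zones largest for five,
smallest for nine) is therefore not reproduced under the packaged load
curve, while the companion claim (−40 °C coverage maximal for the
nine-probe matrix) is. Both are asserted as stated in the acceptance
suite, and the failing direction is documented rather than re-tuned.

## Scenario presets and problem sizes

Presets: `phantom-single`, `phantom-five`, `phantom-seven`,
`phantom-nine` (bench conditions, 25 °C initial) and `liver-nine`
(core temperature, 37 °C). All use 2 cm insertion, 1 cm spacing for
multi-probe patterns, a 900 s freeze, and the four-channel monitor layout
(at the main probe, 5 mm from it, at an auxiliary probe, at a distal
reference) sampled at 1 Hz.

The test and verification suites run deliberately reduced problems chosen
to exercise every code path at desk scale: the single-probe reproduction
runs axisymmetrically at 1 mm on a 4 × 8 cm half-plane (3 200 cells,
900 s); the nine-probe merge study runs at 1.5 mm on a 7 × 7 × 6 cm block
(~88 000 cells); layout-ranking runs use 1.5 mm on 9.75 × 9.75 × 6 cm
(~169 000 cells, $\Delta t = 2$ s). The synthetic fields used by the
morphometrics tests (spheres, ellipsoids, pocketed shells) are analytic
level sets, which is what makes their expected values exact; they do not
emulate the irregular, heterogeneous isotherms of real tissue, so passing
them demonstrates correctness of the measurement operators, not realism of
the fields being measured.

## Known limitations

* The load-curve plateau is an assumption (see above); absolute ice-ball
  dimensions inherit its uncertainty wholesale.
* Homogeneous, isotropic tissue; no vasculature or heat-sink effect, no
  porous-media perfusion coupling.
* The damage model is a threshold/time law; it does not represent the
  graded time–temperature dose response or the diffuse histological
  transition zone observed in real tissue.
* Single freeze–thaw cycle per run (the load curve has one thaw ramp).
* Probe trajectories are vertical and parallel; bent or angled insertions
  are out of scope.
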