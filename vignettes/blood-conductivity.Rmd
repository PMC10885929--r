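---
title: "Anisotropic blood conductivity from velocity fields: models, parameters and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anisotropic blood conductivity from velocity fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemocond)
```

## What the package models

Blood conducts electricity through its plasma; red blood cells (RBCs) are
essentially insulating at the frequencies used in bioimpedance
measurements. Because RBCs are flat (oblate) rather than spherical, the
conductivity of whole blood depends not only on how many cells there are
(the hematocrit) but on how they are *oriented* — and orientation is set by
the local flow. At low shear the cells tumble and the orientation
distribution is random; with increasing shear an increasing fraction
settles into tank-treading motion, a steady orientation in which the
membrane circulates around the cytoplasm and the short (symmetry) axis of
the cell points away from the flow. Blood in shear is therefore a
transversely isotropic conductor, and this package computes the full
conductivity tensor field from a velocity field:

$$\sigma = \sigma_\alpha\, (e_\alpha \otimes e_\alpha)
         + \sigma_\beta\, (I - e_\alpha \otimes e_\alpha),$$

where $e_\alpha$ is the dominant direction of the RBC short axis,
$\sigma_\alpha$ the principal conductivity along it and $\sigma_\beta$
(twice degenerate) transverse to it.

Two ingredients are needed per grid point: the *axis* $e_\alpha$ and the
*principal values* $(\sigma_\alpha, \sigma_\beta)$.

## The two orientation models

Experiments on tank-treading RBCs support two readings of "where the short
axis points", which coincide in unidirectional shear (Couette, Poiseuille)
but not in general 3D flow:

**Eigenvector (EV) model.** The cell's flat face lies in a plane of
maximum shear stress. With the Newtonian stress
$\tau = 2\eta_{bl} D$, $D = \tfrac12(\nabla u + \nabla u^T)$, and its
spectrum $\tau_1 \ge \tau_2 \ge \tau_3$ (eigenvectors $e_1, e_2, e_3$),
the two maximum-shear-plane normals are the diagonals
$(e_1 \pm e_3)/\sqrt2$. The model selects the normal of the plane that
(mostly) contains the velocity — equivalently, the candidate making the
*larger* angle with $u$:

$$e_\alpha^{EV} =
\begin{cases}
(e_1 - e_3)/\sqrt2 & \text{if } |\langle u, (e_1+e_3)/\sqrt2\rangle| >
                     |\langle u, (e_1-e_3)/\sqrt2\rangle| \\
(e_1 + e_3)/\sqrt2 & \text{otherwise.}
\end{cases}$$

**Velocity–vorticity (VV) model.** The long axes lie along the flow and
the vorticity, so the short axis is the normalised Lamb vector
$e_\alpha^{VV} = u \times \omega / |u \times \omega|$, $\omega = \nabla
\times u$.

Both are implemented per point (`eigenvector_axis()`, `lamb_axis()`) and
over whole grids (`conductivity_field()`, with a compiled batch kernel for
the per-point $3\times3$ eigendecompositions).

## The Maxwell–Fricke chain for the principal values

The principal conductivities follow suspension theory for non-conducting
spheroids at volume fraction $H$ in plasma of conductivity
$\sigma_{pl}$:

$$\frac{\sigma_{\alpha,\beta}}{\sigma_{pl}}
  = \frac{1-H}{1 + (C_{\alpha,\beta}-1)H},$$

with orientation factors built from the shape of the *deformed* cell:

* deformation: $\lambda_d(\tau_{max}) = \lambda\,(1 + \tau_{max} b /
  4\mu)^{-3}$ — shear stress stretches the cell, lowering its aspect
  ratio;
* shape factor: $M(\lambda_d) = (\phi - \sin\phi\cos\phi)\cos\phi /
  \sin^3\phi$ with $\phi = \arccos\lambda_d$, rising to $2/3$ at the
  sphere;
* aligned factors $C_a = 1/M$, $C_b = 2/(2-M)$ and the random-orientation
  average $C_r = (C_a + 2C_b)/3$;
* alignment: the tank-treading fraction $f(\dot\gamma_{max}) =
  \dot\gamma_{max} / (\dot\gamma_{max} + k\sqrt{\dot\gamma_{max}})$
  interpolates $C_{\alpha,\beta} = f\,C_{a,b} + (1-f)\,C_r$.

Stress and shear rate are redundant through the constitutive law
($\dot\gamma_{max} = \tau_{max}/2\eta_{bl}$); `shear_state()` derives one
from the other and refuses inconsistent pairs (relative mismatch over
1e-6), so the deformation (stress-driven) and alignment (rate-driven)
halves of the chain can never be fed contradictory states.
`fricke_chain()` exposes every intermediate. At zero shear
$f = 0$ and both conductivities equal the random-orientation value
(stationary blood, 0.549 S/m at defaults); the ratio
$\lambda_\sigma = \sigma_\alpha/\sigma_\beta$ decreases monotonically with
shear rate.

```{r chain}
fricke_chain(c(0, 1.9, 16), blood_params())[, c("gamma_dot_max", "lambda_d",
                                                "f", "sigma_alpha",
                                                "sigma_beta", "lambda_sigma")]
```

## Parameters, units and one deliberate override

All parameters are strict SI, carried by `blood_params()`:

| parameter | default | unit | meaning |
|---|---|---|---|
| `lambda` | 0.38 | – | undeformed RBC aspect ratio $a/b$ (oblate) |
| `sigma_pl` | 1.3 | S/m | plasma conductivity |
| `hematocrit` | 0.45 | – | RBC volume fraction |
| `a`, `b` | 1.52e-6, 4e-6 | m | short / long semiaxes |
| `mu` | 1e-5 | kg/s² | membrane shear modulus (deformability) |
| `k` | 1 | s^(-1/2) | orientation constant of the alignment law |
| `eta_pl` | 4.8e-2 | kg/(m s) | plasma dynamic viscosity (Merrill input) |
| `rho_bl` | 1060 | kg/m³ | blood density |
| `eta_bl_override` | 0.048654 | kg/(m s) | effective blood viscosity (see below) |

**The viscosity override.** The Merrill relation
$\eta_{bl} = \eta_{pl}(1 + 2.5H + 7.32H^2)$ applied to
`eta_pl = 4.8e-2` gives $\eta_{bl} = 0.173$ kg/(m s) and a kinematic
viscosity of 1.63e-4 m²/s — but the benchmark flow cases and the
conductivity-ratio results this package reproduces are built on
$\nu_{bl} = 4.59\times10^{-5}$ m²/s. The two are irreconcilable: either
the tabulated plasma viscosity or the kinematic viscosity is off by a
factor ≈ 3.6 (a plausible culprit is a plasma viscosity of ≈ 1.35e-2
being inflated to 4.8e-2 somewhere upstream). We resolve the conflict in
favour of the kinematic viscosity, because every downstream number
(Reynolds numbers 6.97 and 11.50, the ratio $\lambda_\sigma(1.9\,{\rm
s^{-1}}) = 0.77$) is consistent with it: `blood_params()` carries
`eta_bl_override = 1060 * 4.59e-5` and `eta_bl()` uses it everywhere
stresses and shear rates are interconverted. Setting
`eta_bl_override = NULL` restores the literal Merrill value.

**Shear-rate regimes.** "Low" and "high" shear are defined through the
aligned fraction, not through fixed rates: $f < 0.2$ is low, $f > 0.8$
high. With $k = 1$ these boundaries sit at 0.0625 and 16 s⁻¹
(`alignment_shear_rate()`, `classify_shear_rate()`); for other $k$ they
move with the law.

## Model disagreement metrics

`compare_models()` runs both models on one flow and reports per point the
axis angle $\psi_\alpha = \arccos|\langle e^{EV}_\alpha,
e^{VV}_\alpha\rangle|$ and the tensor angle $\psi_\sigma$ (Frobenius inner
product). Because both tensors share $(\sigma_\alpha, \sigma_\beta)$, the
two angles are linked exactly:

$$\cos\psi_\sigma = \frac{\lambda_\sigma^2\cos^2\psi_\alpha
  + 2\lambda_\sigma(1-\cos^2\psi_\alpha) + 1 + \cos^2\psi_\alpha}
  {\lambda_\sigma^2 + 2}.$$

$\psi_\sigma \le \psi_\alpha$ always: weak anisotropy (ratio near 1)
mends even orthogonal axis disagreement. At the chain's ratio for
$\dot\gamma_{max} = 1.9$ s⁻¹ ($\lambda_\sigma \approx 0.77$) the
worst-case tensor angle is

```{r bound}
psi_sigma_closed_form(0.77, 90)
```

## Benchmark flows and the synthetic generators

* **`poiseuille_pipe()`** — the straight rigid vessel,
  $u_z(r) = 2\bar u(1 - (2r/D)^2)$ along $+z$, analytic gradient, no-slip
  wall, points outside the lumen masked (`in_domain = FALSE`). Here both
  models provably coincide (axes radial), $\sigma_\beta$ peaks and
  $\sigma_\alpha$ dips at the wall, and the anisotropy indicator
  $\eta = (\sigma_\beta - \sigma_\alpha)/(2\sigma_\beta + \sigma_\alpha)$
  grows monotonically from the centreline. The default benchmark case is
  $D = 0.04$ m, $\bar u = 0.008$ m/s (Re ≈ 6.97, wall shear rate
  $8\bar u/D = 1.6$ s⁻¹).

* **`swirling_pipe()`** — the in-package flow in which the models
  *disagree*. Design note: a pure solid-body swirl $u_\theta = \Omega r$
  does not work for this purpose. For any axisymmetric
  $u = u_\theta(r)e_\theta + u_z(r)e_z$, the stress shear vector lies in
  the $(\theta, z)$ plane, so the EV selection rule always returns the
  radial candidate, while $u \times \omega$ is algebraically radial too —
  both axes stay radial and $\psi_\alpha \equiv 0$ (solid-body rotation
  additionally has zero strain rate, leaving the stress untouched). The
  generator therefore modulates the swirl axially,
  $u_\theta(r, z) = \Omega r (1 - (2r/D)^2)\cos(2\pi z/L)$: still exactly
  divergence-free and no-slip, reducing continuously to Poiseuille at
  $\Omega = 0$, with core vorticity $(0, 0, 2\Omega)$ at the origin — but
  now $\partial u_\theta/\partial z$ gives the vorticity a radial
  component and the two axes genuinely separate (tens of degrees at
  $\Omega$ of a few s⁻¹), emulating the secondary-flow regions of curved
  vessels at desk scale.

* **`random_solenoidal_field()`** — the curl of a random trigonometric
  vector potential: exactly divergence-free, smooth, seeded, with analytic
  gradients; used for property testing (frame equivariance, finite
  difference convergence).

What these generators do *not* emulate: real aortic geometry and its
boundary layers, pulsatility, non-Newtonian rheology, or cell-scale
physics. Passing tests on them demonstrates correctness of the
*postprocessing map* from velocity to conductivity, not validity of the
models against measurements — the models' experimental validation is an
open question, and full-geometry comparisons (bend flows with
$\psi_\alpha$ up to ~85°) require a CFD solution that is out of scope
here.

## Numerical choices

* **Eigendecomposition.** Grid sweeps run through a compiled
  RcppArmadillo kernel (`eig_sym` per point); the single-point R functions
  use `base::eigen`. The two routes are cross-checked in the tests.
* **Sign convention.** Eigenvectors and orientation axes are defined up
  to sign; every reported axis is flipped so its first component exceeding
  1e-12 of the norm is positive. The tensor is sign-invariant, the
  convention only makes output reproducible.
* **Ties in the EV rule.** Exact ties (velocity orthogonal to both
  candidate normals, e.g. $u \parallel e_2$) take the "otherwise" branch,
  as the selection rule is written. Such points arise at pipe walls where
  $u \to 0$; they are boundary artifacts of the rule, not of the
  implementation.
* **Degeneracies are flags, not errors.** `zero-stress`
  ($\tau_{max} < \varepsilon_\tau$, default 1e-12 Pa),
  `repeated-eigenvalue` (extreme pair closer than 1e-9 of the spectrum
  norm — the axis is still computed when $\tau_1 - \tau_3$ itself is
  separated, since only $e_1$ and $e_3$ enter), `parallel-u-omega`
  ($|u\times\omega| < \varepsilon_L |u||\omega|$, default 1e-8) and
  `zero-velocity`. Degenerate points fall back to the isotropic
  random-orientation conductivity $\sigma_r(\tau_{max})$ — the continuous
  limit, since the aligned fraction vanishes with shear — and are excluded
  from angle statistics (counted instead). For VV-degenerate points at
  finite stress, `vv_fallback = "ev"` borrows the EV axis instead of
  isotropising; the flag stays either way.
* **Angles.** Naive $\arccos$ of a clamped inner product cannot resolve
  angles below ≈ 2e-6 degrees (its derivative diverges at 1). Axis angles
  are therefore evaluated as $\mathrm{atan2}(\|e_1 \times e_2\|,
  |\langle e_1, e_2\rangle|)$ and tensor angles through the chord form
  $2\arcsin(\|\hat A - \hat B\|_F/2)$; the closed-form relation is
  rearranged to $\sin(\psi_\sigma/2) = \sin\psi_\alpha\,(1 -
  \lambda_\sigma)/\sqrt{2(\lambda_\sigma^2+2)}$. All three are
  algebraically identical to their arccos definitions and accurate to
  machine precision near zero — which is what makes "the two models
  coincide on the pipe" testable at 1e-6 degrees rather than asserting
  against a resolution floor.
* **Sphere limit.** $M(\lambda)$ has a removable 0/0 at $\lambda = 1$;
  for $\lambda > 1 - 10^{-6}$ the series limit $2/3$ is returned exactly.
* **Incompressibility.** $\mathrm{trace}(\nabla u)$ is monitored; fields
  exceeding $10^{-6}\|\nabla u\|$ warn. The analytic generators achieve
  $< 10^{-12}$.
* **Finite differences.** Second-order central stencils (one-sided at
  boundaries) on possibly non-uniform monotone axes; exact for per-axis
  quadratics, order-2 convergent on smooth fields. Analytic gradient
  closures, when a generator provides them, take precedence.
* **Serialisation.** CSV is the archival format: doubles are written with
  17 significant digits and parsed back with base R's correctly rounded
  reader, giving bit-exact round trips. The legacy-VTK writer/reader
  covers the ASCII `STRUCTURED_POINTS` dialect with a `VECTORS velocity` /
  `TENSORS conductivity` attribute for visualisation toolchains.

## Problem sizes

The test suite exercises grids from 5³ to 17³; the straight-vessel
benchmark property runs on a 65³ grid (≈ 275k points, a few seconds
through the compiled kernel). These sizes were chosen as the smallest at
which the asserted properties (radial axes, monotone anisotropy profile,
wall extremes, order-2 convergence) are unambiguous.

## Known limitations

* Oblate-spheroid RBCs: tank-treading cells are really triaxial, which
  would split $\sigma_\beta$ into two distinct transverse values.
* Constant hematocrit: no cell migration or plasma skimming.
* Newtonian rheology with an isotropic viscosity, although aligned cells
  should strictly make viscosity anisotropic too; the conductivity models
  take hemodynamics as input and feed nothing back.
* Steady-state pointwise mapping: no orientation relaxation dynamics, no
  Jeffery-orbit tumbling model.
* The Navier–Stokes equations are not solved here; velocity fields are
  analytic or imported from external CFD output.
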