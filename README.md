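# hemocond

Anisotropic electrical conductivity of flowing blood, computed pointwise
from a 3D velocity field.

## The problem

Bioimpedance methods (impedance cardiography and plethysmography) sense the
electrical conductivity of blood, which changes with the flow: red blood
cells (RBCs) are non-conducting oblate spheroids that deform and align in
shear. In the tank-treading regime the cell keeps a steady orientation with
its short axis normal to the plane that carries the local shear, so current
passes more easily along the flow than across it and the conductivity
becomes a *tensor* field tied to the local hemodynamics. Classical
treatments handle only unidirectional pipe or channel flow; `hemocond`
implements two models that extend the picture to arbitrary 3D flows, for
people building CFD-driven bioimpedance simulations or studying how flow
disturbances show up in impedance signals.

## The models

Both models take the pointwise velocity gradient ∇u, form the Newtonian
viscous stress τ = 2η\_bl D with D = (∇u + ∇uᵀ)/2, and decompose it:
τ₁ ≥ τ₂ ≥ τ₃ with eigenvectors e₁, e₂, e₃. The maximum shear stress is
τ\_max = τ₁ − τ₃ and the maximum shear rate γ̇\_max = τ\_max / (2η\_bl).
They differ in the direction e\_α assigned to the dominant RBC short axis:

- **EV (eigenvector) model** — e\_α is the normal of the maximum-shear
  plane that (mostly) contains the velocity: (e₁ − e₃)/√2 if
  |⟨u, (e₁ + e₃)/√2⟩| > |⟨u, (e₁ − e₃)/√2⟩|, else (e₁ + e₃)/√2.
- **VV (velocity–vorticity) model** — e\_α = u × ω / |u × ω|, the
  normalised Lamb vector, with ω = ∇ × u.

The two principal conductivities come from Maxwell–Fricke suspension
theory with shear-dependent deformation and alignment: the deformed aspect
ratio λ\_d = λ (1 + τ\_max b / 4μ)⁻³ sets the shape factor M(λ\_d) and the
orientation factors C\_a = 1/M, C\_b = 2/(2 − M), C\_r = (C\_a + 2C\_b)/3;
the aligned fraction f = γ̇ / (γ̇ + k√γ̇) interpolates
C\_{α,β} = f C\_{a,b} + (1 − f) C\_r; and

σ\_{α,β} = σ\_pl (1 − H) / (1 + (C\_{α,β} − 1) H),

with plasma conductivity σ\_pl and hematocrit H. The tensor is
σ = σ\_α (e\_α ⊗ e\_α) + σ\_β (I − e\_α ⊗ e\_α). Model disagreement is
measured by the axis angle ψ\_α = arccos|⟨e\_α^EV, e\_α^VV⟩| and the
Frobenius tensor angle ψ\_σ, linked in closed form through the ratio
λ\_σ = σ\_α/σ\_β.

## Worked example

```r
library(hemocond)
params <- blood_params()

# scalar chain at the benchmark maximum shear rate 1.9 1/s
fricke_chain(1.9, params)[, c("lambda_d", "f", "sigma_alpha", "sigma_beta", "lambda_sigma")]
#>   lambda_d     f sigma_alpha sigma_beta lambda_sigma
#> 1    0.360 0.580       0.461      0.599        0.770

# straight rigid vessel (D = 0.04 m, mean velocity 0.008 m/s)
pipe <- poiseuille_pipe(pipe_spec(diameter = 0.04, u_mean = 0.008), n = 33)
cond <- conductivity_field(pipe, params, model = "EV")
glance(cond)
#>   model n_points n_domain n_degenerate gamma_dot_max sigma_alpha_min sigma_beta_max eta_aniso_max
#> 1 EV       35937    26301           33           1.6           0.465          0.597        0.0795

# a flow in which the two models disagree
cmp <- compare_models(swirling_pipe(pipe_spec(0.04, 0.008, swirl_rate = 2), n = 17), params)
glance(cmp)[, c("psi_alpha_max", "psi_sigma_max", "lambda_sigma_min", "psi_sigma_bound")]
#>   psi_alpha_max psi_sigma_max lambda_sigma_min psi_sigma_bound
#> 1          87.6          11.8            0.720            14.3
```

Reading the numbers: RBCs at γ̇\_max = 1.9 s⁻¹ are 58% aligned and deformed
from aspect ratio 0.38 to 0.36; the radial conductivity σ\_α drops to
0.461 S/m while the transverse σ\_β rises to 0.599 S/m (ratio 0.77). In
the straight vessel the wall shear rate is 8ū/D = 1.6 s⁻¹, the anisotropy
indicator η = (σ\_β − σ\_α)/(2σ\_β + σ\_α) peaks near the wall, and the 33
degenerate points are the zero-shear centreline (isotropic fallback). In
the swirling pipe the model axes disagree by up to ~88°, yet the tensors
differ by ≤ ~12° — anisotropy is weak where the axes disagree most.

A command-line wrapper is installed at `inst/scripts/hemocond`
(subcommands `params`, `fixtures`, `compute`, `compare`, `demo-pipe`,
`demo-aorta-bound`).

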