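---
title: "maskflow: models, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{maskflow: models, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(maskflow)
```

maskflow predicts how far sneeze droplets travel with and without a face
mask by chaining two models: a pore-scale model of the mask's nonwoven
filter media, and a room-scale Lagrangian model of the droplet cloud. This
vignette explains both models, the parameters that matter, the numerical
choices behind them, and — importantly — what the synthetic webs do *not*
capture about real mask materials.

# The micro scale: virtual webs, Stokes flow, capture

## Fiber-web generator

A nonwoven layer is described by a `fiber_layer_spec`: mean fiber diameter
(µm), solidity (solid volume fraction), thickness (µm) and an in-plane
orientation anisotropy. `generate_layer()` lays straight cylindrical
fibers with random in-plane orientation at random depths into a laterally
periodic voxel box until the occupied-voxel fraction reaches the target
solidity within ±0.01; near the target it shortens chords and paints them
in small increments so the tolerance is met regardless of overlap noise.
Fibers are straight and unbonded — adequate for Stokes-flow and capture
statistics, which feel the local fiber density and diameter far more than
crimp. Like a real spunbond or meltblown, the resulting web is a stack of
nearly planar fiber mats.

Defaults: spunbond d_f = 12 µm, meltblown d_f = 3 µm, both with 10%
diameter scatter. The spunbond default is at the fine end of the process
range; it is chosen so that the measured 9.3% single-layer efficiency is
reachable by solidity calibration *inside* the (0, 0.3) solidity domain in
which the layer capture model (and its analytic cross-check) is valid —
with 20 µm fibers the calibration pegs at solidity ≈ 0.34, outside that
domain. Solidity itself is not a free choice: it is the calibration handle
(below).

Mask media: Type A = two 250 µm spunbond layers (0.5 mm total); Type B =
spunbond / meltblown / spunbond with a 470 µm middle layer (0.97 mm
total). Only the totals are constrained by the reference thicknesses; the
middle-layer share follows from keeping the outer layers at 250 µm.

## Stokes solver

Air moves through the pores at Reynolds numbers far below one, so the
momentum balance reduces to the Stokes equations. `solve_stokes()`
discretizes them on a marker-and-cell staggered grid over the voxel
lattice: velocity unknowns live on faces between two fluid cells, faces
touching solid carry zero normal velocity, and tangential stencil legs
ending in solid use a half-cell wall ghost implementing no-slip or, when a
`slip_length` is set, first-order Navier slip (which strictly lowers the
pressure drop, as expected for small fibers). The web is padded with empty
slabs upstream and downstream; a uniform axial velocity is prescribed on
both padded ends (the padding makes the outflow profile uniform to solver
tolerance, standing in for a zero-gradient condition), and the lateral
directions are periodic. The saddle-point system is reduced to its
pressure Schur complement, solved by conjugate gradients with the three
viscous blocks factorized once by sparse Cholesky (CHOLMOD). The
divergence residual is driven below 10⁻⁶, which makes the plane-averaged
axial velocity constant through the stack (discrete mass conservation) and
the computed permeability independent of face velocity to better than 1%.

Pressure drops are read between the planes immediately bounding the web,
not at the Dirichlet ends, so the prescribed plug profile does not
contaminate the reading. Verification: the interior pressure gradient in a
plane-channel fixture matches the Poiseuille closed form to 0.5%, and a
square array of aligned cylinders reproduces the Kuwabara-cell
permeability within the 30% appropriate for a voxelized cylinder.

## Representative slabs and depth scaling

Resolving a full Type B stack (970 µm at sub-µm voxels) is beyond desk
scale. Each layer is instead represented by a laterally periodic slab at
full fiber resolution — voxel size d_f/4, lateral extent 6 d_f, slab
thickness 16 d_f (capped at the layer thickness) — and its pressure drop
scales linearly in thickness (Darcy) while its penetration scales
log-linearly (homogeneous depth filtration, P_layer = P_slab^(t/t_slab)).
Layers then compose in series (ΔP adds) and product (P multiplies). The
16 d_f slab thickness matters: with a 6 d_f slab the depth-scaling
exponent for the meltblown layer is ~25 and slab-realization noise made
the scaled layer efficiency swing between 0.5 and 0.97; at 16 d_f the
exponent drops to ~10 and two averaged realizations give sub-percent
reproducibility at the calibration target. Final results average
`n_realizations = 2` independent webs.

## Capture tracking and calibration

`track_particles()` advances particles (NaCl density 2650 kg/m³ for the
filtration test) through the frozen flow field with slip-corrected
Stokes-drag inertia, gravity along the flow axis, and Brownian
displacements from the Stokes–Einstein diffusivity; every sub-step is kept
below one voxel. A particle is captured when its surface touches the solid
phase — the centre comes within d_p/2 of the voxelized fiber surface,
evaluated by trilinear interpolation of an exact Euclidean distance
transform — and penetrates when it crosses the downstream face. Counts
conserve exactly and identical seeds reproduce counts bit-for-bit. The
classical Kuwabara single-fiber model (diffusion + interception +
impaction with the log-penetration depth law) is kept as an independent
analytic cross-check; tracked and analytic layer efficiencies agree within
a factor of two across 0.4–5 µm, usually much closer.

`calibrate_layer()` adjusts a layer's solidity until the simulated
efficiency at the 0.6 µm test size matches the measured value (9.3% or
95.0%) within ±1 percentage point, in at most 12 evaluations. Because the
evaluator is a stochastic simulation, a plain bisection can be derailed by
a single noisy draw; the search instead brackets once and then iterates a
weighted regression on the depth-filtration transform log(−log(1−E)) vs
log(solidity), which is nearly linear and uses every evaluation. Web
realization wiggle between solidity iterates (~1 pp at this domain size)
means the ±1 pp target cannot be guaranteed on every seed within the
budget; on exhaustion the best iterate is returned with a warning (a hard
error is reserved for genuine bracket failures). The evaluator averages
the same realization seeds used for the final curves, so the calibrated
efficiency and the downstream penetration curve agree to binomial noise.

# The micro→macro bridge: the mask model

A `mask_model` carries the stack penetration curve, the Darcy permeability
and thickness, an effective filter area (150 cm², a typical adult mask),
and three leak ports (nose gap venting 60° upward from the forward axis;
cheek gaps venting laterally with a 20° downward tilt; areas in 2:1:1
ratio, discharge coefficient 0.61). At every instant of the exhalation a
common driving pressure satisfies Darcy flow through the media and orifice
flow through the gaps; the closed-form split defines the instantaneous and
0.4 s-average leakage rate, and `calibrate_ports()` scales the gap areas
until the average matches the 11% (KF94-class fit) or 25% (KF80-class)
target within ±0.5 pp.

`transmit()` routes each injected droplet to the filter or a gap with
probability proportional to the instantaneous flow fractions, with one
physical amendment: reaching a gap requires following the sharp bend of
the leak path along the face, and bend impaction makes that turn
impossible for droplets whose momentum relaxation time exceeds a critical
Stokes number (defaults: turning time 2×10⁻⁴ s from a ~2 mm gap at ~10 m/s,
critical Stokes 0.25). Without this cutoff, occasional 100 µm-class
droplets exit the gaps at the orifice velocity and coast of order a metre
— contradicting the reference observation that forward transmission is
penetration-dominated and leaked droplets stay near the face. The literal
flow-fraction routing is available via `inertial_admission = FALSE`.
Filter-routed droplets survive with probability P(d) and exit forward at
the filter face velocity; gap survivors exit along the port direction at
the orifice velocity, capped at 10 m/s. Droplet counts and statistical
weights are conserved exactly.

# The macro scale: sneeze source, carrier flow, droplet dynamics

## Source

The sneeze profile rises piecewise-linearly to 4.5 m/s at 0.1 s and decays
to zero at 0.4 s (a half-sine option exists; the published profile is
graphical only). Droplets are sampled from a bimodal lognormal number
distribution truncated to 0.4–1500 µm: fine mode 12 µm (σ_g 1.8, weight
0.96), coarse mode 120 µm (σ_g 2.3, weight 0.04). The coarse σ_g is wider
than the fine mode deliberately: a 40 000-droplet sneeze should contain a
handful of millimetre-class droplets — the ones observed to travel
farthest — while ≥95% of droplets by number stay below 50 µm. Parcels
(default 5000; the scenario default is 2000) carry equal statistical
weights summing to 40 000; injection times follow the instantaneous flow
rate; initial velocity equals the air profile at the injection time; and
initial positions sit on a 4 cm² mouth disc at 1.60 m height (1.72 m
person).

## Carrier flow surrogate

The room-scale RANS problem is replaced by a parametric carrier flow:
each exhalation branch (mouth, filter face, or leak port) drives a
self-similar round jet with centreline decay constant B_j = 6, spreading
rate S = 0.11 and a Gaussian radial profile, its source modulated by the
exhalation profile with the shut-off front advected downstream at half the
peak exit speed (so the puff dies causally from behind); a uniform wind
vector is superposed (1.96 m/s for head/tail/side cases); and turbulent
dispersion enters as a per-droplet Ornstein–Uhlenbeck eddy velocity with
intensity 15% of the local mean jet speed and integral time 0.05 s. This
mean + fluctuation decomposition mirrors Reynolds averaging; the jet
constants are standard round-jet similarity values and absorb the fidelity
lost relative to a resolved turbulence model.

## Droplet dynamics

Each droplet (water, 1000 kg/m³ — the 2650 kg/m³ NaCl density belongs to
the filtration test only) obeys gravity + buoyancy and Schiller–Naumann
drag; added-mass and pressure-gradient forces are available behind flags
but default off, since the droplet/air density ratio (~830) makes them
negligible. The update is an exponential integrator over the
drag-corrected relaxation time (stable when the relaxation time is far
below the step) with trapezoidal positions; a 100 µm droplet settles at
the classical ~0.25 m/s terminal velocity within 2% of the independent
drag–gravity fixed point, and halving the step moves a reference
trajectory by under 1%.

Evaporation follows the Spalding law ṁ = −π d ρₐ D_v Sh ln(1+B) with the
Spalding number built from the saturation mass fraction at the droplet
surface and the ambient humidity (20 °C, 70% RH defaults), and the
Ranz–Marshall Sherwood number (exactly 2 for a quiescent droplet). The
published form of the transfer conductance divides by a "droplet mass
diffusivity", which is dimensionally inconsistent; interpreting that
symbol as the droplet diameter recovers the standard rate, verified
against the closed-form d²-law (linear d² decay to better than 1%; a
10 µm droplet fully evaporates in ~0.1 s at these conditions).
Condensation is clamped to zero. Droplet temperature is frozen by default
(`isothermal`), honouring the reference finding that the droplet
temperature change is below 1 °C; the full enthalpy balance
(convective heating minus latent-heat sink) is implemented and can be
switched on. A droplet is removed as fully evaporated below 1 µm (no
solid nucleus retained), deposited on reaching the floor (1.6 m below the
mouth) or the absorbing walls of the 8 × 8 × 4 m room.

Each droplet's maximum forward (x) and lateral (|y|) displacement while
liquid is recorded; the scenario result is the maximum over the
population and, at the scenario level, over an ensemble of 5 seeds
(population maxima are seed-sensitive; the per-seed spread is retained in
the result).

## Scenarios

`build_case(1..8)` reproduces the eight study configurations (no mask;
Type A/B × 11%/25% leakage in still air; Type B 11% under head, tail and
side wind). `run_case()` chains sampling → routing → dispersion;
`compare_cases()` tabulates maxima and percent reductions against the
unmasked baseline. Scenario configurations are pure data and the full
chain is seed-deterministic.

# Problem sizes

The shipped defaults — webs of 24×24 lateral voxels with 64-voxel slabs
(plus 8 padding slices), 1500–3000 tracked particles per size, two web
realizations, 2000 parcels per scenario seed and 5 seeds per scenario —
are the package's desk-scale operating point; they were chosen so a full
calibration-to-scenarios chain runs in minutes while keeping binomial and
realization noise at or below the tolerances quoted above. All of them are
exposed through `micro_control()` and the scenario configuration and can
be raised for production studies.

# What passing the tests does and does not show

The synthetic webs emulate fiber-scale geometry (diameter, solidity,
thickness, layered planar structure) and the transport physics of
mechanical filtration. They deliberately exclude electrostatic (electret)
capture, fiber crimp and bonding, filter loading, and droplet breakup.

The electret exclusion is not a small omission for this application, and
the package's own simulations quantify it. A purely mechanical web whose
single-layer efficiency at 0.6 µm is 9.3% at 0.1 m/s cannot have a quality
factor (−ln P / ΔP) above roughly 0.008 Pa⁻¹ — diffusion, interception and
impaction allow no more at that size — which caps the Type A permeability
near 4×10⁻¹¹ m², several-fold below the experimentally reported
1.54×10⁻¹⁰ m²; the reported pair of (efficiency, permeability) is only
consistent for charged media. Consequently the mechanically calibrated
webs are denser and draggier than the real ones: the computed
permeabilities come out a further order of magnitude below the reported
values, and the mechanically calibrated penetration curves are much
steeper with droplet size than electret curves (which keep up to ~10%
penetration out to ~4.5 µm). That steepness propagates to the masked
scenarios: forward transmission through the virtual masks is carried only
by the smallest droplets, which evaporate within centimetres, so the
masked and tail-wind distances land at the centimetre scale rather than
the reported 10–25 cm. The unmasked scenario, the distance *reductions*,
the leakage calibration and every transport-physics oracle are unaffected.

Other limitations: the carrier flow is a similarity surrogate, so
near-body aerodynamics (face shadowing, wake recirculation) are absent;
lateral distances inherit the jet-spreading and turbulence constants; the
masked forward maxima sit at millimetre-to-centimetre scale where
leak-jet turbulence noise can blur the Type A / Type B ordering on
individual seeds; and single-run population maxima remain stochastic even
with the 5-seed ensemble.
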