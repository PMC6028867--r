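---
title: "A micro-macro finite-element model of implant removal torque"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A micro-macro finite-element model of implant removal torque}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retorq)
```

## The model

Removal torque — the torque needed to break the fixation of a cylindrical
implant by rotation about its long axis — is the standard read-out of implant
anchorage tests. When a rough (for example acid-etched) titanium cylinder is
embedded in a polymer and twisted, retention comes from mechanical
interlocking between the surface asperities and the polymer imprint moulded
around them, and the torque response reflects fractures of the polymer
progressing down the implant side. `retorq` reproduces this process with a
two-scale model:

1. **Micro scale.** One periodic patch (*unit cell*) of the implant surface
   carries a single conical asperity whose dimensions are fitted to areal
   roughness parameters of the acid-etched surface. The embedding polymer is
   meshed with first-order hexahedra; the titanium feature is a rigid master
   surface, offset inward by a nanometre-scale interfacial gap that models
   incomplete contact. The feature is displaced tangentially in small
   increments; at each increment a frictionless unilateral contact problem
   is solved, every element whose von Mises stress has reached the polymer
   yield strength (40 MPa) is deleted, and the increment is re-solved until
   no further elements fail. The recorded output is the
   reaction-force-versus-displacement curve together with the fractured
   volume.

2. **Macro scale.** The embedded cylinder (diameter $d = 3$ mm, embedded
   length $L = 9$ mm, fixed at the bottom) is treated analytically as a
   torsion problem: the twist varies linearly from the applied top rotation
   $\Theta$ to zero at the bottom, so an axial layer with mid-height $z$
   above the bottom sees the tangential surface displacement
   $u(z) = r\,\Theta\, z/L$ with $r = d/2$. The block is divided into 20
   layers of 0.45 mm. The removal torque is the layer-wise summation
   $$T(\Theta) \;=\; \sum_{i=1}^{20} r\,
     \frac{\pi d\, h_\mathrm{layer}}{A_\mathrm{cell}}\,
     F\!\left(u(z_i)\right),$$
   where $F(u)$ is the micro reaction-force curve (linearly interpolated,
   held at its last value beyond the recorded range), $A_\mathrm{cell}$ the
   unit-cell footprint area, and each layer is evaluated at its mean height.
   Because deeper layers lag the top layer by a constant displacement
   difference, fracture progresses from the top of the implant to the
   bottom; the per-layer force contributions retained in every
   `torque_curve` make that ordering inspectable.

## The roughness-derived cone

The surface is characterised by three areal parameters: `Sa` (arithmetic
mean height deviation, 849 nm for the acid-etched surface), `Sdq`
(root-mean-square slope, expressed as its angle, 50°) and `Sdr` (developed
area excess, 40 %). For a cone of base radius $a$ and height $h$ centred in
the $w \times l$ cell, all three have closed forms. The cell-restricted cone
is exactly one period of a uniform lattice of identical cones (the nearest
apex always wins), so the base circle may legitimately overlap the cell
edges; the closed forms then acquire circular-segment terms, still exact.

Two findings shape the fitting interface:

* In the idealisation of a single cone per 3.15 × 6.3 µm cell, **no cone
  matches all three acid-etched parameters at once** (the brute-force search
  in the test suite documents this), and even the pair (Sa, Sdq) misses by about
  2 % — the maximum Sa attainable on the Sdq = 50° profile is 832.5 nm.
* `fit_cone()` therefore solves two-constraint modes exactly when a root
  exists and otherwise minimises the summed squared relative error of the
  named pair, with a warning. For the acid-etched targets this least-squares
  fit achieves Sa = 845.0 nm (−0.47 %) and Sdq = 50.42° (+0.84 %), with
  $a = 2.907$ µm and $h = 3.758$ µm (52.3° flank), and reports the achieved
  Sdr = 55.5 % alongside. The achieved triple is always reported — the
  approximation is explicit, never silent.

```{r fit}
fit <- fit_cone(roughness_spec(849, 50, 40), unit_cell())
tidy(fit)
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `elastic_modulus_gpa` | 3.76 | polymer Young's modulus (GPa) |
| `poisson_ratio` | 0.34 | polymer Poisson ratio |
| `yield_strength_mpa` | 40 | von Mises element-deletion threshold (MPa) |
| `gaps_nm` | 10, 50, 100, 150 | interfacial clearance sweep (nm) |
| `substrate_depth_um` | 6 | resolved polymer depth below the interface (µm) |
| `target_elem_size_um` | 0.4 | hexahedral element edge (µm), ≈ 1920 elements |
| `n_steps` | 30 | displacement increments |
| `total_displacement_um` | 0.6 | total tangential master displacement (µm) |
| `penalty_scale` | 100 | contact penalty = scale × E × element size |
| rotation grid | 0–1° by 0.001° | torque-curve abscissa |

Titanium grade IV constants (E = 113 GPa, ν = 0.32) are retained in the
configuration for a deformable-feature variant, but the tested default
treats the feature as rigid: the stiffness ratio of 30 makes the polymer
compliance dominant, and a rigid master halves the problem size.

### The displacement schedule

The per-increment displacement and the total sweep are free choices of the
bench protocol, so they are declared conventions and deserve
justification. A gap $g$ realised as a uniform normal clearance engages only
after a tangential slack of $g/\sin(\text{flank angle})$ — about 0.19 µm for
the 150 nm gap — and the rise of the reaction force to its fracture-capped
peak spans only a few hundredths of a micrometre beyond engagement (the
first-yield displacement scale is roughly the yield strain times the feature
size). Increments must therefore stay well below the element size, or the
recorded post-fracture samples alias the engagement phase and the gap sweep
ordering degenerates into sampling noise; at 30 × 0.02 µm the model's
orderings (peak force, fractured volume, and peak torque all strictly
decreasing with gap; top layer first past its peak) are clean and stable.
The total of 0.6 µm covers the engagement of every gap in the sweep plus the
decay of the force once the swept channel has fractured. The
six-increment schedule remains available (`micro.n_steps: 6`) and
is exercised in the test suite; it completes, but its coarse samples
under-resolve the transient. The rotation grid is 0.001° because the top
layer sweeps ≈ 0.26 µm of micro-curve abscissa per 0.01° — a coarser grid
misses the torque peak entirely.

## Numerical choices

* **Mesh.** Terrain-following structured hexahedra: node columns are graded
  between the pit surface $f(x,y) = \max(0, h(1 - r/a))$ and the substrate
  bottom. This is body-fitted (top nodes lie exactly on the imprint) and
  guarantees positive Jacobians; the refinement criterion is agreement of
  the FE volume with the design volume (< 1 % at the default size).
* **Contact.** Node-to-analytic-surface penalty with active-set iteration;
  the signed distance of the rigid master (base half-space plus cone row,
  periodic along the enforced direction to match the tied side faces) is
  exact on the polymer side. The penalty stiffness defaults to
  100 × E × element size and escalates tenfold if the penetration tolerance
  (10⁻³ × element size) cannot be met; the factorised stiffness is reused
  across contact iterations through a low-rank (Woodbury) update. Period-2
  active-set cycles, which arise at re-entrant corners of the fractured
  surface, are resolved by pinning the flickering nodes at zero gap.
  Reported contact forces are the converged linearised spring forces, so
  they satisfy global equilibrium to machine precision.
* **Constraints.** Bottom face fixed; side faces normal to the enforced
  direction tied pairwise (exact master–slave elimination — continuity, not
  a penalty); transverse faces fixed in their normal component only.
* **Element death.** Volume-averaged Gauss-point stress per element (the
  mesh-robust choice; max-over-Gauss-points is available), deletion
  criterion σ_vM ≥ 40 MPa, all offending elements deleted simultaneously
  per pass, passes repeated until quiescent. Nodes left without active
  elements, and debris islands with no load path to the support, are frozen
  to keep the operator definite; any stress the moving master builds in
  frozen debris deletes it through the ordinary criterion.
* **Units.** SI internally (m, Pa, N); µm, MPa, mN, N·mm at every
  interface.

## What the synthetic benchmark does and does not show

The packaged default profile emulates the acid-etched bench test: a single
cone per periodic cell, homogeneous isotropic polymer, frictionless
non-adhesive contact and binary element death. Passing tests show that the
solver chain (fit → mesh → contact → fracture → layer summation) implements
this idealisation correctly and that its qualitative predictions — gradual
force decay over the fracture transient, smaller forces, fractured volumes
and removal torques at larger interfacial gaps, loosening from the top layer
downwards — are robust at the tested resolutions. They do not show that a
real acid-etched topography (multi-scale, pits as well as peaks), adhesion
or friction, polymer plasticity before fracture, or bone-like anisotropic
viscoelastic media are captured; all are outside this model by design.

## Known limitations

* **Substrate-depth sensitivity.** In a displacement-driven periodic cell
  with a fully fixed bottom, the mean interfacial traction $F/A$ adds a
  uniform shear compliance $D/(GA)$ in series with the local contact
  stiffness, so the reaction force at a given master displacement depends on
  the resolved substrate depth $D$ whenever the transmitted force is
  appreciable — with the bench constants the series term is ~25 % of the
  total compliance at the force peak. A depth-doubling convergence check on
  the peak force therefore fails at any practical tolerance; the depth is a
  declared model parameter (default 6 µm), not a converged one. A traction
  or far-field-compensated driving protocol would remove this term, but
  would no longer be the stated protocol.
* **Coarse-mesh force tails.** After the fracture cascade the residual
  contact force is carried by whichever boundary elements barely survived;
  at ~2000 elements these tails are irregular at the 0.005 mN scale. The
  orderings reported above are carried by the resolved transient, not the
  tails.
* The absolute torque magnitudes depend on the declared displacement
  schedule; only their ordering and shape are meaningful claims of this
  implementation.

## Reproducing the numbers

Problem sizes used throughout the documentation and tests: 1920 elements
(0.4 µm target size), 30 increments of 0.02 µm, four gaps, 2048² roughness
rendering. A full default pipeline run takes a few minutes on one core:

```{r pipeline, eval = FALSE}
run <- run_removal_torque(default_config(), out_dir = "retorq_out")
run$summary
autoplot(run$torques$gap_10nm)
plot_layer_contributions(run$torques$gap_10nm)
```

`scripts/acceptance.R` recomputes the analytic twist kinematics and the
roughness round trip from scratch and writes them as JSON.
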