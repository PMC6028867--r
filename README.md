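# retorq

Micro–macro finite-element simulation of implant removal torque.

Removal torque — the torque needed to break the fixation of an implant by
rotating it about its long axis — is the standard read-out of implant
anchorage tests. For a rough (acid-etched) titanium cylinder embedded in a
polymer, retention comes from mechanical interlocking between the surface
asperities and the polymer moulded around them, and the measured torque
curve reflects fractures in the polymer progressing down the implant side.
`retorq` is for biomaterials and implant-mechanics researchers who want to
predict that torque response from surface-roughness data and bulk material
constants, and to inspect the fracture progression that produces it.

## The model

1. **Surface.** A conical asperity is fitted so that its closed-form areal
   roughness parameters match measured targets — Sa (arithmetic mean height
   deviation), Sdq (RMS slope, as an angle) and Sdr (developed area
   excess) — inside one periodic unit cell of the implant surface.
2. **Micro FEM.** The embedding polymer below one cell is meshed with
   first-order hexahedra and loaded by displacing the rigid, gap-offset
   feature tangentially: frictionless unilateral contact (penalty with
   active-set iteration), tied periodic side faces, fixed bottom. Fracture
   is element death: any element whose von Mises stress reaches the polymer
   yield strength (40 MPa) is deleted and the increment re-solved until no
   further elements fail, giving a reaction-force-versus-displacement curve
   `F(u)` per interfacial gap size.
3. **Macro torsion layers.** The embedded cylinder (radius `r`, embedded
   length `L`, bottom fixed) twists linearly, so an axial layer at height
   `z` sees the tangential displacement `u(z) = r·Θ·z/L`. The removal
   torque at rotation Θ is the layer-wise summation

   `T(Θ) = Σ_layers r · (π·d·h_layer / A_cell) · F(u(z_layer))`,

   which rises while layers load, peaks, and falls as layers pass their
   force peak in sequence from the top of the implant to the bottom.

## Worked example

The packaged default profile (`default_config()`, the acid-etched bench
model: Sa 849 nm / Sdq 50° / Sdr 40 %, polymer E = 3.76 GPa, ν = 0.34,
yield 40 MPa, gaps 10–150 nm, 3 mm cylinder embedded 9 mm in 20 layers):

```r
library(retorq)
run <- run_removal_torque(default_config(), out_dir = "retorq_out")
#> [fit] fitting cone to roughness targets (mode sa+sdq)
#> [mesh] building unit-cell mesh (target element size 0.4 um)
#> [mesh] 1920 elements, 2448 nodes
#> [micro] gap 10 nm ... [micro] gap 150 nm
#> [done] 172.6 s elapsed

run$fit
#> <cone_fit> mode sa+sdq (least squares)
#> <cone_feature> base radius 2.90697 um, height 3.75797 um, flank angle 52.28 deg
#> target:  Sa 849 nm, Sdq 50 deg, Sdr 40 %
#> achieved: Sa 845 nm, Sdq 50.42 deg, Sdr 55.54 %

run$summary
#> # A tibble: 4 x 5
#>   gap_nm rotation_deg torque_Nmm torque_Ncm fractured_volume_um3
#>    <dbl>        <dbl>      <dbl>      <dbl>                <dbl>
#> 1     10        0.002      183.       18.3                  6.51
#> 2     50        0.006       98.9       9.89                 5.76
#> 3    100        0.214       64.3       6.43                 4.21
#> 4    150        0.021       38.2       3.82                 3.47
```

Reading the output: no single cone can match all three roughness targets at
once (a documented property of the one-cone-per-cell idealisation), so the
fit reports the least-squares pair solution and the achieved triple; the
recomputed Sa and Sdq land within 1 % of the targets. The summary gives, per
interfacial gap, the simulated removal torque (peak of the torque-rotation
curve, N mm and N cm), the rotation at which it occurs and the polymer
volume lost to fracture: larger gaps mean less contact, fewer fractures and
lower removal torque. `autoplot()` methods plot force-displacement and
torque curves, and `plot_layer_contributions()` shows each layer letting go
in top-to-bottom sequence; `tidy()`/`glance()` return the fit and curve
summaries as tibbles.

A thin command-line front end wraps the same pipeline:

```sh
Rscript inst/cli/retorq.R full-run --config my_config.yml --out out_dir
```

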