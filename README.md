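# edem — extended discrete element analysis of articular joint contact

`edem` estimates contact pressure and contact area in an articular joint —
its motivating application is the tibiotalar (ankle) joint during the stance
phase of gait — for researchers in musculoskeletal biomechanics who need
joint contact estimates orders of magnitude faster than finite element
analysis. Bones are rigid triangulated surfaces and the cartilage is an
elastic foundation: a mattress of independent compressive springs cast along
the talar triangle normals onto the tibial surface.

Each spring spanning a gap `h_i` over a triangle of area `A_i` has the
confined-column stiffness

    k_i = s(nu) * E * A_i / h_i,    s(nu) = (1 - nu) / ((1 - 2 nu)(1 + nu))

so stiffness is strain-dependent: it grows as the gap closes. Springs longer
than a threshold `h_T` are excluded (the *nominal* contact region); a
translation-only force balance with iterative release of tensile springs
yields the *active* region, per-triangle pressures `p_i = f_i / A_i`, and
the talus displacement. Two modes share the solver:

* **DEM** — the classical method: each time point is an independent static
  solve with the talus at its reference pose (`f_i = k_i n_i·u`);
* **EDEM** — the extended method: the talus translates cumulatively and each
  active spring carries its *push-back* force between time points
  (`f_i = k_i n_i·u + f_i,t-1`), letting the bone settle under rising load
  and move back as the load falls.

Around the core the package provides mesh I/O (STL/OBJ/PLY), least-squares
cylinder fitting of the joint axis, tension-only ligament bundles, gait CSV
parsing, parametric synthetic joint fixtures with known analytic behaviour,
a stance-phase pipeline, EDEM-vs-DEM comparison, and a global sensitivity
analysis of peak pressure over the (threshold, ligament modulus) plane.

## Worked example

A synthetic incongruent ankle (convex talar trochlea of radius 20 mm in a
shallower tibial sector, nominal gap 1.5 mm) driven through a 21-frame
half-sine stance peaking at 2000 N with 10° of dorsiflexion ramp:

```r
library(edem)

joint   <- make_joint(fixture_spec("cylinder_incongruent", gap = 1.5,
                                   radius_tibia = 40, resolution = 800))
bundles <- make_bundles(joint$attachments)          # four ligament bundles
frames  <- make_gait_profile(21, 2000, peak_angle = 10)

edem_run <- run_stance(joint$talus, joint$tibia, joint$axis, bundles,
                       frames, material_params(), method = "EDEM")
dem_run  <- run_stance(joint$talus, joint$tibia, joint$axis, bundles,
                       frames, material_params(), method = "DEM")
edem_run
#> <stance_result> EDEM, 21 frames (21 solved); peak pressure 6.331 MPa, max active area 5.403 cm^2
dem_run
#> <stance_result> DEM, 21 frames (21 solved); peak pressure 6.460 MPa, max active area 5.026 cm^2
compare_methods(edem_run, dem_run)
#> <method_comparison> stance-average active area: EDEM 4.780 cm^2, DEM 4.691 cm^2 (delta 0.090); mean active-set overlap 0.952

subset(edem_run$summary, frame %in% c(1, 6, 11, 16, 21),
       select = c(frame, fy, peak_mpa, area_cm2, uy))
#>    frame       fy peak_mpa area_cm2     uy
#> 1      1    0.000   0.0000   0.0000 0.0000
#> 6      6 1414.214   4.3432   5.1514 0.2211
#> 11    11 2000.000   6.3305   5.4027 0.3117
#> 16    16 1414.214   5.0912   4.9001 0.2520
#> 21    21    0.000   1.1968   4.7744 0.0402
```

Reading the summary: the talus settles superiorly (`uy`, mm) as the load
rises, peak pressure (MPa) tracks the load and maximises at the peak-load
frame, and the active contact area (cm²) grows as the settling talus brings
more springs under the length threshold — which is why the EDEM
stance-average area exceeds DEM's on the same inputs. At the final unloaded
frame the push-back forces have returned the talus nearly to its reference
pose; the residual pressure is the ligament pre-tension induced by the
rotated tibia. `pressure_map()` exposes the full per-triangle field, and
`write_pressure_vtk()` exports it for ParaView.

A command-line wrapper over the same functions is installed at
`system.file("cli", "edem.R", package = "edem")` with `run`, `sensitivity`
and `synth` subcommands driven by a YAML configuration (see
`default_config()`).

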