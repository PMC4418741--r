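# paleofract

Image-based finite-element inference of long-bone fracture mechanics, for
palaeontologists and biomechanists who want to ask of a fossil fracture:
*what loading regime broke this bone, with what force, and what event could
have delivered it?*

A partially healed fracture in a CT-scanned long bone preserves the
geometry of the failure plane. `paleofract` implements the full inference
chain from volumetric image to impact scenario:

1. **Synthetic phantoms** — capped-cylinder bone volumes and tetrahedral
   meshes with a cortical shell, concentric cancellous density classes,
   oriented trabecular microstructure, a planted subsurface pathologic
   fracture and wider surface-breaking taphonomic cracks, all with ground
   truth, so every downstream stage is testable without a fossil scan.
2. **Segmentation** — ISODATA (iterative intermeans) thresholding,
   greyscale binning into cortical + N cancellous classes, and detection
   and classification of dark crack components by the field rule:
   *pathologic* cracks are narrow (about two voxels) and subsurface,
   *preservational* cracks are wider and reach the surface.
3. **Fabric analysis** — the mean intercept length (MIL) method:
   `MIL(n) = total test-line length / bone-void crossings` over
   quasi-uniform orientations, the fabric tensor from the least-squares
   ellipsoid fit `n'Hn = 1/MIL(n)^2`, the degree of anisotropy
   `DA = t1/t3`, and the alignment angle of the primary fabric axis.
4. **Material mapping** — the density-modulus power law
   `E = 0.001 rho^1.3266` (E in GPa, rho in kg/m^3), rounded to the
   nearest 0.5 GPa; nu = 0.3 for cancellous bone; fixed literature values
   for cortical bone; volume-weighted homogenisation and a total-mass
   check.
5. **Finite elements** — a linear-static constant-strain tetrahedron
   solver (sparse Cholesky, prescribed displacements, reusable
   factorisation) with von Mises stress/strain and principal-stress
   post-processing, five canonical comparison regimes, and a
   heterogeneous-vs-homogeneous material comparison harness.
6. **Fracture-regime search** — a seeded grid over load patch centres and
   direction cones, scoring each candidate by two field criteria: strain
   localisation on the fracture surface (C1) and Mohr-consistency of the
   principal stress directions with shear slip along it (C2).
7. **Scaling mechanics** — force extrapolation by linearity
   `F = F_ref (eps_yield / eps_peak)`, equivalent loading mass `F/g`,
   isometric body mass `m_ref (l/l_ref)^3`, body-weight ratios, and fall
   kinematics `v_max = sqrt(2 (F/m) s_d)`,
   `s_h = v_max^2/(2g) + s_d`, forward and inverse.

## Worked example

```r
library(paleofract)

## a fossil-like phantom with known ground truth
sp <- phantom_spec(seed = 1)
ph <- generate_phantom(sp)
seg <- segment_materials(ph$volume, n_cancellous = 4,
                         thresholds = ph$truth$thresholds)
crack_report(classify_cracks(detect_cracks(ph$volume, seg)))
#>   id n_voxels median_width touches_surface surface_fraction classification
#> 1  1      658            2            TRUE        0.1884498 preservational
#> 2  2      637            2            TRUE        0.2056515 preservational
#> 3  3      956            2           FALSE        0.0000000     pathologic
```

One narrow interior component (the planted pathologic fracture) and two
surface-breaking preservational cracks, as planted.

```r
## trabecular anisotropy of an axis-aligned cancellous texture
tv <- generate_trabecular_volume(axis = c(0, 0, 1), anisotropy_ratio = 3,
                                 bvf = 0.3, seed = 31)
fab <- fabric_analysis(tv, n_orientations = 128, n_points = 150, seed = 3)
degree_of_anisotropy(fab)        # 1.87  (> 1: preferred orientation)
alignment_angle(fab, c(0, 0, 1)) # 2.3 degrees from the long axis

## the force/mass/fall chain from the reference FE solution
fracture_scenario_chain()
#> Fracture force: 1120 N (exact 1122.0 N) from 56.1 N at 6000/300 microstrain
#> Equivalent loading mass: 114.3 kg
#> Isometric body mass for 1-1.5 m: 6.2-21.1 kg
#> Force in body weights (10, 25 kg): 11.4, 4.6
#> Fall: m = 25 kg, s_d = 0.150 m -> v_max = 3.67 m/s, height 0.85 m (exact 0.836 m)
#> Fall: m = 15 kg, s_d = 0.127 m -> v_max = 4.35 m/s, height 1.13 m (exact 1.090 m)
```

Reading the chain: if a reference load of 56.1 N produces a peak of about
300 microstrain in the fracture zone, then reaching the 6000-microstrain
yield strain of bone takes about 1120 N — roughly a 114 kg static load, or
5-11 body weights for a 10-25 kg animal. A 25 kg animal decelerating over
its 0.15 m body depth reaches that force by falling about 0.85 m; a 15 kg
animal (body depth rescaled isometrically) by falling about 1.1 m.

The regime search itself:

```r
tp <- generate_tet_phantom(sp, target_elements = 4000)
surf <- fracture_surface_from_spec(tp$mesh, sp)
mats <- material_props(tp$mesh, material_card(tp$class_densities))
head(search_loading(tp$mesh, mats, surf), 3)[, c("cx","cy","cz","dx","dz","combined")]
#>         cx cy cz         dx         dz  combined
#> 1 10.53907  0 55 -0.1830127 -0.9659258 0.5101380
#> 2 10.53907  0 55 -0.2588190 -0.9659258 0.4920265
#> 3 10.53907  0 55  0.0000000 -1.0000000 0.4837518
```

The top-ranked regimes all place the load on the proximal-most lateral
surface, directed essentially axially towards the distal end — the planted
truth; a concentrated single-node load (a bite analogue) scores about half
the top combined score.

An end-to-end run with artifacts and a manifest:

```r
run <- run_pipeline(pipeline_config(seed = 1, out_dir = "out"))
pf_report(run)
```

or from a shell: `Rscript inst/cli/paleofract.R run --seed 1 --out out`.

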