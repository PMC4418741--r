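---
title: "Methods: image-based inference of long-bone fracture mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based inference of long-bone fracture mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleofract)
```

# The problem

A healed or partially healed fracture in a fossil long bone records the
mechanical event that caused it. If the three-dimensional geometry of the
fracture plane can be read from a CT scan, linear-elastic finite element
analysis can be used to ask which loading regime — where on the bone the
force acted, and in which direction — produces strain and stress fields
consistent with that plane, and Newtonian mechanics can then translate the
reference FE solution into an impact force, an equivalent loading mass, and
a minimum fall height. `paleofract` implements that whole chain as testable,
seeded, scriptable code, together with a synthetic phantom generator that
stands in for a fossil scan so that every stage can be validated against
known ground truth.

# The synthetic phantom

The phantom is a capped cylinder: a dense cortical shell (default density
2.06 g/cm^3) around a cancellous interior divided into concentric density
classes (defaults 1.6, 1.4, 1.2, 1.1 g/cm^3, outer to inner), mirroring the
axially concentric pattern of density seen in sectioned long bones.
Greyscale is linear in density (gain 100 per g/cm^3) plus Gaussian noise
(default SD 2% of the dynamic range): the simplest relation that makes the
classes separable by thresholding, since the true greyscale-density
relation of fossilised bone is unknown. Two kinds of planted defects carry
ground-truth labels:

* a **pathologic fracture**: a dark sheet at most 2 voxels thick on a
  paraboloid patch `z = z0 - c r^2` concentric with the shell — parabolic
  in axial section, concentric with the margins in transverse section,
  strictly interior (just beneath the endosteal surface), and confined to
  an azimuthal window (default the lateral side);
* **taphonomic cracks**: darker planar slabs 4 voxels wide that reach the
  outer surface, placed in separated axial slots in the distal half so that
  distinct cracks can never merge into one connected component.

Default dimensions (60 mm long, 10 mm outer radius, 2 mm cortex, 0.5 mm
voxels) keep every stage runnable on one CPU in seconds while leaving all
geometric contrasts (shell vs. interior, narrow vs. wide cracks) several
voxels wide.

The trabecular texture generator is separate: a Gaussian random field
smoothed by an anisotropic Gaussian kernel whose along-axis standard
deviation is `anisotropy_ratio` times the transverse one, thresholded at
the `1 - bvf` quantile so the realised bone volume fraction equals the
request exactly up to ties. This is a *texture model*, not a biological
model: it has a controllable principal axis, anisotropy, and volume
fraction, but no rod/plate architecture, no cortical gradient, and no
remodelling history. Passing fabric tests on it shows the estimator chain
is correct, not that any particular fossil value is reproducible. The bone
volume fraction default (0.3) is a free parameter chosen as typical for
load-bearing cancellous bone; no fossil value is asserted.

The tetrahedral phantom is meshed by structured subdivision (triangulated
disc extruded into wedges, each wedge split into three tetrahedra with
quad diagonals through the globally smallest node index, which keeps the
mesh conforming). Ring radii are aligned with the material class
boundaries and inflated so each polygonal annulus has exactly the area of
its circular counterpart; total volume and per-class mass are then exact
to rounding, and the measured minimum dihedral angle (enforced floor 5
degrees, typically 12-16 degrees at 5k-20k elements) is reported.

# Segmentation and crack taxonomy

Materials are segmented by greyscale binning inside a bone mask
(`background cut` from iterative intermeans thresholding — the ISODATA
fixed point `t = (mean below + mean above)/2` — then a chessboard
morphological closing, radius 2, so dark internal cracks stay inside the
mask). With explicit cuts the binning is exact; without, cuts default to
equal-count quantiles, a reproducible stand-in for the subjective
by-appearance choice a human would make. Crack candidates are voxels
darker than the within-bone mean minus 2 SD, grouped by 26-connectivity;
the outermost mask layers (the closing radius) are excluded because
closing a bumpy voxelized surface deposits a thin dark rind there that
would otherwise bridge separate cracks. Width is twice the median
chessboard distance to the component boundary; surface contact is
26-adjacency to background. The classification rule is the published field
rule: a component is *pathologic* iff it is narrow (median width at most
2.5 voxels) and interior (surface contact over at most 1% of its voxels,
an allowance for a fracture that nears the surface at a groove);
everything else is *preservational*.

# Fabric analysis

Architectural anisotropy is quantified by the mean intercept length (MIL)
method: for each test direction, lines are cast through seeded points
across the region of interest and MIL = total line length / number of
bone-void crossings. Directions are a Fibonacci hemisphere lattice
(antipodes identified) under a seeded random rotation; the default counts
(2049 orientations, 2000 points at full scale; smaller in the bundled
tests) follow standard practice for micro-CT fabric work. Crossings are
counted by an exact incremental voxel traversal in C++; the test suite
contains an independent pure-R oracle that enumerates grid-plane crossing
parameters and must agree *exactly* on crossing counts.

The fabric tensor H is the least-squares fit of the MIL ellipsoid
`n' H n = 1 / MIL(n)^2`; fabric semi-axes are `1/sqrt(eig(H))` sorted
descending, the degree of anisotropy (DA) is the primary/tertiary ratio,
and the alignment angle is the antipodal-invariant angle between the
primary eigenvector and a reference axis. At least 9 non-coplanar
directions are required; coplanar designs raise a rank error. On isotropic
phantoms the DA estimate stays within [1.0, 1.15] over seeds (finite
sampling keeps it above exactly 1); on aligned phantoms with generator
anisotropy 3 the primary axis is recovered within 10 degrees.

# Material model

Cancellous density maps to Young's modulus through the power law
`E = 0.001 rho^1.3266` (E in GPa, rho in kg/m^3), optionally rounded to
the nearest 0.5 GPa to acknowledge mapping uncertainty; Poisson's ratio is
0.3 for all cancellous classes. Cortical bone deliberately bypasses the
regression and uses fixed literature values (2.06 g/cm^3, 20 GPa, 0.4).
One conventional tabulated value — 17.5 GPa for the 1.6 g/cm^3 class —
disagrees with the regression-plus-rounding result (17.8 -> 18.0 GPa); the
material card keeps the tabulated value, records the regression value
alongside, and flags the row rather than silently resolving the conflict.
Homogenisation is the volume-weighted mean density of the cancellous
classes, re-mapped through the same regression. `total_mass` integrates
density over the mesh as a sanity check against the closed-form mass.

# Finite elements

The solver uses constant-strain 4-node tetrahedra ("low-order tetrahedral
bricks"), assembled into a sparse symmetric stiffness matrix and solved by
sparse Cholesky factorisation with prescribed-displacement elimination; the
factorisation is reusable across right-hand sides, which is what makes the
grid search over loading regimes affordable. Known properties of the
element are embraced rather than hidden: it passes the patch test exactly,
reproduces uniform-stress states to solver precision, and is too stiff in
bending at coarse resolution — the bundled cantilever verification
(length/depth = 10) needs about 10 elements through the thickness to come
within 5% of Euler-Bernoulli theory. Every solve reports a global
equilibrium residual (at most 1e-6 relative in all bundled analyses).
Stresses are in MPa (tension positive); strains are reported in
microstrain. The von Mises strain uses the `(1+nu)`-consistent deviatoric
convention, so a uniaxial stress state at axial strain `eps` reports
exactly `eps` and `sigma_vm / E` elementwise.

Five canonical regimes (axial compression, axial tension, axial torsion,
anteroposterior and mediolateral midshaft bending) are built from the mesh
geometry with the restraint scheme of comparative bone FE work: a small
node set at the distal end-face centre for the axial cases, both end
centres for the bendings. "Small number of nodes in the centre" is
operationalised as all end-face nodes within 2% of the bone length of the
face centroid, expanded if necessary to at least 7 nodes so all six
rigid-body modes are removed. Distributed loads are area-weighted over
surface patch nodes — the same stated purpose (suppressing point
artifacts) as the stiff-beam articular-surface devices used in fossil FE
models, which are out of scope here.

For the heterogeneous-versus-homogeneous comparison, the mean von Mises
element strain is reported both volume-weighted and unweighted, with the
volume-weighted difference as the headline number. On a mesh of
near-uniform voxel-derived elements the two coincide; on this package's
structured meshes element volumes grade by a factor of about fifty from
the axis outward, so the element-count mean overweights the tiny,
softest, central elements and inflates the apparent het/hom difference.
The volume-weighted estimator is the faithful analogue of the original
comparison; at about 20k elements all five regimes differ by under 5%.

# Fracture-regime inference

The fracture surface is discretised as the set of elements within one mean
edge length of the paraboloid patch, each carrying the analytic surface
normal and a slip direction (the in-plane component of the distal axis —
distal displacement of the external fragment). Two field criteria score a
candidate solution:

* **C1, strain localisation** — high-strain elements H are those at or
  above half the peak proximal von Mises strain (how "regions of high
  strain" read off a contour plot; a fixed-percentile H was tried and
  rejected because it forces |H| to the same size for every load, which
  lets a concentrated load's halo cover the surface at desk-scale mesh
  resolution). C1 = precision x coverage, where precision is the fraction
  of H within 1.5 mean edges of the surface and coverage is the fraction
  of surface samples with an H element that close. Coverage is what
  defeats a concentrated "bite-type" load: its strain blob is near the
  surface (high precision) but spans only one spot of it.
* **C2, shear consistency** — over near-surface elements, the fractions in
  which the maximum principal stress sits at a high angle (>= 45 deg) to
  the plane, the minimum principal stress at a low angle (<= 45 deg), and
  the intermediate principal stress lies in-plane (<= 30 deg) and
  perpendicular to slip (>= 60 deg), averaged. The thresholds encode the
  qualitative words "high angle / low angle / parallel / perpendicular"
  and are configurable and reported; near-hydrostatic elements have no
  defined principal directions and are counted as inconsistent and
  flagged. Absolute C1/C2 values are implementation-defined — acceptance
  is by recovery and ranking, never by matching a printed score.

The published search was manual trial and error over nineteen regimes;
here it is a reproducible grid: patch centres on the outer surface of the
proximal third (default 12 = 4 azimuths x 3 heights), force directions in
a cone around the distally-directed long axis sampled at 15-degree steps
(default 25), one linear solve per candidate against a single cached
factorisation, magnitude fixed at 56.1 N (by linearity it cannot affect
the ranking, which is asserted in tests). On the default phantom the
planted proximolateral, distally-directed patch load is ranked first, and
a single-node point load scores roughly half the top combined score.

# Force scaling, body mass, and fall kinematics

The closed-form chain: by linearity the fracture force is the reference
load scaled by the ratio of yield strain (assumed 6000 microstrain) to the
peak fracture-zone strain at the reference load (F = 56.1 x 6000/300 ~
1120 N at three significant figures); dividing by g = 9.8 m/s^2 gives the
equivalent loading mass (~114 kg). Body mass is bounded isometrically from
total length against a 2 m / 50 kg salamander-grade reference (6.25 and
21.09 kg at 1 and 1.5 m, conventionally handled as a 10-25 kg range,
making the fracture force 5-11 body weights). Fall kinematics: an animal
of mass m decelerating from free fall over its body depth s_d experiences
a = F/m, so v_max = sqrt(2 a s_d) and the free-fall drop is
v_max^2 / (2g); the fall height adds s_d. Two conventions are emitted:
exact, and a "paper rounding" mode that rounds the free-fall drop to
0.1 m before the sum (0.836 m prints as 0.85 m under that convention).
For a lighter animal the deceleration distance is rescaled by the cube
root of the mass ratio — isometry applied to a linear body dimension; this
reconstruction of the unstated "scaled appropriately" is validated by
reproducing the printed ~110 cm for 15 kg. g defaults to 9.8 m/s^2 (the
convention of the source arithmetic), not 9.81; both g and every distance
are arguments. The exact inverse (force from height) is provided and
round-trips to 1e-9.

# Numerical choices and problem sizes

* Defaults for the bundled analyses: voxel phantoms at 0.5 mm spacing
  (~44 x 44 x 136 voxels), trabecular fields at 64^3, FE meshes at 4k
  (search) to 20k (het/hom comparison) elements, fabric runs at 128-2049
  orientations and 150-2000 points. These sizes were chosen so the full
  validation suite runs on a single CPU in a few minutes while keeping
  every contrast several voxels or elements wide.
* Determinism: every stochastic stage takes an integer seed; identical
  seeds give bit-identical volumes, meshes, orientation sets and reports.
* Ties: the trabecular threshold uses the empirical quantile, so the
  realised volume fraction equals the request up to ties; MIL lines that
  graze voxel corners are avoided by seeding points at generic interior
  positions.
* Degenerate inputs raise explicit errors: constant histograms, solid
  ROIs along a direction, coplanar direction sets, inverted or degenerate
  tetrahedra, insufficient restraints.

# Limitations

The phantom is idealised: straight axis, circular sections, concentric
classes, linear greyscale. The solver is linear-static with isotropic
materials — no contact, no crack propagation, no impact transients (the
impact is handled through the quasi-static strain-scaling argument). The
fabric estimator's absolute DA depends on texture scale relative to voxel
size; only its ordering and axis recovery are asserted. No claim is made
that any fossil-specific printed value (a fabric DA of a real bone, the
het/hom percentages of a particular specimen) is recoverable without the
original scan; the tests assert the properties that are recoverable at
desk scale.
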