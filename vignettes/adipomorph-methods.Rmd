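---
title: "Methods: 3D adipocyte morphometry on synthetic cleared-tissue volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D adipocyte morphometry on synthetic cleared-tissue volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

adipomorph quantifies adipocyte morphology in 3D light-sheet volumes of
cleared, fluorescently stained adipose tissue: Nile Red-type lipid staining
makes cell interiors bright, a 5-DTAF-type stain marks the extracellular
matrix (ECM) shell separating cells. The package covers the full analysis
chain — segmentation, per-cell shape measurement, and group statistics —
and pairs it with a synthetic tissue-phantom generator with exact ground
truth, so that every stage is verifiable without access to raw microscope
data. This vignette records the models, the parameters that matter, the
numerical choices, and the design decisions taken where several
realizations were defensible.

## The tissue phantom

The generator emulates the statistical structure the analysis assumes, not
the microscope physics in detail. A phantom is built in four steps:

1. **Volumes.** True cell volumes follow a right-skewed lognormal law
   parameterized by mean and coefficient of variation (CV). The
   `quantile_matched_lognormal` family places the `n` values at evenly
   spaced quantiles `(i - 0.5)/n` and rescales so the sample mean equals the
   requested mean *exactly*; it is the calibration tool used whenever a
   cohort must hit a prescribed mean. The default CV is 0.4. No dispersion
   value is available from tissue studies that report only the SEM of the
   mean, so the default was fixed once at a value that yields the ~40–130 µm
   equivalent-diameter range typical of rat visceral adipocytes; it is
   configurable.
2. **Packing.** Cells are non-overlapping spheres placed by random
   sequential addition, largest first, with surface-to-surface clearance of
   at least `ecm_gap` (default 4 µm) between cells and between each cell and
   the domain wall (the wall margin keeps a wall-clipped blur tail from
   biasing border filtering; real tissue has no walls). Densities are
   feasible below a ~55% packing fraction; the reference study packs at
   ~25–30%. Spheres make the ground-truth sphericity analytic; real
   adipocytes in dense tissue flatten against each other, which is one
   reason measured tissue sphericities (~0.8) sit below the phantom's ~1.
3. **Optics.** The lipid channel is 1 inside cells and 0 outside; the ECM
   channel fills the shell of thickness `ecm_gap` around cells. Both are
   blurred with an anisotropic Gaussian PSF (`psf_sigma`, default (2, 2, 3)
   µm: lateral blur of a 4x/0.35 objective, axial blur of a ~4 µm light
   sheet) and attenuated by `exp(-z / attenuation_length)`. The default
   attenuation length of 400 µm reproduces the phenomenology of cleared
   adipose tissue, where image quality degrades beyond a few hundred µm of
   depth. A single exponential is the simplest model with that behaviour;
   scattering, shadowing and refractive-index mismatch artifacts are
   deliberately out of scope.
4. **Noise.** Poisson photon noise at `photon_scale` expected photons per
   unit intensity plus Gaussian read noise (`read_sigma`, in photons) — the
   standard sCMOS model. Defaults (100, 2) give a foreground SNR of ~10.

Default voxel spacing is 1.62 × 1.62 × 4 µm (camera pixel size and
light-sheet step of the emulated acquisition). Grids are stored `[y, x, z]`
with physical coordinates reported `(x, y, z)` in µm and the origin at the
first voxel center. Everything is seeded: identical parameters give
bit-identical phantoms, and a study derives per-sample seeds
deterministically from one master seed.

What passing tests on phantoms do **not** show: robustness to crown-like
macrophage structures, vasculature, non-convex or collapsed cells, staining
heterogeneity, or clearing artifacts — none of which the generator emulates.

## Segmentation

The classical backend is fully deterministic and composes:

1. **Depth normalization** (on by default): the per-slice 99th-percentile
   intensity is regressed log-linearly against depth; if it decays, the fit
   is divided out. A global threshold is meaningless on depth-attenuated
   data otherwise.
2. **Thresholding**: Otsu's criterion on the (normalized) lipid channel —
   the threshold maximizing between-class variance on a 256-bin histogram —
   or a fixed threshold. Enclosed 3D holes are filled (background components
   not connected to the grid boundary).
3. **Circular open** (default radius 10 µm): removes regions that cannot
   accommodate a ball of the given physical radius. Implemented as the ball
   granulometry — the union of all inscribed Euclidean balls with radius
   above the cutoff — computed from a squared distance transform and an
   additively weighted (power-diagram) transform, both anisotropy-aware.
   This form is exactly anti-extensive, idempotent and monotone in the
   radius; the textbook erode-then-dilate composition loses
   radius-monotonicity on discrete grids, which is why it is not used. The
   radius is a free parameter: commercial pipelines name the operation but
   not its size, so 10 µm (well below the ~20 µm minimum cell radius) was
   fixed as the default and exposed in the configuration.
4. **Separate objects**: Euclidean distance transform in physical units,
   h-maxima suppression of shallow peaks (default h = 4 µm), then seeded
   watershed flooding of the mask in order of decreasing distance. Every
   mask voxel is assigned to a basin; fronts with larger distance win and
   ties resolve deterministically by insertion order. The default h was
   chosen at the scale of the ECM gap: distance-map wobble below that scale
   is texture, not cell structure.
5. **Filtering**: objects below `min_volume` (default 20,000 µm³, an
   equivalent diameter of ~34 µm, below any plausible adipocyte) are
   dropped, and objects touching the grid boundary are excluded by default
   because their volumes are clipped low. Both are configurable.

The opening is applied to the binary mask *before* separation by default
(opening a label image is ill-defined); a configuration flag applies it
per-object after separation instead.

A learned backend exists alongside the classical one: a logistic pixel
classifier over local intensity features, trained with a two-round
curriculum (short first round on a few z-averaged slices, long refinement
round; defaults 200 and 1500 iterations) with the cross-entropy loss logged
per iteration. It reproduces the *protocol* of interactive deep-learning
segmentation tools so the training loop is exercisable end-to-end on
synthetic data; it is deliberately not a neural network, never the default,
and no result in this package depends on it.

## Morphometry

Per labelled object:

* **Volume** `V` = voxel count × voxel volume (µm³).
* **Equivalent diameter** `d_eq = (6 V / π)^(1/3)` — the diameter of the
  volume-matched sphere.
* **Surface area** `A`: the object's binary mask is Gaussian-smoothed
  (σ = 1 voxel per axis) and the 0.5 isosurface is meshed by marching
  tetrahedra (six tetrahedra per cell sharing the main diagonal, watertight
  across cells) with the anisotropic physical spacing; `A` is the summed
  triangle area. Voxel-face counting was rejected because it overestimates
  curved surfaces by up to ~50%, which would corrupt sphericity; smoothing
  plus meshing recovers sphere areas to well under 1% at radii of a few
  tens of voxels. Anisotropic grids are meshed directly with per-axis
  spacing rather than resampled, avoiding interpolation bias in `V`.
* **Sphericity** `Ψ = π^(1/3) (6V)^(2/3) / A`, the surface area of the
  volume-matched sphere divided by the measured surface area. The sphere
  attains the maximum, 1. (The inverse ratio would exceed 1 for every
  non-sphere and is sometimes seen in prose descriptions; the form used
  here is the one for which "a sphere has the maximum sphericity = 1"
  holds.) Meshing tolerance can push Ψ slightly above 1 on near-perfect
  digital spheres; values up to ~1.05 are within tolerance.
* **Centroid**: unweighted mean of voxel centers in physical coordinates.
  Lipid interiors are nearly uniform, so intensity weighting would add
  noise without information; the choice is switchable in principle by
  measuring on a different mask.
* **NOD** (nearest object distance): Euclidean distance from the object's
  centroid to the nearest other object's centroid, matching brute-force
  all-pairs search by construction.

Whole-voxel translations leave `V`, `A`, `Ψ` unchanged and shift centroids
exactly; scaling multiplies `V` by `s³` and `A` by `s²` within voxelization
tolerance. Both are enforced by tests, as are analytic oracles (sphere,
cube, prolate spheroid).

## Group statistics

Groups are summarized as mean ± SEM with `SEM = sd/√n` where `n` is the
**pooled per-adipocyte count** of the group (e.g. 1350 for 3 samples × 450
cells) — the convention that matches per-cell reporting of morphometry
studies. Per-sample (per-animal) aggregation is available through the
binned distributions, which average per-sample histograms (n = number of
animals).

Two-group comparisons use the Mann-Whitney U test: midrank ties in U, exact
two-sided p by full enumeration when `n₁ + n₂ ≤ 12` without ties, otherwise
the normal approximation with tie and continuity corrections (delegated to
`stats::wilcox.test`; an exhaustive-permutation oracle in the test suite
checks both routes). Percent differences are
`100 · (other − reference)/reference`.

Class distributions bin each feature per sample with uniform, left-closed/
right-open bins (last bin closed; an overflow bin is appended when data
exceed the range). Default widths — volume 50,000 µm³, NOD 5 µm, equivalent
diameter 10 µm, sphericity 0.04 — correspond to the class conventions of
adipocyte morphometry panels and are configurable. Per-bin group
comparisons apply a Mann-Whitney test to the per-sample counts and control
the false discovery rate at Q = 5% across bins. The default FDR procedure
is the two-stage adaptive step-up (stage one at `Q/(1+Q)` estimates the
number of true nulls, stage two reruns the linear step-up at the adaptive
level) — the convention of the statistics software whose "FDR at Q"
phrasing the field commonly reports — with the standard linear step-up
available as an option. Empty bins are skipped and logged.

## Numerical and testing choices

* Distance transforms use the exact separable squared-distance algorithm
  (parabola envelopes) in physical units; the opening keeps everything in
  squared arithmetic, and a voxel lying exactly on an inscribed-ball
  boundary is excluded (it is background by construction), with a relative
  tolerance of `1e-7·r²` absorbing floating-point ties.
* Watershed flooding uses a max-heap with insertion-order tie-breaking, so
  label assignment is deterministic for a fixed input.
* Degenerate inputs: constant images raise a thresholding error; empty
  masks yield zero labels without error; NOD requires at least two objects;
  objects thinner than two voxels on an axis get a missing surface area and
  are reported.
* Problem sizes in the test-suite and in `scripts/acceptance.R` are the
  package's own reference conditions: cohorts of 450 cells per sample
  rendered at 3.24 × 3.24 × 4 µm (half the native lateral sampling), a
  scale at which a full cohort segments in about a minute while volume
  recovery stays within a couple of percent; the 1350-cells-per-group
  layout (3 samples × 450) is generated at coarser voxels where only
  ground-truth counts are examined.

## Known limitations

* Phantom cells are spheres; sphericity recovery is validated against
  analytic solids, not against deformed-cell ground truth.
* The depth-normalization fit assumes a single global exponential decay.
* NOD on sparse phantoms is larger than in dense tissue at equal cell
  size; NOD comparisons between groups are meaningful, absolute NOD values
  depend on the packing fraction.
* The learned backend is a pixel classifier, not a U-Net; it demonstrates
  the training protocol, not deep-learning segmentation quality.
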