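---
title: "Multimodal image integration for epilepsy presurgical planning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal image integration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Presurgical evaluation of medically intractable focal epilepsy rests on
fusing every localizing modality — structural MRI contrasts, FDG-PET,
ictal/interictal SPECT, MEG dipole solutions, angiography, the post-implant
CT of stereo-EEG (SEEG) electrodes, and finally the resection proposal —
into one anatomical space. `mmii` is a scriptable toolkit for that
workflow. A 3D T1-weighted volume serves as the *base image volume*; every
other dataset is brought into its space by rigid registration, derived
statistical maps travel with their anatomical carrier volume, and all
point-like results (dipoles, electrode contacts, pass markers) live as
named "localize points" in base-frame world millimetres.

This vignette documents the models and the design decisions behind each
stage, the parameters that matter, what the phantom generators do and do
not emulate, and known limitations.

## Coordinate conventions

World coordinates are RAS+ millimetres; voxel indices are 0-based; the
voxel-to-world affine follows the NIfTI convention. DICOM I/O converts
to/from the DICOM LPS patient frame on the way in and out. Transforms are
4×4 homogeneous world-to-world matrices with an orthonormal, det = +1
rotation block; the stored direction is always *moving world → base world*.

## Rigid registration by mutual-information maximization

Let $a$ be the fixed (base) and $b$ the moving volume sampled onto the
fixed grid through the current transform $T_\theta$ with trilinear
interpolation. From a joint histogram with $32^2$ cells (intensities
winsorized at the 0.5/99.5 percentiles so CT metal and MRI bias extremes
cannot dominate the binning) we take marginal and joint Shannon entropies
$H(a)$, $H(b)$, $H(a,b)$ in bits. The user-facing metric is

$$\mathrm{MI}(a,b) = H(a) + H(b) - H(a,b),$$

which is what `mutual_information()` returns and what
`register_rigid()` reports before/after. The *optimization objective*,
however, is the normalized mutual information of Studholme,
$\mathrm{NMI} = (H(a)+H(b))/H(a,b)$: plain MI increases when the moving
volume slides its zero padding onto the fixed background, and NMI is the
standard overlap-invariant remedy.

The optimizer is deliberately simple and derivative-free: a
three-level multi-resolution pyramid (subsampling factors 4, 2, 1, each
level Gaussian-smoothed at σ = 0.8 voxel — the smoothing regularizes the
metric surface against acquisition noise, which matters most for
Poisson-noisy SPECT), Nelder–Mead over the six rigid parameters
(translations in mm, rotations in degrees about the fixed-volume centre),
with

* intensity-centroid initialization of the translations,
* a 7-point multi-start over coarse rotation seeds (±8° per axis) at the
  coarsest level, because MI is multimodal in the rotations,
* one simplex restart per level, and a final small-simplex polish at full
  resolution to tighten the sub-voxel residual.

Everything is deterministic for fixed inputs; there is no stochastic
sampling. If the optimized transform scores below the identity
initialization on the full-resolution metric, the identity is returned
with `converged = FALSE` — registration must never leave the alignment
worse than it found it. Post-operative MRI is registered with a brain mask
that excludes zero-intensity cavity voxels from the metric, so missing
tissue cannot drag the alignment.

On the 64³ @ 2 mm head phantom, 20 random perturbations with
$|t| \le 10$ mm, $|\theta| \le 10°$ are recovered to ≲ 0.1 mm / 0.35°,
and a Poisson-noisy perfusion volume registers to the T1 within 0.3 mm
(the test suite asserts 0.5 mm / 0.5° and 1 mm respectively).

### Derived-map transfer

Statistical maps (fMRI activation, SISCOM z-scores, morphometric z-maps)
are voxel-aligned with the anatomical carrier they were computed on.
`transfer_map()` applies *exactly* the carrier's stored transform to the
map — it never re-estimates, and the test suite checks the output is
bit-identical to resampling with the supplied matrix. Nearest-neighbour
interpolation is mandatory for masks and label maps.

## SISCOM

`compute_siscom()` implements the canonical subtraction procedure: both
perfusion volumes are normalized to a global mean of 100 within the brain
mask, subtracted (ictal − interictal), and the difference is z-scored
against its own mean and standard deviation within the mask; z is zero
outside. Thresholding (z ≥ 1.5 and z ≥ 2 are the conventional review
values) yields 26-connected clusters with at least `min_voxels` voxels
(default 5), ranked by peak z. Optional Gaussian pre-smoothing (FWHM in
mm, default 0 = off) is exposed for noisy inputs. If no mask is supplied
the pipeline derives one from the base T1 by Otsu thresholding, largest
26-connected component, and interior hole filling.

Two pipeline-level choices deserve emphasis, both visible in `run_case()`:

* The subtraction is computed in the interictal SPECT's own space (ictal
  registered SPECT-to-SPECT first) and the z-map is then carried to the
  base frame with the interictal volume's transform. Registering each
  SPECT to the T1 independently and subtracting on the base grid doubles
  the interpolation error and produces rim artifacts.
* When the pair went through registration, the statistics mask is eroded
  by one voxel (`mask_erosion`), because sub-voxel misregistration shows
  up exactly on the brain edge. Cluster statistics are computed in the
  carrier space and only the cluster *coordinates* are mapped to the base
  frame — interpolating a z-map and re-thresholding it can split clusters.

With the default phantom conditions (+15 % perfusion lesion of radius
8 mm, Poisson counting noise, mean ≈ 100 counts in brain), the top
z ≥ 2 cluster lands within 2 mm of the true lesion centre in 10/10 seeds,
and lesion-free pairs produce a z ≥ 2 tail fraction within binomial error
of the standard-normal expectation (the tolerance is seven binomial
standard errors, which also absorbs the slight skewness of the Poisson
difference). Note the blob's *peak* z (≈ 4) is close to the expected
maximum of ~5·10⁴ null normals, so small `min_voxels` values admit noise
clusters; the phantom analyses use `min_voxels = 10`.

## Talairach proportional grid

`build_frame()` constructs the AC–PC frame: origin at the anterior
commissure, y along PC→AC (anterior), z the component of AC→MS orthogonal
to y (superior), x = y × z (lateral-right). VCA and VCP are the planes
through AC and PC perpendicular to the AC–PC line. The brain bounding box
enters as six positive distances from the frame's reference planes, which
makes the frame (and hence every grid cell) exactly equivariant under
rigid motion of the inputs — a property the suite tests directly.

The proportional divisions are: four even sagittal sectors between VCA
and the anterior bound, four between VCP and the posterior bound, the
intercommissural block as the single undivided sector E; eight even level
bands between the AC–PC plane and the superior bound and four below; four
even coronal columns per hemisphere between the midsagittal plane and the
lateral bound. Where the lettering direction is not forced we use: A most
anterior, D abutting VCA, F abutting VCP, I most posterior; levels 1
(vertex) through 8 (just above AC–PC), 9 (just below) through 12; columns
a (mesial) through d (lateral) — the atlas's own ordering. Band edges are
half-open, inclusive at the edge nearer the AC–PC plane/VCA, so the AC
itself is deterministically E/8/a. Points outside the box are flagged
`out_of_grid` rather than raising an error, since electrode entry points
routinely sit outside the brain box.

Full piecewise-linear warping to atlas space and atlas label lookup are
out of scope: the grid is a *reference frame*, as used for trajectory
planning, not a normalization.

## Trajectories, vessel clearance, contacts

A trajectory is the straight entry→target segment of one electrode.
`vessel_clearance()` reports the minimum distance from the segment to any
vessel-mask voxel centre, plus the same minimum restricted to the first
15 mm from the entry — vessel avoidance matters most at the entry — and a
pass flag against a configurable clearance (default 3 mm; no numeric
criterion is standard, so this is an explicit package default).
`target_coverage()` reports, per localization target, the trajectories
passing within a radius and the minimal distance. All distances are exact
point-to-segment computations, verified against brute-force oracles.

`segment_contact_candidates()` thresholds the post-implant CT (99.9th
intensity percentile by default, absolute override available — phantom
and clinical CTs differ in calibration), labels 26-connected components,
and splits components that merge several contacts at their 3D local
intensity maxima. Peaks count as distinct when separated by at least
0.7 × the nominal contact spacing; the comparison uses sub-voxel-refined
peak positions (intensity-weighted 3³ centroids) and grants half a voxel
diagonal of slack, because discrete maxima snap to voxel centres and
overlapping tails bias refined positions toward each other. Each
candidate is reported at its *centre of maximal intensity*, formalized as
the intensity-weighted centroid of the component's top-20 % intensity
voxels — robust to CT blooming, unlike a bare argmax under ties.
`assign_and_name()` assigns each candidate to the nearest trajectory
within a tolerance (default 4 mm), orders per electrode by projection
from the target outward, and names `<electrode><index>` with index 1
deepest — the prevailing SEEG convention. Ties break by distance to the
axis, then lexicographically, so naming is deterministic and
order-independent. Assignment is per-candidate greedy, which is adequate
while trajectories are far apart relative to the tolerance; a global
matching is a known possible refinement. In the pipeline, candidates are
segmented on the *native-resolution* CT and their coordinates mapped
through the CT→base transform — resampling the CT onto a coarser base
grid first would discard sub-voxel localization.

## Resection planning

"Pass markers" become a scriptable contract: a point set whose `group`
column is the stroke id. `markers_to_mask()` unions spheres of the brush
radius (default 2 mm) at each marker with swept-sphere capsules along
consecutive markers of a stroke, then applies morphological closing with
a ball of half the brush radius to fill inter-stroke gaps. The voxel mesh
is literally the exposed faces of boundary voxels as quads (not marching
cubes); for hole-free masks every edge is shared by exactly two faces.
`export_burned_mask()` prints the mask at `marker_intensity` × global max
into the base volume, and re-thresholding recovers the mask with
Dice ≥ 0.99. Containment of contacts is a voxel lookup with the fraction
inside reported.

## Burned annotations

The print-to-DICOM role of the original clinical platform (dipole points,
trajectory lines, resection masks burned as high intensity into the base
volume) is reproduced by `burn_points()` / `burn_lines()` /
`export_burned_mask()`, with defaults marker radius 2 mm, line radius
1 mm, and intensity factor 1.2 relative to the volume's global maximum —
relative, so the same settings work across MRI and CT dynamic ranges, and
strictly above 1, so burned voxels are recoverable by thresholding.
`extract_bright_points()` inverts the process (components above a
threshold, one point per component at its centre of maximal intensity);
the round trip recovers points with pairwise separation > 2 × marker
radius to within 0.5 voxel. Dipole orientation and strength are not
encoded — only locations, which is all the printed representation
carries.

## File formats

NIfTI-1 via RNifti. DICOM series support is a minimal single-series
reader/writer (Explicit VR Little Endian, monochrome 16-bit with rescale
slope/intercept) covering the geometry tags needed for lossless round
trips and neuronavigation hand-off; slices are assembled by the
projection of ImagePositionPatient on the slice normal, with duplicate
positions an error. Point sets are TSV (`name  x  y  z  group  value`) or
JSON; transforms are plain-text 4×4 matrices or JSON; plans are JSON/CSV;
meshes are OBJ quads; the Talairach frame is JSON.

## The phantom generators

The generators provide ground-truthed stand-ins for the clinical
acquisitions, and they are geometric by design: every operator in the
package depends on geometry, intensity contrast and noise, not on
anatomical realism, so nested ellipsoids keep the tests fast and the
truth exact. The default grid is 64³ at 2 mm for the T1/perfusion pair
(SPECT-like resolution, and small enough that a registration takes
seconds) and 128³ at 1 mm for the implant CT on the same field of view.

* **T1 head**: scalp, skull shell, CSF gap, gray band/white core,
  asymmetric lateral ventricles; Gaussian noise (σ = 2). The head's three
  semi-axes are deliberately distinct, and the ventricles deliberately
  asymmetric: a rotationally near-symmetric head under-determines the
  rotation about the symmetry axis, which is a phantom identifiability
  defect, not a registration failure. AC/PC/MS truth (AC–PC = 23 mm) and
  the brain bounding box are recorded.
* **Perfusion pair**: smoothed brain-proportional activity (mean ≈ 100
  counts) with independent Poisson draws; lesions are multiplicative
  spheres (+15 %, r = 8 mm by default) applied before the ictal draw.
* **Implant CT**: bright skull shell (800), brain (50), contacts as
  Gaussian blobs (peak 3000, σ = 0.9 voxel — the bloomed footprint of a
  sub-millimetre contact on a 1 mm CT) at the planned positions with
  sub-voxel jitter (σ = 0.2 voxel); the truth records the exact jittered
  centres and a recommended absolute threshold (1000, between skull and
  contact intensities — the percentile default assumes clinical
  calibration where contacts, not skull, occupy the top percentile).
* **Vessels**: smooth random tubes (or user-supplied straight polylines
  for analytic tests) with exact centerline truth.

What the phantoms do **not** emulate: MR physics (bias fields, partial
volume, distortion), CT beam hardening, anatomical shape variability,
brain shift after implantation, and scalp/skull conductivity — so passing
tests demonstrate the correctness of the geometry and statistics of the
pipeline, not robustness to every clinical artifact.

All generators restore the caller's RNG state and are bit-reproducible
for a fixed seed.

## Pipeline

`run_case()` fixes the stage order registration → SISCOM → Talairach →
trajectories → contacts → resection, records every artifact in a manifest
(file, stage, inputs, parameters, md5), logs timestamped text plus a JSON
event stream, and continues independent stages past a failed one. The
orchestration adds no computation — each output equals the corresponding
module call, which the suite asserts — and reruns with the same
configuration produce byte-identical checksums (pipeline volumes are
written as uncompressed `.nii` for that reason). The human decision
points of the clinical workflow (implant vs. operate) are deliberately
out of scope: the pipeline computes and reports, never decides.

## Problem sizes used in the tests

The suite runs the registration recovery at 64³ @ 2 mm (20 perturbations
plus one cross-modality case), SISCOM and null calibration over 10 + 3
seeds, contact recovery over 10 implant phantoms at 128³ @ 1 mm, and one
full pipeline case twice for determinism — sizes chosen so the whole
suite completes in a few minutes on one CPU while every tolerance is
asserted at the values stated above.

## Known limitations

* Rigid registration only; no deformable correction, no inter-subject
  normalization, no brain-shift model.
* Greedy (non-global) contact-to-trajectory assignment; subdural grids
  and strips are not reconstructed — depth-style contacts only.
* The DICOM layer reads/writes the package's own single-series profile;
  it is not a general DICOM implementation.
* MEG dipole *fitting* is out of scope; dipoles enter as coordinate
  lists.
* Cluster-level inference for SISCOM is descriptive (size/peak ranking),
  not a calibrated statistical test against a normative database.
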