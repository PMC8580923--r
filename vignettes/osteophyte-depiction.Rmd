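---
title: "Scoring osteophyte depiction in 3D ultrasound and CT surface models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring osteophyte depiction in 3D ultrasound and CT surface models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(osteorms)
```

## The problem

Osteophytes — osseocartilaginous outgrowths at the bone margins — are a
cardinal radiographic feature of knee osteoarthritis, yet they are depicted
inconsistently by conventional imaging. CT renders calcified tissue well but
is blind to cartilage, so an immature, largely cartilaginous osteophyte can
be invisible on a CT-derived bone model. Freehand 3D ultrasound (3D US),
reconstructed from spatially tracked B-mode sweeps, images the soft-tissue
interface and therefore sees the cartilaginous cap — at the price of lower
resolution, noise, and access limited to the medial and lateral acoustic
windows of the joint.

`osteorms` implements a quantitative framework for comparing the two:
surface models from both modalities are rigidly aligned to a high-resolution
structured-light-scan (SLS) model of the dissected joint surface, which
plays the role of ground truth; circumscribed osteophyte regions are then
scored by their RMS surface distance, visualised as colour-coded topographic
maps, and compared statistically. A synthetic condylar phantom stands in for
cadaveric specimens so that every stage is testable end to end.

## The depiction-accuracy metric

For a region $\Omega$ on the ground-truth surface, points $x_i$ are sampled
uniformly by area on $\Omega$ and the unsigned closest-point distance
$d(x_i, S)$ to the test surface $S$ is measured. The score is

$$\mathrm{RMS}(\Omega, S) = \sqrt{\tfrac{1}{n}\sum_i d(x_i, S)^2}.$$

Distances are exact point-to-triangle minima (face, edge and vertex cases),
accelerated by a uniform-grid spatial index whose shell-expansion query is
pruned exactly, so the accelerated result equals the brute-force minimum to
machine precision; the test suite asserts this against an independent
brute-force implementation. By Jensen's inequality the RMS dominates the
mean distance, which is also reported.

Two conventions deserve note:

* **Direction.** Sampling is anchored on the ground-truth (SLS-role)
  surface and measured toward the test model. This keeps a region's sample
  population identical across modality pairs, so CT and 3D US are scored on
  exactly the same points. A `direction = "symmetric"` option additionally
  measures the reverse direction and pools the samples.
* **Sign.** Distances are unsigned, matching absolute-error topographic
  maps. The default map bins are 0–0.5–1–2–3 mm with warm colours
  (yellow–red) for low error and cool colours (green–blue) for high error.

Sampling density defaults to 25 points/mm² with a fixed seed; `n_samples`
is recorded in every output row, and doubling the density changes the
analytic plane-pair benchmarks by well under 1%.

## Three-way registration

The CT frame is the reference (it shows the largest portion of anatomy).
The protocol is:

1. **SLS → CT initialisation** from matched anatomical landmarks, by the
   closed-form least-squares rigid fit (SVD of the cross-covariance of the
   centred point sets, reflection-corrected so the rotation determinant is
   always +1). The reported error is the fiducial registration error (FRE).
2. **Bone-only ICP refinement.** Both surfaces are cropped to their
   bone-labelled submeshes — cartilage is invisible to CT, so letting
   cartilage-covered vertices participate would bias the fit by roughly the
   cartilage thickness. The refined transform is then applied to the
   *complete* SLS model.
3. **3D US assembly and initialisation.** The medial and lateral US models
   are merged and initialised into the CT frame by screw-fiducial
   registration.
4. **Bone-only ICP of US against the registered SLS**, applied to the
   complete US model. Because it is ambiguous whether the US registration
   error should be quoted against the registered SLS (the ICP objective) or
   against CT directly, the stage report emits both.

The ICP variant is point-to-surface with a fixed, seeded sample of 2,000
source points, exact closest-point correspondences, and trimming at the
90th percentile of correspondence distances; trimming guards against
partial-overlap bias, since the US model covers only the acoustic windows.
With a fixed accepted-set size both the correspondence and the update step
are non-increasing in the trimmed RMS, so convergence is monotone (asserted
per-iteration in the tests). Iteration stops when the accepted RMS changes
by less than 1e-4 mm (well below the 0.05 mm SLS point accuracy) or after
100 iterations. Equidistant closest points resolve deterministically to the
lowest face index. Random poses are bounded to ±10° and ±5 mm — the basin
within which ICP converges reliably; anything larger is the landmark
stage's job.

## The statistical comparison

Per-region RMS records are summarised by arithmetic mean and sample
standard deviation (n−1 denominator), pooled and per specimen-side;
rounding to 2 decimals happens only at presentation. Modality pairs are
compared with Welch's unequal-variance two-sample *t* test
(Welch–Satterthwaite degrees of freedom, two-tailed p). The bundled
transcription of the cadaveric per-region values reproduces every printed
summary cell, and on the specimen-1 medial comparison gives

```{r}
rec <- osteophyte_rms_example()
ct <- rec$rms_mm[rec$specimen == "specimen1" & rec$modality_pair == "CT-SLS"]
us <- rec$rms_mm[rec$specimen == "specimen1" & rec$modality_pair == "3DUS-SLS"]
welch_test(ct, us)
```

A paired *t* test on the same four region pairs gives p ≈ 0.02, not 0.001:
the two test families genuinely disagree here, which is why the Welch form
is the default and the paired form is exposed as an explicit option
(`paired = TRUE`) rather than silently substituted. At n = 4 per group the
Welch approximation is slightly conservative (simulated null size ≈ 0.04 at
nominal 0.05); the test suite checks this calibration by Monte-Carlo and
checks the p computation itself against direct numerical integration of the
*t* density. No multiple-testing correction is applied, matching the
original analysis design.

## The synthetic phantom

`make_phantom()` builds a reduced-scale distal-femur-like ground truth from
three axis-aligned ellipsoids (two condyles, one shaft) blended by a
smooth-max with 1 mm temperature into a star-shaped radial surface. On top
of it:

* **Cartilage**: a uniform layer (default 2.3 mm, physiological femoral
  hyaline cartilage being 2.0–2.6 mm) offset along the surface normal over
  the condylar articular facets. The offset is normal, not radial, so the
  outer-to-bone distance over the articular zone equals the nominal
  thickness to machine precision on the facets; the concave intercondylar
  notch and the condyle–shaft blend valley are excluded from coverage, as
  cartilage on a concave blend cannot be thickness-exact under a normal
  offset (and anatomically belongs to the facets).
* **Osteophytes**: Gaussian bumps placed on the articular margin ring,
  graded by the ultrasound atlas convention — grade 1 (small) 1.5 mm,
  grade 2 (medium) 3 mm, grade 3 (large) 5 mm high, base width twice the
  height. The atlas is qualitative, so these sizes are a calibration
  choice, set to keep even grade-1 bumps above the US voxel size. Each bump
  has an `ossified_fraction` f: the bone surface (and hence CT) carries
  only the f-scaled core; the outer surface (and hence US and SLS) carries
  the full bump. Region labels derive from the bump footprint, so region
  area grows strictly with grade.
* **Fiducials and landmarks**: four screw-like fiducials on the shaft and
  five anatomical landmarks in cartilage-free directions, emitted by each
  simulator with Gaussian localisation noise (0.3 mm screws, 0.5 mm
  anatomical picks).

Phantom generation is deterministic; all randomness lives in the
simulators and is seeded.

### Modality simulators

* **SLS**: remeshes the outer surface at the scanner resolution and adds
  isotropic vertex noise at the 0.05 mm point accuracy, then a random
  bounded pose. Measured RMS against the truth sits in [0.03, 0.08] mm.
* **CT** (0.36 × 0.36 × 0.625 mm grid): samples binary bone occupancy —
  only the bone surface, emulating segmentation at a bone-density
  threshold, so cartilage and the cartilaginous fraction of every
  osteophyte are absent — and extracts the isosurface of the binary volume
  by marching tetrahedra. Binarising before extraction is deliberate: it
  reproduces the staircase quantisation of a thresholded scan (≈ half-voxel
  scale) rather than the unrealistically smooth surface a grey-level field
  would give.
* **3D US** (0.5 mm voxels): takes the outer surface (ultrasound sees the
  soft-tissue interface, cartilage included) restricted to medial and
  lateral wedges of ±55° about the transverse axis — the anterior patellar
  sector is absent by construction — snaps the mesh to the voxel grid with
  vertex welding (honest quantisation), and adds 0.15 mm surface noise.

Each simulator's zero-pose surface RMS is asserted to match its configured
noise/quantisation scale within 50%. With mostly-cartilaginous osteophytes
(f ≤ 0.5) the US region error is roughly the noise floor (~0.1 mm) while
the CT region error is dominated by the missing cartilaginous cap
(~2 mm), so US beats CT in every seeded repetition — the phantom
reproduces, and explains, the qualitative superiority of 3D US near
cartilage. Similarly, the CT error over the cartilage-covered articular
facets equals the cartilage thickness up to quantisation, the same
signature the topographic maps show as a green–blue band at the base of
the condyles.

### What the phantom does not emulate

No speckle or B-mode physics, no HU intensities or beam hardening, no
soft-tissue deformation, no segmentation-operator variability, and a
smooth idealised geometry rather than real trabecular margins. Passing the
phantom-based checks therefore demonstrates that the *pipeline* —
registration, distance scoring, statistics — behaves correctly under
controlled degradations of known scale; it does not by itself validate
claims about real cadaveric or in-vivo imaging.

## Problem sizes and runtime choices

The geometric defaults (0.1 mm SLS resolution) mirror the hardware the
package models, but the examples, tests and the acceptance script run a
reduced-scale phantom (condyle semi-axes ~10–16 mm) meshed at 0.5–0.8 mm
with the SLS simulator at 0.5 mm, which keeps the full Monte-Carlo suite in
the order of minutes while leaving every error scale (noise, CT/US
quantisation, cartilage thickness) at its nominal value. Registration
Monte-Carlo uses 20–50 seeded poses; the modality-ordering experiment uses
20 seeds with a one-sided sign test.

## Known limitations

* PLY is the only write format (with integer label and RGB colour
  properties); STL/OBJ are read-only, and labels survive only through PLY.
* The ICP is point-to-point on sampled correspondences; no point-to-plane
  linearisation, no overlap-aware weighting beyond quantile trimming.
* Regions are Euclidean-ball or label-footprint selections, not geodesic
  patches; on strongly folded surfaces a ball can capture faces from an
  opposing sheet.
* The Welch/paired discrepancy is surfaced, not resolved: with four
  regions per side the data cannot adjudicate between the two designs.
* Hausdorff distance and direction-resolved diameter metrics are out of
  scope, as is any volumetric osteophyte quantification.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  phantom = phantom_spec(mesh_edge_mm = 0.7),
  params = modality_params(sls = list(resolution_mm = 0.45)),
  seed = 5L, out_dir = "osteorms-out")
res <- run_pipeline(cfg)
res$registration   # stage RMS errors (sub-millimetre)
res$records        # per-region RMS, both modality pairs
res$comparison     # means/SDs and Welch tests
autoplot(res$maps$ct)
```
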