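# osteorms

Quantifying how faithfully imaging-derived bone-surface models depict knee
osteophytes.

Osteophytes — osseocartilaginous outgrowths at the bone margins — are a
hallmark of osteoarthritis, but conventional imaging depicts them
inconsistently: CT sees only the calcified skeleton, while freehand 3D
ultrasound (3D US) images the soft-tissue interface, cartilage included,
at lower resolution and with partial acoustic access. `osteorms` implements
the full validation pipeline for comparing the two against a
structured-light-scan (SLS) ground-truth surface:

- **Geometry core** — triangle meshes in mm with per-vertex tissue labels,
  PLY/STL/OBJ input (PLY output with labels and colours), and exact
  point-to-triangle-mesh distance queries through a grid-accelerated index
  that provably returns the brute-force minimum.
- **Registration** — closed-form landmark/fiducial alignment (SVD,
  reflection-corrected) and trimmed point-to-surface ICP, composed into the
  three-way protocol: SLS → CT by anatomical landmarks + bone-only ICP,
  then the merged medial/lateral 3D US model → registered SLS by screw
  fiducials + bone-only ICP, with every stage RMS reported.
- **Region analysis** — circumscribed osteophyte regions scored by the RMS
  of unsigned closest-point distances sampled on the ground-truth surface,

  $$\mathrm{RMS}(\Omega, S) = \sqrt{\tfrac1n \textstyle\sum_i d(x_i, S)^2},$$

  plus colour-coded topographic error maps (warm = low, cool = high).
- **Statistics** — mean/SD summary tables (sample SD, n−1) and Welch
  unequal-variance comparisons of the per-region error distributions, with
  a paired variant exposed explicitly.
- **Synthetic phantom** — a condylar ground truth with a 2.0–2.6 mm
  normal-offset cartilage layer and graded marginal osteophytes
  (grade 1/2/3 → 1.5/3/5 mm, each with an ossified fraction), and
  simulators for SLS (0.1 mm / 0.05 mm noise), CT (0.36/0.625 mm binary
  voxelisation + marching-tetrahedra isosurface, bone only) and 3D US
  (0.5 mm quantisation, medial/lateral windows, cartilage included).

## Worked example

Scoring the bundled cadaveric per-region RMS transcription (18 osteophyte
regions, 5 femoral sides, both modality pairs):

```r
library(osteorms)
rec <- osteophyte_rms_example()
summarize_rms(rec)
#> # A tibble: 2 × 4
#>   modality_pair     n mean_mm sd_mm
#> 1 3DUS-SLS         18   0.871 0.332
#> 2 CT-SLS           18   0.947 0.324

ct <- rec$rms_mm[rec$specimen == "specimen1" & rec$modality_pair == "CT-SLS"]
us <- rec$rms_mm[rec$specimen == "specimen1" & rec$modality_pair == "3DUS-SLS"]
welch_test(ct, us)
#> <welch_result> Welch test: t = 6.040, df = 5.98, p = 0.0009457
```

Pooled over all regions the two modalities are statistically
indistinguishable (≈0.95 vs ≈0.87 mm mean RMS); on the medial side of
specimen 1 — small, partly cartilaginous osteophytes — 3D US is
significantly more accurate (0.63 vs 1.25 mm, p = 0.001).

The same analysis runs end to end on synthetic data:

```r
res <- run_pipeline(pipeline_config(
  phantom = phantom_spec(mesh_edge_mm = 0.7),
  params = modality_params(sls = list(resolution_mm = 0.45)),
  seed = 5L, out_dir = "osteorms-out"))
res$registration
#>          stage           comparison rms_error_mm iterations converged
#> 1 sls_landmark     SLS-CT landmarks       1.1999          1      TRUE
#> 2      sls_icp               SLS-CT       0.0738         49      TRUE
#> 3  us_fiducial    3DUS-CT fiducials       0.6742          1      TRUE
#> 4       us_icp 3DUS-SLS(registered)       0.1291         41      TRUE
#> 5     us_vs_ct              3DUS-CT       0.1675         NA        NA
```

All registration stages land sub-millimetre; the output directory holds the
stage report (`table2.csv`), per-region records (`table3.csv`),
per-specimen summaries with p values (`table4.csv`), colour-map PLYs and a
JSON manifest recording the seed and every parameter. A thin CLI over the
same functions lives at `inst/scripts/osteo-pipeline.R`
(`run`/`phantom`/`stats` subcommands).

The methods vignette (`vignettes/osteophyte-depiction.Rmd`) documents the
model, the registration and sampling conventions, the phantom's
assumptions and its limits.

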