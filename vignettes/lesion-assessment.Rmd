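---
title: "Assessing focused-ultrasound ablation lesions with diffusion MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing focused-ultrasound ablation lesions with diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

MR-guided focused ultrasound (MRgFUS) deposits acoustic energy in a small
ellipsoidal "treatment cell" and coagulates the tissue inside it. In the
acute phase, before T1/T2 changes are fully established, the clearest
imaging signature of the lesion is diffusional: coagulative necrosis
restricts water motion, so diffusivity drops, diffusion-weighted volumes
attenuate less, and the lesion appears *hyperintense* on the mean
diffusion-weighted image (MDWI, the plain voxel-wise average of all DWI
volumes including the b = 0 baseline) while every tensor-derived scalar
map (FA, MD, AD, RD) and the ADC appear *hypointense*. `fusdti`
implements the complete assessment pipeline around this observation:
delineate the lesion on MDWI, quantify diffusion-metric changes in radial
layers around it, and demonstrate mechanical tract interruption with
streamline tractography.

The in-vivo datasets this workflow was designed for (piglet fornix
ablations at 1 mm isotropic resolution, one b = 0 plus 128 directions at
b = 800 s/mm^2) are not publicly deposited, so the package ships a
first-class synthetic phantom generator that emulates the acquisition and
provides exact ground truth. Every quantitative claim the test-suite
makes about the pipeline is made on that phantom; the section on
limitations below spells out what this does and does not establish about
real data.

## The forward model and tensor estimation

Signals follow the monoexponential single-tensor model
`S_i = S_0 exp(-b_i g_i' D g_i)` with `D` symmetric positive
semidefinite. `fit_tensor_loglinear()` estimates `(ln S_0, D)` per voxel
by ordinary least squares on the log-signals — the classical log-linear
fit. Design choices:

* voxels with any nonpositive intensity are marked invalid rather than
  clipped: the log is undefined there and clipping would bias the fit;
* negative eigenvalues (possible under noise) are clamped to zero after
  decomposition and the number of affected voxels is reported;
* the fit refuses rank-deficient direction schemes. Noteworthy corner
  case: the 6-point spherical-Fibonacci lattice lies on a common central
  quadric and does not determine a tensor, although generic 6-direction
  schemes do; from 7 directions on the lattice is well conditioned.

Scalar maps follow the standard definitions: AD = lambda1,
RD = (lambda2 + lambda3)/2, MD = mean(lambda),
FA = sqrt(3/2) ||lambda - mean|| / ||lambda|| (0 at the origin). On
noiseless, consistent data the log-linear system is exact and the fit
recovers eigenvalues to floating-point precision, which the tests assert
at 1e-9 relative error over random SPD tensors.

**ADC vs MD.** The pipeline computes ADC from the *direction-averaged
signal*, `ADC = -(1/b) ln(mean(S_dw)/mean(S_0))`, not from the tensor
trace. The two estimators coincide for isotropic tissue; in anisotropic
tissue the convexity of the exponential makes the signal average exceed
the attenuation of the average exponent, so ADC <= MD. Treating them as
distinct maps keeps ADC meaningful as the model-free companion to the
tensor metrics, and the inequality is asserted as a property test.

## The synthetic phantom

`phantom_spec()` / `make_phantom()` build a pre/post-treatment DWI pair
on a 64 x 80 x 56 grid of 1 mm isotropic voxels (reduced-size grids keep
the same proportional layout):

* **brain**: an ellipsoid of mildly anisotropic background tissue with
  eigenvalues (0.75, 0.70, 0.65) x 1e-3 mm^2/s (MD 0.7e-3, FA = 0.07).
  The background was chosen so its direction-averaged DWI brightness
  matches the tract's: strongly anisotropic tissue is intrinsically
  bright on MDWI (Jensen's inequality — the signal average over
  directions exceeds the attenuation at the average exponent), and a
  background much darker than the tract would hand the histogram-tail
  segmentation rule a spurious bright structure that has nothing to do
  with the lesion;
* **tract**: a C-shaped anterior-posterior tube of radius 2 mm
  (fornix analogue) with eigenvalues (1.7, 0.3, 0.3) x 1e-3
  (FA = 0.799), bending gently (curvature radius about 30 mm, far
  above the 1 mm tracking bound);
* **reference**: a small left-right oriented region with tract
  eigenvalues (splenium analogue), used for metric normalization;
* **lesion**: an ellipsoid with semi-axes (4, 4, 6) mm centered on the
  tract apex — about four times the volume of the nominal 4 x 10 mm
  treatment cell, matching the observed lesion-to-cell volume ratio.

**The lesion model.** With `s(r)` the linear radial profile
(`lesion_scale_profile()`: `core_scale` at the center rising to 1 at the
lesion boundary) the post-treatment tensor is

```
D' = s(r) * ( lambda3 I + a(r) (D - lambda3 I) )
```

where `lambda3` is the voxel's smallest eigenvalue and `a(r)` an
anisotropy-retention factor that falls linearly from 1 to 0 as the local
suppression `1 - s(r)` grows to `aniso_loss_threshold` (default 0.15).
The rationale: heat coagulation both restricts diffusion overall and
destroys the aligned microstructure that sustains fast axial diffusion,
so the model pulls the fast eigenvalues down toward the restricted
transverse level. Three properties follow by construction and are what
the assessment pipeline relies on:

1. every eigenvalue is non-increasing, so each lesion voxel attenuates
   less in *every* gradient direction and MDWI hyperintensity is exact,
   voxel by voxel — not just on average;
2. all five scalar metrics (FA included) decrease, most strongly at the
   core, reproducing the radially graded layer effect;
3. for isotropic tissue the map reduces to plain eigenvalue scaling by
   `s(r)`, and at `core_scale = 1` it is the identity (null phantom).

A model that merely multiplied all eigenvalues by `s(r)` would leave FA
untouched (FA is scale-free), which contradicts the observed FA drop in
ablated tissue and would make the tract-disruption assay vacuous.

Defaults `core_scale = 0.45` and `aniso_loss_threshold = 0.15` encode a
45% peak diffusivity suppression with complete anisotropy loss wherever
suppression exceeds 15%; in-vivo reports of acute coagulative lesions
show diffusivity drops of this order, and the threshold guarantees the
full tract cross-section inside the lesion becomes isotropic (FA below
the 0.15 tracking cutoff). The magnitudes are generator parameters, not
published values — the source study reports the layered changes only
graphically.

**Noise.** Rician, the magnitude-MR convention: two independent
Gaussian channels of standard deviation `noise_sigma` added to the
noiseless signal, `sqrt((S + n1)^2 + n2^2)`, with independent draws for
the pre and post volumes from one explicit integer seed; identical specs
reproduce bit-identical volumes. The default `s0/noise_sigma = 50`
matches a high-quality averaged acquisition; at SNR above 20 the Rician
bias of the b = 0 mean is below 1% (asserted in tests). Noise is
simulated inside the brain mask; air voxels are zero. Gradient
directions use a deterministic spherical-Fibonacci lattice (the vendor's
128-direction scheme is unpublished); its minimum pairwise angular
separation at n = 128 is 15.7 degrees.

## Lesion segmentation and layering

The lesion is delineated on the post-treatment MDWI with the
voxel-fraction rule (`select_cutoff()`): the cutoff is the smallest
intensity present in the brain such that strictly brighter voxels make
up less than 1.1% of the brain volume. The published description ties
this fraction to an inflection point in the intensity histogram; the
inflection criterion is not reproducibly specified, so the fixed
fraction is the implemented rule with the fraction configurable.
`extract_lesion()` keeps the 26-connected supra-cutoff component
containing the global intensity maximum (ties broken at the lowest
linear voxel index). 26-connectivity captures the diagonal contiguity of
a smooth blob; the one-voxel erosion and dilation in `make_layers()` use
the 6-connected structuring element instead, the closest discrete
analogue of a 1 mm radial peel at 1 mm isotropic voxels. The layers are

* **core** — one-voxel erosion of the region (partial-volume trim),
* **boundary shell** — region minus core,
* **outer shell** — one-voxel dilation minus region (peri-lesional rim).

Statistics default to these *disjoint* shells; the nested reading
(core, full region, dilated region) is available via
`build_layer_report(nested = TRUE)` since the published description is
ambiguous about which masks entered the figure-level statistics.

On the noiseless default phantom the segmented region recovers the
424-voxel ground-truth ellipsoid exactly; with SNR-50 noise the Dice
overlap stays above 0.9 (the acceptance battery requires > 0.8).

## Layer statistics

`build_layer_report()` summarizes each (timepoint, layer, metric) cell as
a raw mean and as a percentage of the same-timepoint reference-region
mean, then runs:

* paired pre-vs-post t tests per (layer, metric), Benjamini-Hochberg
  corrected across the 15-cell family (the published analysis states
  only "FDR corrected"; BH over the metric-by-layer family is the
  implemented reading);
* per-timepoint one-way ANOVA across the three layers per metric with
  Tukey HSD post-hoc contrasts;
* significance at two-sided 0.05 throughout.

**Pairing unit — read this before interpreting p-values.** The source
cohort pairs *animals* (n = 4). A single phantom provides one "animal",
so the testable surrogate pairs *voxels* within each layer between
timepoints. Voxel values within a layer are spatially structured in real
data, so voxel-level p-values must not be read as subject-level
inference; with several subjects, pass per-subject summaries to
`paired_t_test()` directly. On the phantom, voxel noise is independent
by construction and the null calibration is exact: across 200 seeded
null phantoms (`core_scale = 1`), the FDR-significant fraction stays
within binomial bounds of the nominal rate (observed about 1%, bound
0.062).

## Tractography

`track()` implements deterministic single-tensor streamline integration:
Euler steps of 0.1 mm along the principal eigenvector of the
component-wise trilinearly interpolated tensor (interpolate the six
unique elements, then decompose — smoother than nearest-neighbor
eigenvector lookup and well defined at voxel boundaries), sign-aligned
with the previous direction, tracked bidirectionally from each seed and
concatenated. Termination: FA below 0.15, grid exit, 250 mm cap, or a
per-step turning angle exceeding `2 asin(step / (2 R))` with R = 1 mm —
the exact discrete analogue of a circular arc of radius R. Streamlines
shorter than 5 mm are discarded. The published 0.15 cutoff is an
FOD-amplitude threshold from a spherical-deconvolution tracker; for the
single-tensor model the natural analogue is an FA threshold, which is
the documented (and configurable) reinterpretation here.

The disruption assay (`disruption_assay()`) seeds streamlines in a
distal tract segment (fimbria analogue) and counts how many reach a far
target beyond the lesion and how many enter the lesion core. On the
default phantom, nearly all seeds reach the target before treatment; after
treatment the isotropized core drops below the FA cutoff and no
streamline crosses — they terminate inside the lesion, reproducing the
"tracts stop at the lesion" observation.

## Numerical choices and degenerate inputs

* Cutoff selection requires at least one supra-cutoff voxel; a constant
  image raises a degenerate-image error.
* An erosion that empties the segmented region warns and returns an
  empty core rather than failing the pipeline.
* Paired tests with all-zero differences return p = 1 (vacuous truth);
  zero variance with nonzero mean is an error.
* ANOVA with numerically zero between-group variation reports F = 0,
  p = 1 rather than round-off noise.
* Seeds: one integer seed per phantom; the pipeline derives per-stage
  substreams from its global seed so stages can be rerun in isolation.
* Problem sizes used by the test-suite and the acceptance script: the
  default 64 x 80 x 56 / 129-volume phantom for segmentation, layer and
  tractography checks, and a half-scale 32 x 40 x 28 / 25-volume phantom
  for the 200-replicate null-calibration study — chosen to keep the full
  battery to a few minutes while leaving every rate estimate
  well-resolved.

## Known limitations

* The phantom has sharp tissue borders (no partial-volume mixing), no
  susceptibility or eddy distortions, no motion, and a single-shell
  scheme; passing tests demonstrate correctness of the pipeline's
  algorithms, not robustness to those real-world effects, whose
  correction is deliberately out of scope.
* The lesion model's magnitudes (`core_scale`, `aniso_loss_threshold`)
  are plausible but synthetic; only the *qualitative* published findings
  (hyperintense MDWI, all-metrics decrease graded radially, interrupted
  tracts, lesion about four times the cell volume) are reproduced
  quantitatively at desk scale.
* Single-tensor tracking cannot represent crossing fibers; the assay is
  a disruption probe, not an anatomical reconstruction.
* ADC requires a single nonzero shell by design.

## A worked run

```{r, eval = FALSE}
library(fusdti)

cfg <- default_config(out_dir = "fusdti_out", seed = 42)
res <- run_pipeline(cfg)

res$segmentation$volumes      # layer volumes + cutoff
res$report$paired             # FDR-corrected pre/post tests
res$assay                     # tract-disruption counts
```

Every output file is written next to a `.provenance.txt` sidecar echoing
the full configuration, seed, and package version, and rerunning the
same configuration reproduces byte-identical tabular outputs.
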