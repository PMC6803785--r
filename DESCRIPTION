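Package: fusdti
Title: Diffusion Tensor Assessment of Focused Ultrasound Ablation Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for acute lesion assessment after MR-guided focused
    ultrasound (MRgFUS) thermal ablation using diffusion-weighted MRI.
    Provides a seeded synthetic DWI phantom generator with a focal
    diffusivity-suppressed lesion, log-linear diffusion tensor fitting with
    scalar maps (FA, MD, AD, RD, ADC) and the mean diffusion-weighted image
    (MDWI), voxel-fraction cutoff lesion segmentation with one-voxel
    erosion/dilation layering, reference-normalized layer statistics
    (paired t tests with Benjamini-Hochberg correction, one-way ANOVA with
    Tukey HSD), and single-tensor deterministic streamline tractography
    with a tract-disruption assay. Reads and writes NIfTI-1 volumes with
    FSL-style bval/bvec gradient tables and TrackVis TRK streamlines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
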