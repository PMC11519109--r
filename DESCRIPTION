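Package: diagqm
Title: Diagnostic Quality Assessment of Accelerated MRI Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the diagnostic (rather than purely visual) quality of
    accelerated-MRI reconstruction for prostate T2-weighted imaging. Simulates
    retrospective k-space undersampling with variable-density Cartesian masks,
    reconstructs volumes naively (zero-filled inverse FFT) or with a small
    trainable convolutional encoder-decoder, runs a lesion-detection stage
    producing voxelwise likelihood heatmaps, and compares conditions with
    conventional image-quality metrics (SSIM, PSNR) versus a diagnostic-quality
    metric: the partial area under the free-response ROC curve between 0.1 and
    2.5 false positives per patient. Includes a seeded synthetic prostate
    phantom cohort generator with ground-truth lesions, FROC candidate
    extraction and 10%-overlap matching, patient-level ROC, paired permutation
    and Wilcoxon tests, and Cohen's kappa concordance analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse,
    pROC
Config/testthat/edition: 3
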