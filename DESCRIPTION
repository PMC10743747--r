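Package: lvclust
Title: Cluster-Based Post-Processing and Trabecular Quantification for
    Left-Ventricle Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for multi-class left-ventricle
    segmentation stacks from short-axis cardiac MRI. Removes segmentation
    hallucinations (typically a mislabelled right ventricle) by per-slice
    connected-component cluster generation followed by an inter-slice
    cluster-selection pass that links candidates across slices by centroid
    distance and overlap, skipping irrecoverable slices. Quantifies the
    trabecular volume percentage and applies the left-ventricular
    non-compaction decision threshold, scores segmentations with per-class
    Dice coefficients and diagnostic confusion-matrix metrics, and ships a
    synthetic short-axis phantom generator with controllable hallucinations
    so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    png,
    jsonlite,
    yaml,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    EBImage
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
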