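Package: petcad
Title: Region-Based Computer-Aided Diagnosis for Amyloid PET Volumes
Version: 0.1.0
Authors@R: person("petcad", "developers", role = c("aut", "cre"),
    email = "petcad@example.org")
Description: A region-based computer-aided diagnosis (CAD) pipeline for
    amyloid (PiB) PET-like volumes. Volumes are denoised by symlet-8
    wavelet shrinkage with SURE soft thresholding, parcellated into the
    116 regions of an AAL-style atlas, summarised per region by
    scale-normalized Laplacian-of-Gaussian blob features with automatic
    scale selection, screened by Bonferroni-corrected two-sample t-tests
    on regional mean uptake, and classified by a two-level support vector
    machine: per-region Platt-calibrated SVMs produce local abnormality
    probabilities in [0,1] which a fusion SVM combines into a global
    normal-control versus mild-cognitive-impairment call. A deterministic
    116-parcel phantom generator provides seeded synthetic cohorts so the
    whole pipeline is testable without access to clinical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
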