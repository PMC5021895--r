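Package: fuzzybias
Title: Joint Fuzzy Segmentation and Bias Field Estimation for MR Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simultaneous brain MR tissue segmentation and intensity
    inhomogeneity (bias field) correction by fuzzy c-means clustering with
    a truncated-Gaussian local constraint, a nonlocal-means global
    constraint with a per-pixel adaptive local/global weight, and a coupled
    multiplicative bias field. Includes the classical baselines (FCM,
    BCFCM, GIFP_FCM, CLIC), a synthetic multi-tissue phantom generator
    with smooth bias fields and Rician noise, Jaccard-based evaluation
    with optimal cluster-to-truth label matching, and NIfTI/PNG/TIFF
    image input and output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    Rcpp,
    RNifti,
    png,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
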