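Package: perivasc
Title: Semiautomated Quantification of White-Matter Enlarged Perivascular
    Spaces and Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multimodal (T1/T2) quantification of enlarged perivascular
    spaces (ePVS) in cerebral white matter: CSF-like candidate detection
    within a binarized white-matter mask, component-wise intensity-profile
    correlation filtering, multiscale Hessian-eigenvalue (Sato) tubularity
    filtering, density-based clustering in physical coordinates, and
    STRIVE-style size classification with mm3 volumetrics. Includes brain
    parenchymal fraction morphometry, the accompanying statistical design
    (group comparisons, standardized and interaction regressions with
    Benjamini-Hochberg false-discovery-rate control and variance-inflation
    screening), a per-analyte plasma proteomic association screen with
    PCA-based outlier handling and network hub-degree arithmetic, and a
    synthetic multimodal phantom and cohort generator with ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    car,
    optparse,
    withr,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
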