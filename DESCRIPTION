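Package: hypoxrad
Title: Longitudinal FMISO-PET Hypoxia Dynamics and Delta-Radiomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies peritherapeutic dynamics of tumor hypoxia from
    longitudinal 18F-FMISO PET imaging. Segments hypoxic sub-volumes within a
    clinician-drawn boost volume by a target-to-background-ratio threshold,
    classifies size changes (increasing/stable/decreasing hypoxia) and
    geographic changes via an overlap-based classification parameter (CP),
    extracts 130 radiomic features (first-order, shape, GLCM, GLRLM, GLSZM,
    NGTDM, with wavelet band-pass and equal-probability quantization
    variants) inside the baseline hypoxic sub-volume at each time-point, and
    relates their relative deviations (delta-radiomics) to survival and
    binary treatment outcomes with Kaplan-Meier/log-rank, Cox, Mann-Whitney,
    imbalance-adjusted bootstrap AUC, Spearman redundancy filtering,
    Benjamini-Hochberg correction, and a two-time-point confirmation rule.
    Ships a synthetic longitudinal cohort generator so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    survival,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
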