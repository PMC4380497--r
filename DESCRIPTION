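Package: hydromap
Title: Quantitative Brain Water Content Mapping on Digital Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantitative cerebral
    water content imaging at 3T. Generates seeded digital brain phantoms
    with known white matter, gray matter and cerebrospinal fluid (CSF)
    water content, simulates the multi-scan spoiled gradient-echo protocol
    used for proton-density based water mapping (PD scan, T1 scan, a
    multi-flip-angle B1+ series, low-resolution receive-field scans and a
    multi-echo T2* series), and inverts the acquisitions through the
    five-step correction chain: transmit/receive field compensation, T2*
    decay compensation, T1-saturation correction, residual bias removal
    and normalization to ventricular CSF. Downstream tools provide
    partial-volume suppression, bivariate (water, T1) Gaussian-mixture
    tissue classification, probabilistic-atlas ROI statistics, and the
    group-level statistical layer (Wilcoxon rank-sum tests, linear mixed
    models with group-by-time interactions, correlations, Cohen's d,
    Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    mclust,
    lme4,
    lmerTest,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
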