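Package: pvsmap
Title: Perivascular Space Segmentation and Regional Quantification on T2/FLAIR MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies enlarged perivascular spaces (PVS) on co-registered 3D
    T2-weighted and FLAIR MRI using multiscale Frangi vesselness filtering,
    region-aware thresholding with dual-sequence agreement inside white matter
    hyperintensities, small-cluster removal and lesion exclusion. Computes
    regional fractional PVS volumes (white matter, basal ganglia, brainstem),
    the WM/BG-PVS ratio and WMH/ICV normalisation, and provides the downstream
    statistical layer: correlation matrices, a nine-candidate normality
    transformation ladder, unadjusted and covariate-adjusted linear
    regressions, and quartile group tests. Includes a synthetic MRI phantom
    generator with exact tubular ground truth and a clinical covariate
    simulator, so the full pipeline is testable end to end without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
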