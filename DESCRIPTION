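Package: oleoflux
Title: Growth-Phase Physiology, Core-Model Flux Analysis and Absolute
    Proteomics for Oleaginous Yeast Batch Cultivations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing batch cultivations of oleaginous yeasts
    (Rhodotorula toruloides) growing on xylose: segmentation of batch
    time series into growth phases driven by nitrogen and carbon
    exhaustion, estimation of specific rates, yields, carbon balances
    and C/N ratios; a curated core stoichiometric model of xylose and
    polyol metabolism with flux balance analysis maximising non-growth
    associated ATP maintenance (NGAM), flux variability analysis,
    hit-and-run flux sampling, cofactor turnover accounting and
    branch-point partitioning; absolute protein quantification by the
    total protein approach with differential allocation, principal
    component analysis, reporter-metabolite scoring against the model's
    enzyme-metabolite graph and proteome allocation profiles; and a
    synthetic-data generator that emulates three-phase batch kinetics
    and labelled-standard proteomics with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
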