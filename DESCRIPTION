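Package: xistruct
Title: Chromosome Structure and Allelic Reactivation Analysis of the Inactive X
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for allele-resolved Hi-C and allelic
    expression/accessibility data from the inactive mouse X chromosome:
    A/B compartment calling on mega-domain-split contact matrices with
    Gaussian-mixture calibration of the first eigenvector, spatial
    subcompartment segmentation by k-means on weighted eigenvectors,
    TAD calling from insulation scores, domain-score dynamics and
    in-silico matrix mixing, saddle-plot compartmentalization strength,
    inter-mega-domain interaction fractions, and allele-specific
    expression ratios with escapee and reactivation calling. Includes
    synthetic generators that plant compartments, TADs, mega-domains,
    escapee genes and peak schedules so every stage has a
    parameter-recovery test.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust,
    igraph,
    jsonlite
Encoding: UTF-8
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
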