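Package: suppscan
Title: Genome-Wide Suppression Scans via Mediation Analysis of Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting suppression effects in genome-wide association
    scans of quantitative traits. Provides per-SNP additive linear-model
    association under configurable covariate adjustment sets (with and without
    a candidate mediator), the four-criterion mediation analysis with the Sobel
    test and classification of full mediation, partial mediation and
    suppression, sample- and SNP-level quality control (minor allele frequency,
    call rate, Hardy-Weinberg exact test), two-locus EM haplotype frequency
    estimation with linkage-disequilibrium statistics and haplotype
    association, and a synthetic cohort generator emulating the statistical
    structure of an adiponectin/HDL-C biobank study so that every stage is
    testable without access-controlled data. A pipeline orchestrator runs
    simulate, QC, scan, mediation and haplotype stages reproducibly with a
    hashed run manifest.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
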