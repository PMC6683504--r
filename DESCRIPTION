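Package: rdscreen
Title: Genomic Correlates of Recurrence in Post-Chemotherapy Residual Breast Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for residual-disease tumor genomics after neoadjuvant
    chemotherapy in triple-negative breast cancer. Calls somatic copy-number states
    on a targeted gene panel against normal-derived reference ranges, corrects
    variant allele frequencies and copy numbers for tumor purity, infers loss of
    heterozygosity from allele-frequency skew, assigns a graduated three-tier TP53
    inactivation risk stratum per patient, runs Kaplan-Meier/log-rank/proportional-
    hazards survival associations, performs a two-stage copy-number recurrence
    screen, and provides expression-side analyses (RPKM, differential expression,
    transcriptional-amplification detection, cytoband-region screens). A seeded
    synthetic-cohort generator with ground-truth labels makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
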