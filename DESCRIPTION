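Package: gvpipe
Title: Integrated Germline Variant Calling from Exome and RNA-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates per-patient variant calls from normal-tissue exome
    sequencing, tumor exome sequencing and tumor RNA sequencing to determine
    germline genotype status. Applies a coverage correction that marks
    genotypes at sites with fewer than ten reads as unknown, rescues unknown
    normal-sample statuses from the matched tumor and then RNA-seq sample,
    estimates cohort allele frequencies from genotype counts, filters on
    population minor allele frequency, and tests surviving variants for
    association with patient outcome by log-rank tests and multivariate Cox
    proportional-hazards regression. Includes a simplified count-based
    candidate caller and a synthetic-cohort generator so the whole pipeline
    runs without controlled-access data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    survival,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
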