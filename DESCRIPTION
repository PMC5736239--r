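Package: cnvcohort
Title: Cohort-Level Quantification of Absolute Copy-Number Variation and
    Copy-Neutral LOH
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Aggregates allele-specific copy-number segment calls (ASCAT or
    Sequenza segment tables) across a cohort of tumour samples into windowed
    and base-resolution copy-number matrices, estimates each sample's ploidy
    as the modal windowed copy number, classifies every genomic segment as
    gain/neutral/loss, heterozygous/homozygous, LOH or copy-neutral LOH
    relative to the sample ploidy, and summarises the cohort as stacked
    frequency tracks, Ward-linkage dendrograms and heatmaps, and region-wise
    Fisher exact comparisons of gain categories.  Includes a deterministic
    synthetic-cohort generator with planted events for validation, and
    exporters for GISTIC segmentation input and tab-delimited event tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
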