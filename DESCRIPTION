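Package: buscan
Title: Rule-Based Detection of Basal Unwinding System (BUS) Modules in
    Bacterial Replication Origins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scans predicted bacterial replication-origin (oriC) sequences
    for basal unwinding system (BUS) modules: one or two DnaA-boxes, a short
    spacer, and a run of at least three DnaA-trio trinucleotides (N-A-N).
    Provides mismatch-bounded, strand-aware motif scanning, a two-step
    candidate search with a three-step screening cascade that retains a
    single call per origin, cohort-level survey statistics (prevalence,
    tandem-box fraction, spacer distribution, per-position trio base
    frequencies, per-phylum breakdowns), a seeded synthetic-origin generator
    with planted ground truth for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
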