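Package: mutsel
Title: Selection Signatures of Somatic Mutations from Functional Impact Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies evolutionary selection acting on somatic mutations in
    tumor cohorts. Scores missense mutations with an entropy-based functional
    impact score computed from residue conservation in protein family and
    subfamily alignment columns, measures the non-uniformity of per-gene
    mutation distributions with a Simpson-diversity statistic (the ratio of
    the total to the effective number of mutated genes), quantifies
    concurrency of high-impact missense mutations with truncating mutations
    and with copy-number loss, and nominates candidate driver genes with a
    passenger-flagging rule. Includes a synthetic-cohort generator that plants
    driver genes with conserved-position mutation enrichment so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    withr,
    yaml,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
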