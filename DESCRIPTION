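Package: samqc
Title: Quality Assurance for Sequenced-Read Alignment Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale quality-assurance toolkit for SAM/BAM alignment
    files. Validates files against the SAM specification (header consistency,
    field syntax, functional relationships between fields), extracts
    biological-plausibility features (per-kilobase coverage and read
    frequency, mapping-quality summaries, mapping ratio, anomalous-chromosome
    counts, discordant-pair structural-variation scores) as compound
    key-value pairs, correlates coverage and mapping quality across read
    groups over megabase bins to expose batch effects, and assigns
    threshold-driven pass/warn/fail verdicts per file. All feature jobs run
    through a map/combine/reduce engine whose output is provably independent
    of how the input is partitioned. A deterministic synthetic-fixture
    generator plants violations of every registered rule with ground-truth
    manifests, so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
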