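Package: poolcross
Title: Outcrossing Rate Estimation from Pooled Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates plant outcrossing rates from amplicon sequencing of
    pooled progeny (seeds). Paired-end reads are assigned to amplicons by
    anchored gene-specific primer matching, trimmed to identical lengths
    across primer variants, linked into haplotype fragments and counted.
    Frequency filters remove sequencing errors and sample-private PCR
    jackpot artifacts; fragments are classified as parental or
    non-parental against leaf libraries of the maternal lines, and twice
    the mean non-parental frequency across amplicons estimates the
    outcrossing rate. Includes Welch and paired t-test comparisons, a
    seeded simulator of pooled-progeny sequencing with a configurable
    haplotype-sharing bias, and a simplified conserved-primer design
    module.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
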