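Package: methrel
Title: Probe-Level Reliability Analysis for DNA Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Test-retest reliability analysis for array-based DNA methylation.
    Estimates per-probe intraclass correlations (two-way random-effects,
    absolute-agreement, average of k = 2 measurements) from paired beta-value
    matrices, decomposes probe variance into additive-genetic, shared- and
    unique-environmental components in twin samples, tests probe sets for
    concentration at the reliable end of the ranking with a weighted
    running-sum statistic and permutation null, tallies direction-consistent
    cross-study replication of epigenome-wide association hits, relates
    reliability to external per-probe statistics such as blood-brain
    concordance, and estimates how many technical replicates are needed to
    recover the reliable-probe set. Ships a synthetic-data generator with
    known ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
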