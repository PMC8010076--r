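Package: dualquant
Title: Dual-Platform Differential Proteomics with Cross-Platform Verification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential protein abundance analysis for studies that quantify the
    same tissue on two complementary platforms: pooled isobaric-label (TMT) reporter
    channels and per-animal label-free LC-MS. Implements per-channel log2
    median-centring with a Gaussian empirical-null z-score statistic and
    Benjamini-Hochberg correction for the pooled design; median-log-ratio run
    normalization, pooled-control construction, per-protein one-way ANOVA and a
    fold-change/p/q significance cascade for the per-animal design; cross-platform
    verification of regulated proteins, evidence weighting, condition clustering and
    ratio-distribution summaries; ortholog mapping, body-fluid presence annotation
    and hypergeometric overrepresentation tests; and a synthetic-data generator with
    known spiked regulation so every stage can be benchmarked against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
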