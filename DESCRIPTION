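Package: rembench
Title: Chemical Benchmarking of Aquatic Biodegradation Rate Constants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much of the spatiotemporal variability in
    first-order aquatic biodegradation rate constants can be removed by
    chemical benchmarking, i.e. normalizing each chemical's rate constant
    to that of a reference chemical measured in the same system. Provides
    preprocessing of rate-constant tables (sorption and pH-speciation
    corrections, interquartile-range outlier removal, ecosystem-coverage
    filtering), universal and group-specific benchmarking with the REM
    variance-reduction statistic, data-dependent chemical grouping by
    Ward clustering of pairwise Pearson correlation profiles,
    data-independent grouping on structural and biotransformation-rule
    descriptor matrices, and a synthetic generator of group-structured
    rate-constant data with closed-form expectations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
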