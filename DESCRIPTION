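Package: rablhic
Title: Contact-Map Analysis Toolkit for Budding-Yeast Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of binned Hi-C contact matrices from Saccharomyces
    cerevisiae, organised around the Rabl configuration of the yeast nucleus.
    Provides HiC-Pro-style sparse matrix input/output, sequencing-depth
    equalisation by exact multivariate-hypergeometric downsampling, ICE
    iterative matrix balancing, differential log2 ratio maps, distance-decay
    contact-probability curves, short-versus-long (SVL) interaction ratios,
    centromere virtual-4C profiles, inter-centromere (CEN-CEN) aggregate
    pile-ups with central-window statistics, observed/expected transformation
    with kernel-correlation loop detection and quantification, region-restricted
    interaction scoring, and replicate agreement via Pearson correlation and the
    stratum-adjusted correlation coefficient (SCC). A synthetic generator of
    paired control/depleted Rabl-configuration contact maps with planted,
    recoverable structure makes every stage verifiable without deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
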