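Package: mfaterm
Title: Marker Frequency Analysis of Bacterial Replication Termination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates replication fork convergence points (fcp) and
    termination-zone widths (S95) on circular bacterial chromosomes from
    binned sequencing coverage of exponentially growing cultures (marker
    frequency analysis).  Coverage is trimmed, normalised and fitted with a
    two-sided piecewise log-linear (Cooper-Helmstetter) model per
    inter-origin segment; the cell-to-cell spread of convergence positions
    is modelled as a Gaussian mixture of the two arm profiles.  Supports
    multi-origin chromosomes, crtS-coupled initiation of a secondary
    chromosome, origin localisation from coverage peaks, termination
    synchrony classification, and a population-level forward simulator so
    the whole pipeline is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    GenomicRanges,
    IRanges,
    rtracklayer,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
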