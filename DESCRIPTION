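Package: unzipnuc
Title: Single-Molecule DNA Unzipping Analysis of Transcription Factor and
    Nucleosome Positions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-molecule DNA unzipping experiments in
    which force signatures report the positions of a bound transcription factor
    and a nucleosome on the same template. Provides a seeded generator of
    synthetic force-versus-position traces (naked-DNA baseline, transcription
    factor peak, two-cluster nucleosome signature, instrument shift and
    stretch), cross-correlation alignment of traces to a naked-DNA reference,
    peak detection and cluster segmentation with the field's 8 bp and 43 bp
    position-calling conventions, remodeling-ensemble simulation for
    ISW1a-like barrier centering and SWI/SNF-like factor eviction, and
    population statistics: double-Gaussian decomposition of position
    histograms, Poisson event-count fractions, equilibrium binding isotherm
    fits, and precision, accuracy, centering, directionality and eviction
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
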