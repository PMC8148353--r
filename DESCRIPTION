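Package: disctrace
Title: Agreement Analysis for Optic Disc Tracings in Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying inter-rater agreement and precision of
    hand-traced optic disc boundaries in retinal fundus images. Implements
    bounding-box Cohen's kappa on pixel masks (region and border variants),
    the dice overlap coefficient, and the average radial boundary distance
    from the reference centroid over a fixed set of directions; repairs
    misaligned tracing strokes by direct least-squares ellipse fitting
    (constrained-eigenproblem conic fit); and orchestrates full studies
    stratified by dataset and retinal condition with before/after ellipse
    fitting comparisons. Includes a synthetic observer-tracing generator
    (radial jitter, misaligned stroke arcs, condition-dependent sector bias
    emulating peripapillary atrophy confusion) so the whole pipeline is
    testable without image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
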