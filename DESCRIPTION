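Package: fractionate
Title: Simulation and Inference for One-Sided Genome Fractionation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A continuous model of fractionation, the progressive loss of
    duplicate genes after whole-genome duplication.  Deletion events arrive
    along the visible (retained) genome with exponential spacings and remove
    exponentially distributed lengths, in repeated independent sweeps.  The
    package provides a sweep-based stochastic simulator with event-counter
    bookkeeping and replenishment, closed-form results of the model (the
    visible spacing law, the geometric law for overlapping deletions, the
    event-count distribution recursion), exponential and gamma fitting of
    segment-length samples with Cullen-Frey diagnostics, empirical shape and
    rate laws for the invisible-length gamma and their recalibration, and an
    arg-min inference procedure recovering the deletion-length mean, the
    spacing mean, and the number of sweeps from observed length
    distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    fitdistrplus,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
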