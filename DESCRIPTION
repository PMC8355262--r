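Package: mitopore
Title: Analysis of Mitochondrial Permeability Transition Pore Channel
    Recordings and Bulk Permeability Transition Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Idealization and conductance statistics for single-channel
    patch-clamp recordings of the mitochondrial permeability transition
    pore (mitochondrial megachannel), together with scalar readouts for
    the bulk assays used to characterize the permeability transition:
    amplitude-histogram multi-Gaussian fitting, piecewise-constant level
    idealization, per-experiment maximal transition conductance (G_max),
    activity-conditional mean conductance (G_mean) and 4-second charge
    transfer (Q_4s) with the event-based inclusion rule; mitochondrial
    swelling fraction, calcium retention capacity, oxygen consumption
    rate summaries and calcein/TMRM timecourse quantification. Includes
    a continuous-time Markov channel gating simulator and bulk-assay
    simulators with known ground truth for recovery testing, a plain-text
    trace dialect, and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    mclust,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
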