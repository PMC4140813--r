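Package: cbopto
Title: Simulation and Analysis of Purkinje Cell Spike Trains Under
    Optogenetic Perturbation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seeded point-process simulation of cerebellar Purkinje cell
    simple and complex spike trains under four light-perturbation modes
    (direct ChR2 drive of Purkinje cells, molecular layer interneuron
    mediated suppression, slow bidirectional granule cell modulation, and
    opsin-free thermal drift), together with the spike-train statistics
    used to characterise such recordings: Purkinje cell identification via
    the climbing-fiber pause, peri-stimulus time histograms, modal
    frequency from Fourier-transformed autocorrelation histograms, CV and
    CV2 regularity, onset/offset latency estimation, and exponential
    kinetics of rate time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
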