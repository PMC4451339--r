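Package: delayrc
Title: Delay-Based Reservoir Computing with a Single Nonlinear Node
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for reservoir computing with a
    single nonlinear node subject to delayed self-feedback. Virtual nodes are
    defined by time-multiplexing the input over the delay line through a mask,
    and a linear (ridge) readout is trained on the resulting state matrix.
    Includes an Ikeda-type sin^2 node, Mackey-Glass and linear node families,
    binary/maximum-length-sequence/multi-valued input masks, matched and
    desynchronized mask timing, detection-noise emulation, task-independent
    quality measures (linear memory capacity, kernel quality rank,
    generalization rank, computational ability), synthetic benchmarks
    (NARMA-10, chaotic one-step prediction, multiclass temporal pattern
    classification), and config-driven experiment sweeps over the operating
    point and the reservoir size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
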