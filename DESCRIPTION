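Package: snnpart
Title: Partitioned Emulation and Training of Spiking Neural Networks on
    Resource-Constrained Neuromorphic Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for emulating and training spiking neural networks that
    exceed the physical size of an accelerator substrate. Provides a chip
    resource model with neuron-circuit combining arithmetic, a partition
    planner that maps layers to sequential single-substrate runs, an
    execution-instance signal-flow executor with inter-execution spike
    record/playback, a leaky integrate-and-fire emulator with ideal and
    hardware-constrained (weight-quantized, bandwidth-limited, readout-clipped)
    modes, time-to-first-spike image encoders, and surrogate-gradient
    backpropagation-through-time training with hardware-in-the-loop style
    mixed execution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
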