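Package: gradchip
Title: Digital Twin of a Multi-Drug Concentration-Gradient Microfluidic Chip
Version: 0.1.0
Authors@R:
    person("gradchip", "maintainers", email = "gradchip@example.org",
           role = c("aut", "cre"))
Description: Models a valve-controlled microfluidic chip that generates
    combinatorial drug concentration gradients across arrays of serially
    connected cell-culture chambers. Provides the chip's logical layout and
    capacity arithmetic, the combinatorial (k-control-1) valve multiplexer
    that addresses inlet channels with a minimal valve set, a calibrated
    per-pulse liquid-replacement model plus a de-novo depth-averaged
    finite-volume advection-diffusion solver for the chamber cascade,
    path-directed dose-matrix planning with the device's reporting
    conventions, and summaries of per-cell fluorescent-reporter readouts
    including a synthetic dose-response cohort generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
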