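Package: ptxseq
Title: Parallel-Transmit Pulseq Sequences: Packing, Conversion, Validation and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with parallel-transmit (pTx) RF pulses inside
    unmodified Pulseq v1.5.0 sequence files. Reads and writes the Pulseq text
    format including the derivative run-length shape codec and the signature
    section, packs and unpacks per-channel RF waveforms into single spec-compliant
    RF events via repeated time shapes, converts pulses between scanner platforms
    (channel reordering, B0-direction reversal, gradient-axis remapping, raster
    regridding), validates sequences against hardware limits, and verifies pulses
    with a multi-channel Bloch simulator: synthetic B1+ maps, flip-angle maps,
    k-space trajectories, a simulated 2D gradient-echo acquisition with
    root-sum-of-squares reconstruction, and per-channel RF power monitoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
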