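Package: effcount
Title: Effective Cell Counting in Fluorescence Micrographs of Biofilm-Embedded Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies fluorescently stained cell sub-populations (such as
    live/dead viability staining) in 2D micrographs of biofilm-embedded or
    adherent cells, where cell clumping defeats direct object counting. A
    two-step algorithm thresholds a colour channel, segments the binary mask
    into 8-connected objects, calibrates the typical single-cell area from
    objects inside a size window, and reports an effective cell count as
    total stained area divided by mean single-cell area. Includes a
    multi-threshold object-size-histogram sweep for balancing the detection
    threshold against the single-cell size window, slice-wise analysis of
    confocal Z-stacks with optional Gaussian or Sobel prefiltering,
    no-intercept regression validation statistics, a ground-truth synthetic
    micrograph generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    jpeg,
    yaml,
    optparse,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
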