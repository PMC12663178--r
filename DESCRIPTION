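Package: piuptake
Title: Spatiotemporal Propidium Iodide Uptake Analysis After Single-Bubble Cavitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies membrane permeabilization of surface-attached bacteria
    after a single microbubble cavitation event from time-lapse fluorescence
    microscopy. Provides per-cell trace extraction from image stacks
    (registration, background subtraction, autofluorescent-bead masking),
    first-order saturation-kinetics fitting of propidium iodide uptake, a
    radial inverse-distance law for final intensity, and a modified Goldman
    transport model yielding spatiotemporal permeability and membrane-damage
    fields. A synthetic-data generator emulates the statistical structure of
    the microscopy so that every stage is testable without raw image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    data.table,
    minpack.lm,
    deSolve,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
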