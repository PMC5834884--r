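Package: synapse3d
Title: Three-Dimensional Synapse Quantification for Volume Electron Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying chemical synapses in volume electron
    microscopy (FIB/SEM) stacks and for comparing groups of subjects.
    Implements Cavalieri point-count volume fractions on semithin sections,
    tissue-shrinkage and fixation-artifact corrections, unbiased 3D
    counting-frame synapse densities, synaptic apposition surface (SAS)
    morphometry including an area-based curvature index, 3D spatial
    point-pattern statistics (G, F and K functions with CSR simulation
    envelopes), nonparametric group comparisons, and a synthetic-data
    generator that emulates the statistical structure of cortical neuropil
    so the whole pipeline can be exercised and validated without microscope
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
Config/testthat/edition: 3
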