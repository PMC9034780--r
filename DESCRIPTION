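Package: scracm
Title: Subcellular Optogenetic Input Mapping of Dendritic Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for subcellular channelrhodopsin-assisted
    circuit mapping (sCRACM) of thick-tufted layer 5 pyramidal neurons:
    turns grid-stimulation voltage-clamp sweeps into per-spot synaptic
    charge measurements, builds and aligns two-dimensional input maps,
    allocates input among basal, oblique and tuft dendritic compartments
    using depth-binned morphology profiles, and tests Peters'-rule
    axo-dendritic overlap predictions against measured input profiles.
    Includes a synthetic-data generator (morphologies, laminar axon
    density profiles, simulated recording sessions with known ground
    truth) so every stage is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
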