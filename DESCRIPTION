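Package: permkin
Title: Four-Compartment Kinetics of Solute Permeation Across Lipid Vesicle Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic modelling of passive solute permeation in suspensions of
    unilamellar lipid vesicles, treating the two bilayer leaflets as explicit
    compartments so that the suspension is described by four compartments:
    outer aqueous medium, outer leaflet, inner leaflet and inner aqueous
    lumen.  Implements the dynamics of non-ionisable solutes and of weak
    acids whose neutral species alone crosses the bilayer midplane, with
    aqueous/leaflet partition and all protonation equilibria at
    quasi-equilibrium and leaflet-to-leaflet flip-flop as the single slow
    step.  Provides mono-exponential extraction of the equilibration rate
    constant from influx traces and the full family of permeability
    coefficient estimators used with liposome assays (general, beta*r/3 and
    its volume-corrected form, aqueous-only variants, and the intrinsic
    permeability defined from the flip-flop rate constant and the partition
    coefficient), together with a configuration-driven scenario runner and a
    synthetic-trace generator for fit validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
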