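Package: archdna
Title: Single-Molecule Mechanics of Architectural DNA-Binding Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward models and analysis tools for single-molecule assays of
    architectural (nucleoid-associated) DNA-binding proteins that bend, bridge
    or stiffen DNA. Implements extensible worm-like-chain force-extension
    relations and fitting, a Metropolis Monte Carlo simulator of a
    surface-tethered DNA-bead system (tethered particle motion), bead
    trajectory analysis with tether selection and population statistics,
    force-distance curve analysis including rupture (serration) detection,
    overstretching-plateau and hysteresis metrics, McGhee-von Hippel lattice
    binding isotherms mapped to concentration-dependent mechanical state, and
    seeded synthetic-data generators for every raw record type the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
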