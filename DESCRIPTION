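Package: cochstream
Title: Sound-Driven Cochlear Fluid Streaming and Inner-Ear Drug Transport
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models sound-facilitated drug transport in the cochlea. A
    parametric traveling-wave surrogate supplies deforming-wall kinematics
    for a reduced two-layer (Corti duct over scala tympani) fluid domain;
    an incompressible Navier-Stokes solver with a Darcy-permeable basilar
    membrane is run to a periodic steady state and period-averaged to
    obtain the steady streaming (drift) field; an advection-diffusion
    solver propagates a round-window solute source through the drift field
    and derives effect-time maps. The package also implements the matching
    experimental analysis chain: Teager-energy driven responses,
    75 percent-threshold effect times, swept-tone DPOAE level estimation
    with an even/odd noise floor, diffusion-trend fitting with dB
    normalization, and stratified group comparisons, together with
    synthetic-data generators for all of these inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
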