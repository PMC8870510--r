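Package: ccmsim
Title: Kinetic Simulation of Tumor Central Carbon Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic kinetic model of central carbon metabolism in fast
    proliferating (tumor) cells: glycolysis with allosterically regulated
    phosphofructokinase, the TCA cycle, a simplified electron transport chain,
    glutaminolysis, and the anaplerotic and anabolic branch points (pyruvate
    carboxylase, reductive carboxylation, malic enzyme, citrate export to
    fatty-acid synthesis). Provides a stiff ODE steady-state solver with
    Newton polishing, conservation and carbon-ledger audits, ATP-yield
    accounting, parameter sweeps with state continuation and hysteresis
    detection, phenotype-crossover mapping, named scenario presets, an
    extension with dynamic cytosolic NAD redox and the glycerol-3-phosphate
    shuttle, YAML model/configuration serialization, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
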