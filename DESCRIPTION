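Package: kpore
Title: Modelling and Analysis of Potassium-Selective Bilayer Graphene Nanopores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying artificial potassium channels built from
    carbonyl-functionalized bilayer graphene nanopores. Constructs atomic pore
    models with twisted carbonyl rings, extracts hopping barriers from
    potential-of-mean-force profiles and converts them to transition-state
    theory permeation rates and K+/Na+ selectivity ratios, fits the linear
    free-energy-barrier decomposition into hydration and carbonyl-coordination
    terms, evaluates primitive-model electrolyte thermodynamics
    (Mansoori-Carnahan-Starling-Leland hard spheres plus mean spherical
    approximation electrostatics) for salt-mixing scenarios behind
    potassium-permselective osmotic power generation, analyses tagged-particle
    trajectories (site occupancy, permeation events, hydration numbers,
    ion-water-ion triplets, water dipole switching), and provides seeded
    synthetic-data generators so every analysis stage is testable without
    molecular dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
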