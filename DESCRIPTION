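Package: bindingspace
Title: Ensemble Binding-Space Analysis of Protein-Ligand Pose Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis layer for ensemble docking studies of small-molecule
    binding, built around the allosteric recognition of amphetamine-like
    cationic ligands by transporter pockets. Provides typed geometric
    interaction fingerprints (hydrogen bonds, salt bridges, pi-pi, cation-pi)
    with per-residue occurrence profiles, binding-space parameterization of
    scored pose sets (free-energy statistics, sensitivity and displacement
    scores, leader clustering, orientation classification), a Metropolis
    Monte Carlo torsional search engine with interaction-distance
    monitoring, electrostatic complementarity scoring on solvent-accessible
    surfaces, a component-structured binding free-energy estimate, and
    correlation of computed energies with experimental potencies. Includes
    seeded generators for toy pockets, ligands and pose ensembles with
    planted statistical structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
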