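Package: cgmemb
Title: Coarse-Grained Membrane Peptide Simulation and Free-Energy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for implicit-solvent coarse-grained (CG) simulation of
    peptides in lipid bilayers and for the free-energy analytics used to
    validate CG hydrophobicity. Provides a five-type protein / nine-type
    lipid site registry with tabulated pair potentials, residue-template CG
    topology building with version-resolved site assignments, Boltzmann
    inversion and fourth-order polynomial fitting of bonded terms, a BAOAB
    Langevin dynamics engine with cell-list neighbor searching and
    center-of-mass umbrella restraints, weighted histogram analysis (WHAM)
    with split-half error estimation and profile symmetrization, and bilayer
    observables (partial densities, ester thickness, helix tilt, insertion
    metrics) together with regression of permeation free energies against
    experimental hydrophobicity scales. Synthetic fixture generators (toy
    pair tables, ideal helices, bilayer slabs, one-dimensional Boltzmann
    samplers) make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite
Config/testthat/edition: 3
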