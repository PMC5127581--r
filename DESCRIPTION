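Package: phorekit
Title: Pharmacophore-Based Virtual Screening and Enzyme Inhibition Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico ligand discovery funnel built around a five-point 3D
    pharmacophore: feature perception on small-molecule conformers, sphere-tolerance
    pharmacophore matching by least-squares rigid superposition, pose placement with
    steric clash filtering and re-checking of pharmacophore fulfillment, typed
    atom triangle (TAT) fingerprints with Tanimoto similarity and Jarvis-Patrick
    diversity clustering, and the enzyme-kinetics analyses used to characterise
    hits (Michaelis-Menten and Lineweaver-Burk fitting, inhibition-mode calling
    with Ki, four-parameter logistic IC50, mutant-control normalisation).
    Includes geometric trajectory analytics (RMSD, per-residue RMSF,
    hydrogen-bond occupancy) and synthetic-data generators with known ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    bio3d,
    minpack.lm,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
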