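Package: fragrank
Title: Fragment Dissection and Ligand Efficiency Indices for Small-Molecule
    Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical dissection of small molecules into ring systems,
    linkers, side chains, scaffolds (simplified structures) and graph
    frameworks; molecular descriptors (heavy atom count, molecular weight,
    hydrogen-bond donors and acceptors, rotatable bonds); conversion of
    binding free energies to pKi and computation of ligand efficiency
    (LE = -dG/HAC) and binding efficiency index (BEI = pKi/MW in kDa);
    normalisation, priority ordering, constitutional-isomer and isostere
    detection, and side-chain effect reports.  Includes a synthetic molecule
    generator with recorded ground-truth atom roles and additive binding
    energies for end-to-end validation, and reference tables for a set of
    BACE-1 inhibitors and their fragments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
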