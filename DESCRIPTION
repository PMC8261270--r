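Package: cimvf
Title: Corralled Vibrational-Frequency Descriptors and Receptor-Ligand
    Contact Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for discriminating olfactory-receptor agonists from
    non-agonists using molecular vibrational spectra. Converts per-molecule
    normal-mode (wavenumber, intensity) lists into the corralled intensity of
    molecular vibrational frequency (CIMVF) descriptor, a fixed-length vector
    of intensity sums over 5 cm^-1 wavenumber bins spanning 0-4,000 cm^-1.
    Ranks corrals by information gain in bits, classifies ligand panels under
    leave-one-out cross-validation, and measures minimum ligand-to-residue
    distances between docked ligand poses (SDF/PDB) and a receptor structure
    (PDB). Includes seeded generators for class-labelled synthetic spectra and
    receptor/pose coordinate fixtures with known ground truth, standing in for
    upstream quantum-chemistry and docking outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
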