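Package: dockcsp
Title: Contact Classification of Docked Protein-Ligand Complexes and NMR
    Chemical Shift Perturbation Consistency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validates predicted protein-ligand docking poses against
    solution NMR evidence. Enumerates receptor-ligand heavy-atom contacts,
    classifies them into moderate hydrogen-bond, weak hydrogen-bond/van der
    Waals and hydrophobic distance classes, and aggregates per-residue
    interaction profiles, binding ranges and hotspot residues. Computes
    combined amide chemical shift perturbations (CSP) from free/bound
    1H-15N shift tables, locates the significant perturbation range and
    peak residue, ranks ligands by perturbation strength, and cross-checks
    the docking-derived binding map against the CSP profile. Includes
    readers for PDB and mmCIF structures with per-residue pLDDT confidence
    summaries, synthetic toy-complex and CSP-titration generators with
    analytically known ground truth, and transcribed reference fixtures
    for the polysialyltransferase ST8Sia4 inhibitor systems (CMP, low
    molecular weight heparin, LFcinB11).
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
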