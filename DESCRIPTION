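Package: spacerfold
Title: Secondary-Structure Constraint Analysis of Ribosomal Internal
    Transcribed Spacers
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tests whether nuclear ribosomal internal transcribed spacers
    (ITS1/ITS2) are under selective constraint for secondary structure.
    Folds RNA sequences into minimum-free-energy secondary structures
    under a nearest-neighbor thermodynamic model, enumerates energy-banded
    ensembles of suboptimal structures, censuses hairpins, stems and
    paired bases, generates GC- and length-matched random null sequences,
    compares structural metrics between sequence classes with two-way
    analysis of variance, and maps hairpin counts onto a phylogeny with
    Fitch-Hartigan parsimony ancestral-state reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    car,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
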