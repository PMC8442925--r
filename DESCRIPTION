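Package: coapep
Title: De Novo Design and Analysis of Charge-Complementary Coassembling
    Beta-Sheet Peptide Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for discovering pairs of charge-complementary 11-residue
    peptides predicted to coassemble into two-layer beta-sheet fibrils while
    remaining unassembled alone.  Provides a constrained peptide sequence
    space (HP pattern, composition and charge rules), a Metropolis Monte
    Carlo sequence-design engine minimising a combined score of per-peptide
    fibril binding energy and intrinsic self-aggregation propensity, a
    sequence-based amyloidogenicity screen, an idealized two-layer
    antiparallel beta-sheet scaffold builder, orientation and composition
    analysis of multi-chain assembly structures, and quantitative peak
    fitting of 1D NMR spectra for nanofiber composition ratios and
    linewidths.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
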