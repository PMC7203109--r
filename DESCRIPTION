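Package: rbrid
Title: RNA-Binding Region Identification from 4SU Cross-Linking Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of RBR-ID experiments, which locate RNA-binding
    regions (RBRs) of a protein from the depletion of RNA-crosslinked
    peptides in mass spectrometry. Reads replicated +/-4SU peptide
    intensity tables (generic TSV or MaxQuant peptides.txt), normalizes
    by run totals, computes per-peptide log2 depletion ratios, Student
    t-test P values and RBR-ID scores, projects peptide scores onto
    protein residues, smooths the residue track with a from-scratch
    implementation of Friedman's variable-span super smoother, and calls
    candidate RNA-binding segments. A fully seeded synthetic-experiment
    generator (in-silico tryptic digestion, log-normal abundances,
    planted depletion, intensity-dependent dropout) supports end-to-end
    calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
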