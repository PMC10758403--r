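Package: cpcub
Title: Codon Usage Bias Analysis for Chloroplast Protein-Coding Genes
Version: 0.1.0
Authors@R: person("cpcub", "maintainers", email = "cpcub@example.org", role = c("aut", "cre"))
Description: Tools for analysing synonymous codon usage in chloroplast
    protein-coding sequences: nucleotide composition (GC1/GC2/GC3/GC3s),
    relative synonymous codon usage (RSCU), the effective number of codons
    (ENc) with Wright's expected-ENc curve, the codon adaptation index (CAI),
    parity rule 2 (PR2) bias coordinates, neutrality-plot regression,
    optimal-codon calling from high/low-expression gene sets, FPKM
    quantification from count tables, and classification of C-to-U RNA
    editing effects. Includes seeded synthetic-data generators for
    mutation-driven and selection-driven codon usage regimes, a pipeline
    runner and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
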