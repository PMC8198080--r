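Package: cubtools
Title: Codon Usage Bias Analysis for Coding Sequence Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for codon usage bias analysis of protein-coding
    sequences: nucleotide composition by codon position, dinucleotide odds
    ratios, relative synonymous codon usage (RSCU) with cross-species averaging
    and clustering, Wright's effective number of codons (ENc) with the expected
    ENc-GC3 curve, the codon adaptation index (CAI), the P2 translational
    selection index, neutrality and parity-rule-2 diagnostics of mutation
    versus selection, Kimura two-parameter distances with neighbor-joining
    tree construction, and matching of preferred codons to isoacceptor tRNA
    gene pools. Includes a synthetic coding-sequence generator with known
    codon-usage structure so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Biostrings, stats, utils
Suggests: testthat (>= 3.0.0), ape, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
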