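Package: mitocodon
Title: Codon Usage Bias Analysis for Mitochondrial Protein-Coding Genes
Version: 1.0.0
Authors@R:
    person("Mitocodon", "Maintainers", email = "mitocodon@example.org",
           role = c("aut", "cre"))
Description: Computes relative synonymous codon usage (RSCU), GC content at
    synonymous third codon positions (GC3s), Wright's effective number of
    codons (ENC) with the mutation-only expected-ENC null curve, and an
    ENC-ratio screen for selection on codon usage, under the invertebrate
    mitochondrial genetic code (NCBI translation table 5) or the standard
    code. Includes nucleotide-composition and sliding-window skew profiles
    for mitogenomes, a cross-species comparative layer (species-by-codon
    RSCU matrices, frequent/infrequent codon partition, hierarchical
    clustering, paired RSCU t-tests, selection tallies), readers for
    multi-FASTA and GenBank flat-file CDS sets, a synthetic CDS generator
    with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    optparse,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
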