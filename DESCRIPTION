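Package: mitocomp
Title: Comparative Mitogenomics of Annotated Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated circular mitochondrial
    genomes, built around the 37-gene avian gene arrangement. Parses gene
    feature tables and GenBank-style flat files, extracts strand-correct gene
    sequences from circular coordinates, computes codon usage and relative
    synonymous codon usage (RSCU) under the vertebrate mitochondrial code with
    truncated-stop handling, base composition and AT/GC strand skews,
    nucleotide diversity and variable sites from gene alignments, and
    Nei-Gojobori Ka/Ks with Jukes-Cantor correction. Includes a codon-model
    mitogenome simulator with known per-gene omega for ground-truth validation,
    and a supermatrix concatenation step emitting partition files for
    phylogenetic inference.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
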