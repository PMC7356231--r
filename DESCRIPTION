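Package: mytifam
Title: Comparative Genomics of Hypervariable Antimicrobial Peptide Gene
    Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully scriptable pipeline for the comparative
    genomics of multi-copy, hypervariable antimicrobial peptide (AMP) gene
    families across individual genome assemblies, modelled on the myticins
    of the Mediterranean mussel.  Provides locus mining by six-frame
    translated Smith-Waterman search, variant dereplication and
    classification by open-reading-frame and cysteine-array rules, greedy
    identity clustering with codon consensus, presence/absence variation
    (PAV) matrices and statistics, mature-peptide biophysics (isoelectric
    point, net charge, sliding-window pI profiles), Jukes-Cantor /
    neighbor-joining trees, a counting-based per-site selection test,
    ungapped promoter motif discovery by expectation maximisation under a
    zero-or-one-occurrence-per-sequence model, and expression / RNA-editing
    assessment by exact-match read coverage.  A synthetic gene-family
    generator with a full ground-truth table allows every stage to be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
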