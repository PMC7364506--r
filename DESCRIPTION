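Package: homeoprimer
Title: Homologue-Specific Primer Design for Gene Cloning in Polyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated design of homologue-specific PCR primer pairs for
    cloning complete genes in polyploid genomes. Given a gene sequence and
    one or more genome assemblies, the package locates the gene and its
    close homologues (homeologues and paralogues), builds a multiple
    sequence alignment, mines it for single-nucleotide polymorphisms that
    discriminate the target copy from every off-target copy, and anchors
    primer 3' termini on those sites so that only the target locus
    amplifies. Overlapping products are chosen by a shortest-path
    optimisation to tile the whole input sequence, internal primers are
    added for Sanger sequencing of long products, and every design is
    checked by an in-silico PCR model that enforces 3'-terminal match
    specificity. A synthetic polyploid genome generator with a recorded
    mutation truth table makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    optparse,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
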