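Package: snoverify
Title: Identification, Classification and Target Validation of Box C/D snoRNA Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating box C/D small nucleolar RNA (snoRNA) genes in
    vertebrate genomes and for telling genes from pseudogenes. Detects the
    conserved C (RUGAUGA), D (CUGA), C'/D', H (ANANNA) and ACA boxes by
    degenerate-consensus scanning, finds the terminal stem formed by short
    inverted repeats, predicts 2'-O-methylation target sites from the
    antisense element by the four-nucleotide D/D'-box offset rule, and
    validates claimed guide/target assignments against that rule. A relaxed
    seeded local-alignment search (word size 3, cheap gaps) locates snoRNA
    homologs in host-gene introns or genome-wide; genomic context
    (intronic/exonic/intergenic) and box/stem/element integrity feed a
    reason-coded gene-versus-pseudogene classifier and per-family census.
    Includes a species-prefix nomenclature generator for homologs of human
    snoRNAs, a seeded synthetic-fixture generator (toy genomes with truth
    tables), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    optparse,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
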