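Package: pgtools
Title: Proteogenomic Search Databases and Novel-Peptide FDR from RNA-Seq Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds customized protein search databases for shotgun proteomics by
    layering RNA-Seq evidence on a reference genome and proteome: single-nucleotide
    variants and INDELs from VCF are projected onto coding sequences to emit variant
    proteins, splice junctions from BED12 are translated across the junction, and
    novel or de novo assembled transcripts are translated in three or six frames or
    by longest open reading frame. Reversed-sequence decoys are appended and the
    database written as annotated FASTA. Peptide-spectrum matches from an external
    search engine are post-processed with a class-separate false discovery rate
    estimator for novel peptides, filtered at a score threshold, classified as
    variants of existing genes or products of novel genes, and canonical peptides
    are assembled into a minimal protein list by parsimony. A synthetic-data module
    generates internally consistent toy inputs with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    xml2,
    graphics,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
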