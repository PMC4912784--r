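vcf_file <- function(rows) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", rows), path)
  path
}

test_that("read_vcf splits multi-allelic lines and applies FILTER policy", {
  path <- vcf_file(c(
    "chr1\t5\trs1\tA\tG\t50\tPASS\t.",
    "chr1\t9\t.\tC\tG,T\t50\t.\t.",
    "chr1\t20\trs3\tA\tG\t50\tq10\t."))
  v <- read_vcf(path)
  expect_equal(nrow(v), 3L)  # q10 dropped, multi-allelic split
  expect_equal(v$pos[1], 5L)
  expect_equal(v$var_type, c("SNV", "SNV", "SNV"))
  expect_equal(sort(v$alt[v$pos == 9]), c("G", "T"))

  expect_equal(nrow(read_vcf(path, keep_filters = NULL)), 4L)

  path2 <- vcf_file("chr1\t5\tsv1\tA\t<DEL>\t50\tPASS\t.")
  expect_warning(v2 <- read_vcf(path2), "symbolic")
  expect_equal(nrow(v2), 0L)
})

test_that("read_vcf classifies variant types by allele lengths", {
  path <- vcf_file(c(
    "chr1\t5\tsnv\tA\tG\t50\tPASS\t.",
    "chr1\t7\tins\tA\tAGG\t50\tPASS\t.",
    "chr1\t9\tdel\tATT\tA\t50\tPASS\t."))
  v <- read_vcf(path)
  expect_equal(v$var_type, c("SNV", "INS", "DEL"))
})

test_that("SNV projection assigns missense/synonymous/intronic effects", {
  ref <- toy_reference()
  # codon 2 of gene A is GCC (Ala); genomic offset 14 is its middle base
  mis <- data.frame(chrom = "chrT", pos = 15L, ref = "C", alt = "T",
                    variant_id = "v1", var_type = "SNV")
  e <- project_variant(mis, ref$txA, ref$genome)
  expect_equal(e$effect_class, "missense")
  expect_equal(e$cds_position, 4L)
  # the two codons, translated by the independent oracle
  expect_equal(e$ref_aa, oracle_translate("GCC"))
  expect_equal(e$alt_aa, oracle_translate("GTC"))
  expect_equal(e$alt_protein, "MVDK")

  syn <- data.frame(chrom = "chrT", pos = 16L, ref = "C", alt = "A",
                    variant_id = "v2", var_type = "SNV")
  expect_equal(project_variant(syn, ref$txA, ref$genome)$effect_class,
               "synonymous")

  intronic <- data.frame(chrom = "chrT", pos = 25L,
                         ref = substring(ref$genome, 25, 25), alt = "A",
                         variant_id = "v3", var_type = "SNV")
  if (intronic$alt == intronic$ref) intronic$alt <- "C"
  expect_null(project_variant(intronic, ref$txA, ref$genome))
})

test_that("a 1-bp coding deletion is a frameshift matching re-translation", {
  ref <- toy_reference()
  del <- data.frame(chrom = "chrT", pos = 14L,
                    ref = substring(ref$genome, 14, 15),
                    alt = substring(ref$genome, 14, 14),
                    variant_id = "d1", var_type = "DEL")
  e <- project_variant(del, ref$txA, ref$genome)
  expect_equal(e$effect_class, "frameshift")
  # independent re-translation of the edited coding sequence
  edited <- paste0(substr(ref$cdsA, 1, 4), substr(ref$cdsA, 6, nchar(ref$cdsA)))
  expect_equal(e$alt_protein, oracle_translate(edited, to_first_stop = TRUE))
})

test_that("minus-strand SNVs are projected strand-aware", {
  ref <- toy_reference()
  # codon 2 of gene B is AAA (Lys); coding offset 4 maps to plus offset 10
  g0 <- ref$txB$cds$start + 10L
  snv <- data.frame(chrom = "chrT", pos = g0 + 1L,
                    ref = substring(ref$genome, g0 + 1L, g0 + 1L),
                    alt = "G",  # plus-strand G = coding C
                    variant_id = "m1", var_type = "SNV")
  expect_equal(snv$ref, "T")
  e <- project_variant(snv, ref$txB, ref$genome)
  expect_equal(e$effect_class, "missense")
  expect_equal(e$cds_position, 4L)
  expect_equal(e$ref_aa, "K")
  expect_equal(e$alt_aa, "T")
})

test_that("strand symmetry: mirrored plus-strand fixture gives the same effect", {
  ref <- toy_reference()
  Lg <- nchar(ref$genome)
  mirrored <- stats::setNames(oracle_revcomp(unname(ref$genome)), "chrT")
  exons_m <- data.frame(start = Lg - rev(ref$txB$exons$end),
                        end = Lg - rev(ref$txB$exons$start))
  txB_m <- transcript_model("txB", "geneB", "chrT", "+", exons_m, exons_m)
  expect_equal(translate(cds_sequence(txB_m, mirrored), to_first_stop = TRUE),
               ref$protB)

  g0 <- ref$txB$cds$start + 10L
  snv <- data.frame(chrom = "chrT", pos = g0 + 1L, ref = "T", alt = "G",
                    variant_id = "m1", var_type = "SNV")
  snv_m <- data.frame(chrom = "chrT", pos = Lg - g0, ref = "A", alt = "C",
                      variant_id = "m1", var_type = "SNV")
  e <- project_variant(snv, ref$txB, ref$genome)
  e_m <- project_variant(snv_m, txB_m, mirrored)
  expect_equal(e_m[c("cds_position", "ref_aa", "alt_aa", "effect_class",
                     "alt_protein")],
               e[c("cds_position", "ref_aa", "alt_aa", "effect_class",
                   "alt_protein")])
})

test_that("applying a variant and its inverse recovers the reference protein", {
  ref <- toy_reference()
  snv <- data.frame(chrom = "chrT", pos = 15L, ref = "C", alt = "T",
                    variant_id = "v1", var_type = "SNV")
  e <- project_variant(snv, ref$txA, ref$genome)
  mutated <- ref$genome
  substring(mutated, 15, 15) <- "T"
  inv <- data.frame(chrom = "chrT", pos = 15L, ref = "T", alt = "C",
                    variant_id = "v1r", var_type = "SNV")
  e_back <- project_variant(inv, ref$txA, mutated)
  expect_equal(e_back$alt_protein, ref$protA)
  expect_equal(e_back$ref_protein, e$alt_protein)
})

test_that("variant entries: substitutions, suppression rules, counts", {
  ref <- toy_reference()
  mk_snv <- function(pos, refb, altb, id)
    data.frame(chrom = "chrT", pos = pos, ref = refb, alt = altb,
               variant_id = id, var_type = "SNV")
  effects <- list(
    project_variant(mk_snv(15L, "C", "T", "v1"), ref$txA, ref$genome),  # missense
    project_variant(mk_snv(16L, "C", "A", "v2"), ref$txA, ref$genome),  # synonymous
    NULL)                                                               # no overlap
  entries <- build_variant_entries(effects, ref$txA, ref$genome, min_len = 4L)
  n_nonsyn <- sum(vapply(effects, function(e)
    !is.null(e) && !e$effect_class %in% c("synonymous", "noncoding"), logical(1)))
  expect_equal(nrow(entries), n_nonsyn)  # count conservation
  expect_equal(entries$sequence, "MVDK")
  expect_equal(entries$category, "SAP")
  expect_match(entries$accession, "^VAR\\|SAP\\|v1\\|txA\\|4:A>V$")

  # Hamming distance to the reference protein is exactly 1 at the recorded spot
  d <- strsplit(entries$sequence, "")[[1]] != strsplit(ref$protA, "")[[1]]
  expect_equal(sum(d), 1L)
  expect_equal(which(d), 2L)  # cds_position 4 -> codon 2

  # short products are suppressed under the default minimum length
  expect_equal(nrow(build_variant_entries(effects, ref$txA, ref$genome,
                                          min_len = 7L)), 0L)
})

test_that("variants straddling a CDS/intron boundary are dropped as noncoding", {
  ref <- toy_reference()
  # deletion spanning the end of exon 1 of gene A into the intron
  del <- data.frame(chrom = "chrT", pos = 18L,
                    ref = substring(ref$genome, 18, 21),
                    alt = substring(ref$genome, 18, 18),
                    variant_id = "dx", var_type = "DEL")
  expect_warning(e <- project_variant(del, ref$txA, ref$genome), "boundary")
  expect_equal(e$effect_class, "noncoding")
  expect_equal(nrow(build_variant_entries(list(e), ref$txA, ref$genome)), 0L)
})
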