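test_that("frames_of yields 3 frames stranded, 6 unstranded", {
  expect_equal(nrow(frames_of("ATGGCC", stranded = TRUE)), 3L)
  fr <- frames_of("ATGGCC", stranded = FALSE)
  expect_equal(nrow(fr), 6L)
  expect_equal(fr$reading[4], oracle_revcomp("ATGGCC"))
  # frames shorter than one codon translate to nothing
  short <- frames_of("ATG", stranded = TRUE)
  expect_equal(translate(short$reading[2]), "")
})

test_that("six-frame output equals forward plus reverse-complement three-frame", {
  set.seed(41)
  for (i in 1:20) {
    s <- random_dna(sample(30:90, 1))
    six <- frames_of(s, stranded = FALSE)
    fwd <- frames_of(s, stranded = TRUE)
    rev <- frames_of(oracle_revcomp(s), stranded = TRUE)
    expect_equal(six$reading[1:3], fwd$reading)
    expect_equal(six$reading[4:6], rev$reading)
    expect_equal(six$frame, c(fwd$frame, rev$frame + 3L))
  }
})

test_that("stop-to-stop fragmentation filters by length and strips stops", {
  # frame 0 of this sequence translates to MAAA*KKKKKKK
  s <- paste0("ATG", "GCTGCCGCA", "TAA", strrep("AAA", 7))
  e <- stop_to_stop_fragments(s, "t1", translation_policy("three_frame", 7L))
  expect_equal(e$sequence[e$accession == "VAR|NTX|t1|frame0|frag1"], "KKKKKKK")
  expect_false(any(grepl("*", e$sequence, fixed = TRUE)))

  all_stop <- strrep("TAA", 5)
  e2 <- stop_to_stop_fragments(all_stop, "t2",
                               translation_policy("three_frame", 1L))
  expect_false(any(e2$frame == 0L))
})

test_that("fragmentation agrees with a regex split oracle on random input", {
  set.seed(42)
  for (i in 1:30) {
    s <- random_dna(300)
    pol <- translation_policy("six_frame", min_protein_len = 5L)
    e <- stop_to_stop_fragments(s, "tx", pol)
    expected <- unlist(lapply(0:5, function(f) {
      src <- if (f < 3) s else oracle_revcomp(s)
      aa <- oracle_translate(substr(src, f %% 3 + 1, nchar(src)))
      frags <- strsplit(aa, "*", fixed = TRUE)[[1]]
      frags[nchar(frags) >= 5]
    }))
    expect_equal(sort(e$sequence), sort(unname(expected)))
  }
})

test_that("longest_orf matches the spec examples and tie rules", {
  pol <- translation_policy("longest_orf", min_protein_len = 1L)
  orf <- longest_orf("AAATGGCCGCCTAAA", pol, stranded = TRUE)
  expect_equal(orf$protein, "MAA")
  expect_equal(orf$frame, 2L)

  expect_null(longest_orf("AAACCCGGGTTT", pol, stranded = TRUE))  # no ATG

  # equal-length ORFs in frames 0 and 2: frame 0 wins
  tie <- paste0("ATGAAATAA", "CCATGGCTTAAC")
  o <- longest_orf(tie, pol, stranded = TRUE)
  expect_equal(o$frame, 0L)
  expect_equal(o$protein, "MK")
})

test_that("longest_orf dominates an exhaustive enumerator on random input", {
  set.seed(43)
  for (req in c(TRUE, FALSE)) {
    pol <- translation_policy("longest_orf", 1L, orf_requires_start = req)
    for (i in 1:60) {
      s <- random_dna(sample(40:120, 1))
      orf <- longest_orf(s, pol, stranded = FALSE)
      all_orfs <- oracle_orfs(s, requires_start = req, stranded = FALSE)
      if (is.null(orf)) {
        expect_equal(length(all_orfs), 0L)
      } else {
        best <- max(vapply(all_orfs, function(o) nchar(o$protein), integer(1)))
        expect_equal(nchar(orf$protein), best)
        expect_equal((orf$nt_end - orf$nt_start) %% 3L, 0L)
        expect_true(orf$protein %in%
                      vapply(all_orfs, `[[`, character(1), "protein"))
      }
    }
  }
})

test_that("novel transcript entries carry gene-overlap metadata", {
  ref <- toy_reference()
  # an intergenic transcript in the trailing tail of the toy genome
  n <- nchar(ref$genome)
  ntx_free <- transcript_model("n1", "ng1", "chrT", "+",
                               data.frame(start = n - 9L, end = n))
  ntx_hit <- transcript_model("n2", "ng2", "chrT", "+",
                              data.frame(start = 10L, end = 25L))
  e <- novel_transcript_entries(list(ntx_free, ntx_hit), ref$genome,
                                annotation = list(ref$txA, ref$txB),
                                min_len = 1L)
  ov <- vapply(strsplit(e$provenance, ";"), function(p)
    sub("gene_overlap=", "", p[grepl("gene_overlap=", p)]), character(1))
  expect_true(all(ov[grepl("\\|n1\\|", e$accession)] == "no"))
  expect_true(all(ov[grepl("\\|n2\\|", e$accession)] == "yes"))
})

test_that("de novo contigs translate in six frames with ORF mode available", {
  ref <- toy_reference()
  contig <- paste0("CCCC", ref$cdsA, "GGGG")
  e6 <- novel_transcript_entries(genome = ref$genome, denovo = c(d1 = contig),
                                 min_len = 4L)
  expect_true(any(grepl(ref$protA, e6$sequence, fixed = TRUE)))
  eo <- novel_transcript_entries(genome = ref$genome, denovo = c(d1 = contig),
                                 mode = "longest_orf", min_len = 4L)
  expect_equal(nrow(eo), 1L)
  expect_equal(eo$sequence, ref$protA)
})
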