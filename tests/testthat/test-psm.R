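small_db <- function() {
  ref <- data.frame(
    accession = c("P1", "P2"),
    sequence = c("MADKILVANDPEPTIDE", "MKCRWWLLSEQVENCE"),
    category = "REF", provenance = "source=test", stringsAsFactors = FALSE)
  var <- data.frame(
    accession = c("VAR|SAP|v1|t1|4:A>V", "VAR|NTX|n1|frame0|frag1",
                  "VAR|NTX|n2|frame0|frag1", "VAR|JUC|j1|c:5-9|frame0|strand+"),
    sequence = c("MVDKILVANDPEPTIDE", "KKKKWKKK", "QQQQFQQQ", "MVDKHHHH"),
    category = c("SAP", "NTX", "NTX", "JUC"),
    provenance = c("x=1", "gene_overlap=no", "gene_overlap=yes", "x=1"),
    stringsAsFactors = FALSE)
  add_decoys(assemble(ref, var, dedup = FALSE))
}

psm_row <- function(spectrum, peptide, proteins, evalue, charge = 2L)
  data.frame(spectrum = spectrum, peptide = peptide, proteins = proteins,
             evalue = evalue, charge = charge, stringsAsFactors = FALSE)

test_that("PSM table reading: scores, best-per-spectrum, decoy flag, errors", {
  tab <- rbind(
    psm_row("s1", "ADKILV", "P1", 0.25),
    psm_row("s2", "ADKILV", "P1", 1e-3),
    psm_row("s2", "MVDKIL", "VAR|SAP|v1|t1|4:A>V", 1e-5),
    psm_row("s3", "EDITPE", "REV_P1;REV_VAR|SAP|v1|t1|4:A>V", 1e-2))
  path <- write_psm_tsv(tab, tempfile(fileext = ".tsv"))
  p <- read_psm_table(path)
  expect_equal(nrow(p), 3L)
  expect_equal(p$score[p$spectrum_id == "s1"], 2)      # -log2(0.25)
  expect_equal(p$peptide[p$spectrum_id == "s2"], "MVDKIL")  # best e-value kept
  expect_true(p$is_decoy[p$spectrum_id == "s3"])
  expect_false(any(p$is_decoy[p$spectrum_id != "s3"]))

  bad <- tab[, setdiff(names(tab), "charge")]
  pb <- write_psm_tsv(bad, tempfile(fileext = ".tsv"))
  expect_error(read_psm_table(pb), "missing column")

  neg <- psm_row("s1", "AAA", "P1", 0)
  pn <- write_psm_tsv(neg, tempfile(fileext = ".tsv"))
  expect_error(read_psm_table(pn), "positive")
})

test_that("the mzIdentML subset reader recovers peptides and accessions", {
  mzid <- tempfile(fileext = ".mzid")
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<MzIdentML xmlns="http://psidev.info/psi/pi/mzIdentML/1.1">
 <SequenceCollection>
  <DBSequence id="DBS_1" accession="P1"/>
  <DBSequence id="DBS_2" accession="REV_P1"/>
  <Peptide id="PEP_1"><PeptideSequence>ADKILV</PeptideSequence></Peptide>
  <Peptide id="PEP_2"><PeptideSequence>EDITPE</PeptideSequence></Peptide>
  <PeptideEvidence id="PE_1" dBSequence_ref="DBS_1"/>
  <PeptideEvidence id="PE_2" dBSequence_ref="DBS_2"/>
 </SequenceCollection>
 <DataCollection><AnalysisData><SpectrumIdentificationList>
  <SpectrumIdentificationResult id="SIR_1" spectrumID="scan=1">
   <SpectrumIdentificationItem id="SII_1" chargeState="2" peptide_ref="PEP_1">
    <PeptideEvidenceRef peptideEvidence_ref="PE_1"/>
    <cvParam accession="MS:1002053" name="MS-GF:EValue" value="0.25"/>
   </SpectrumIdentificationItem>
  </SpectrumIdentificationResult>
  <SpectrumIdentificationResult id="SIR_2" spectrumID="scan=2">
   <SpectrumIdentificationItem id="SII_2" chargeState="3" peptide_ref="PEP_2">
    <PeptideEvidenceRef peptideEvidence_ref="PE_2"/>
    <cvParam accession="MS:1002053" name="MS-GF:EValue" value="0.5"/>
   </SpectrumIdentificationItem>
  </SpectrumIdentificationResult>
 </SpectrumIdentificationList></AnalysisData></DataCollection>
</MzIdentML>', mzid)
  p <- read_psm_table(mzid, dialect = "mzid")
  expect_equal(nrow(p), 2L)
  expect_equal(p$peptide, c("ADKILV", "EDITPE"))
  expect_equal(p$proteins, c("P1", "REV_P1"))
  expect_equal(p$score, c(2, 1))
  expect_equal(p$is_decoy, c(FALSE, TRUE))
})

test_that("novelty flagging maps peptides against the reference space", {
  db <- small_db()
  tab <- rbind(
    psm_row("s1", "ADKILV", "P1", 1e-3),                       # canonical
    psm_row("s2", "MVDKIL", "VAR|SAP|v1|t1|4:A>V", 1e-4),      # SAP only
    psm_row("s3", "KKKWKK", "VAR|NTX|n1|frame0|frag1", 1e-4),  # NTX only
    psm_row("s4", "EDITPE", "REV_P1", 1e-2))                   # decoy (REF parent)
  p <- flag_novelty(read_psm_table(write_psm_tsv(tab, tempfile())), db)
  expect_equal(p$is_novel[p$spectrum_id == "s1"], FALSE)
  expect_equal(p$is_novel[p$spectrum_id == "s2"], TRUE)
  expect_equal(p$novel_class[p$spectrum_id == "s2"], "SAP")
  expect_equal(p$novel_class[p$spectrum_id == "s3"], "NTX")
  expect_false(p$is_novel[p$spectrum_id == "s4"])  # decoy of a REF entry

  dn <- psm_row("s5", "HHHHKD", "REV_VAR|JUC|j1|c:5-9|frame0|strand+", 1e-2)
  p2 <- flag_novelty(read_psm_table(write_psm_tsv(rbind(tab, dn), tempfile())), db)
  expect_true(p2$is_novel[p2$spectrum_id == "s5"])  # decoy of a VAR entry

  ghost <- psm_row("s6", "WWWWYYYY", "P1", 1e-2)
  expect_error(
    flag_novelty(read_psm_table(write_psm_tsv(rbind(tab, ghost), tempfile())), db),
    "not found in any database entry")
})

test_that("I/L folding maps isobaric peptides to the reference", {
  db <- small_db()
  # reference P1 contains ILVAND; the I->L variant spelling maps only when folded
  tab <- rbind(psm_row("s1", "KLLVAND", "P1", 1e-3),
               psm_row("s2", "ADKILV", "P1", 1e-3))
  p <- read_psm_table(write_psm_tsv(tab, tempfile()))
  folded <- flag_novelty(p, db, equate_il = TRUE)
  expect_false(folded$is_novel[folded$spectrum_id == "s1"])
})

test_that("the novel-peptide FDR equation reproduces direct substitution", {
  # D+ = 10, Dn = 2, D = 10, Tn+ = 50 at threshold 1 -> 10*(2/10)/50 = 0.04
  psms <- data.frame(
    score = rep(5, 60),
    is_decoy = rep(c(TRUE, FALSE), c(10, 50)),
    is_novel = c(rep(TRUE, 2), rep(FALSE, 8), rep(TRUE, 50)))
  r <- novel_fdr(psms, 1)
  expect_equal(r$tally, list(D_plus = 10L, T_n_plus = 50L, D_n = 2L, D = 10L))
  expect_equal(r$fdr_n, 0.04)

  psms$is_novel[1:2] <- FALSE   # Dn = 0 -> numerator zero
  expect_equal(novel_fdr(psms, 1)$fdr_n, 0)

  no_decoy <- psms[!psms$is_decoy, ]
  expect_equal(novel_fdr(no_decoy, 1)$fdr_n, 0)  # D = 0 convention
})

test_that("novel_fdr equals the brute-force recount on random PSM sets", {
  set.seed(51)
  for (i in 1:30) {
    psms <- random_psm_set(150L)
    for (t in stats::runif(5, 0, 40)) {
      expect_identical(novel_fdr(psms, t)$fdr_n, oracle_novel_fdr(psms, t))
    }
  }
})

test_that("FDR filtering follows a hand-computed threshold walk", {
  # alternating target/decoy by descending score
  psms <- data.frame(score = 10:1,
                     is_decoy = rep(c(FALSE, TRUE), 5),
                     is_novel = FALSE,
                     peptide = paste0("p", 10:1), proteins = "P1",
                     stringsAsFactors = FALSE)
  r <- filter_at_fdr(psms, 0.5, "global")
  expect_equal(r$threshold, 8)
  expect_equal(nrow(r$psms), 2L)   # targets scoring 10 and 8
  r2 <- filter_at_fdr(psms, 0.8, "global")
  expect_equal(r2$threshold, 2)
  expect_equal(nrow(r2$psms), 5L)

  all_targets <- data.frame(score = 1:5, is_decoy = FALSE, is_novel = FALSE)
  expect_equal(nrow(filter_at_fdr(all_targets, 0.01, "global")$psms), 5L)

  top_decoy <- data.frame(score = c(10, 9), is_decoy = c(TRUE, FALSE),
                          is_novel = FALSE)
  expect_warning(r3 <- filter_at_fdr(top_decoy, 1e-9, "global"), "no PSMs")
  expect_equal(nrow(r3$psms), 0L)
})

test_that("the step-down FDR envelope is monotone while raw estimates need not be", {
  # raw novel FDR can rise with the threshold (novel target drops out first)
  psms <- data.frame(score = c(10, 9, 8),
                     is_decoy = c(TRUE, FALSE, FALSE),
                     is_novel = TRUE)
  expect_lt(novel_fdr(psms, 7)$fdr_n, novel_fdr(psms, 8.5)$fdr_n)
  env <- fdr_step_down(psms, "novel")
  expect_true(all(diff(env$fdr) <= 0))
})

test_that("novel peptide classification follows unique-class mapping", {
  db <- small_db()
  tab <- rbind(
    psm_row("s1", "MVDKILVAND", "VAR|SAP|v1|t1|4:A>V", 1e-4),  # unique SAP
    psm_row("s2", "KKKWKK", "VAR|NTX|n1|frame0|frag1", 1e-4),  # NTX, intergenic
    psm_row("s3", "QQQFQQ", "VAR|NTX|n2|frame0|frag1", 1e-4),  # NTX, gene overlap
    psm_row("s4", "MVDK", "VAR|SAP|v1|t1|4:A>V;VAR|JUC|j1|c:5-9|frame0|strand+",
            1e-4))                                             # SAP and JUC
  p <- flag_novelty(read_psm_table(write_psm_tsv(tab, tempfile())), db)
  msgs <- capture_messages(p <- classify_novel(p, db))
  expect_true(any(grepl("ambiguous", msgs)))
  expect_equal(p$gene_status[p$spectrum_id == "s1"], "existing_gene_variant")
  expect_equal(p$gene_status[p$spectrum_id == "s2"], "novel_gene_product")
  expect_equal(p$gene_status[p$spectrum_id == "s3"], "none")
  expect_equal(p$gene_status[p$spectrum_id == "s4"], "none")
  expect_equal(p$novel_class[p$spectrum_id == "s4"], "none")
})

test_that("parsimony inference solves the textbook instances", {
  mk <- function(...) {
    rows <- list(...)
    data.frame(peptide = vapply(rows, `[[`, character(1), 1),
               proteins = vapply(rows, `[[`, character(1), 2),
               stringsAsFactors = FALSE)
  }
  # p2's proteins subsume p1's: single group A
  g <- infer_proteins(mk(c("p1", "A"), c("p2", "A;B")))
  expect_equal(length(g), 1L)
  expect_equal(g[[1]]$representative, "A")

  # both A and B are needed
  g2 <- infer_proteins(mk(c("p1", "A"), c("p2", "B"), c("p3", "A;B")))
  expect_equal(sort(vapply(g2, `[[`, character(1), "representative")),
               c("A", "B"))

  # indistinguishable proteins merge into one group
  g3 <- infer_proteins(mk(c("p1", "A;B"), c("p2", "A;B")))
  expect_equal(length(g3), 1L)
  expect_equal(g3[[1]]$members, c("A", "B"))
})

test_that("greedy covers are complete, irredundant and near-minimal", {
  set.seed(52)
  excess_total <- 0L
  for (i in 1:25) {
    n_prot <- sample(3:8, 1)
    n_pep <- sample(5:12, 1)
    peps <- paste0("pep", seq_len(n_pep))
    pepsets <- lapply(seq_len(n_prot), function(j)
      sort(sample(peps, sample(1:4, 1))))
    names(pepsets) <- paste0("PR", seq_len(n_prot))
    rows <- do.call(rbind, lapply(peps, function(p) {
      owners <- names(pepsets)[vapply(pepsets, function(s) p %in% s, logical(1))]
      if (!length(owners)) return(NULL)
      data.frame(peptide = p, proteins = paste(owners, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(rows)) next
    g <- infer_proteins(rows)
    covered <- sort(unique(unlist(lapply(g, `[[`, "peptides"))))
    expect_equal(covered, sort(unique(rows$peptide)))  # full coverage
    # no redundancy: removing any group uncovers at least one peptide
    for (k in seq_along(g)) {
      rest <- unique(unlist(lapply(g[-k], `[[`, "peptides")))
      expect_true(length(setdiff(g[[k]]$peptides, rest)) >= 1L)
    }
    # greedy is never below the exhaustive minimum; any excess is reported
    minimum <- oracle_min_cover(pepsets, sort(unique(rows$peptide)))
    expect_gte(length(g), minimum)
    excess_total <- excess_total + (length(g) - minimum)
  }
  if (excess_total > 0L)
    cat("greedy cover excess over exhaustive minimum (25 instances):",
        excess_total, "\n")
})
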