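# Independent oracles and tiny in-code fixtures shared across tests.

# Translation oracle: plain lookup in Biostrings' published codon table,
# written as a character-by-character loop so it shares nothing with the
# package's vectorized path.
oracle_translate <- function(seq, to_first_stop = FALSE) {
  tab <- Biostrings::GENETIC_CODE
  out <- character(0)
  i <- 1L
  while (i + 2L <= nchar(seq)) {
    codon <- substr(seq, i, i + 2L)
    aa <- if (grepl("[^ACGT]", codon)) "X" else unname(tab[[codon]])
    if (to_first_stop && aa == "*") return(paste(out, collapse = ""))
    out <- c(out, aa)
    i <- i + 3L
  }
  paste(out, collapse = "")
}

oracle_revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Brute-force recount of the novel-peptide FDR equation, literal and
# independent of novel_fdr()'s vectorized code.
oracle_novel_fdr <- function(psms, threshold) {
  D_plus <- 0L; D <- 0L; D_n <- 0L; T_n_plus <- 0L
  for (i in seq_len(nrow(psms))) {
    if (psms$is_decoy[i]) {
      D <- D + 1L
      if (psms$is_novel[i]) D_n <- D_n + 1L
      if (psms$score[i] >= threshold) D_plus <- D_plus + 1L
    } else if (psms$is_novel[i] && psms$score[i] >= threshold) {
      T_n_plus <- T_n_plus + 1L
    }
  }
  if (D == 0L || T_n_plus == 0L) return(0)
  min(1, D_plus * (D_n / D) / T_n_plus)
}

# Random PSM set with just the columns the FDR estimators consume.
random_psm_set <- function(n = 200L) {
  data.frame(
    score = round(stats::runif(n, 0, 40), 2),
    is_decoy = stats::runif(n) < 0.4,
    is_novel = stats::runif(n) < 0.3,
    peptide = replicate(n, paste(sample(LETTERS[1:20], 8, TRUE), collapse = "")),
    proteins = "P1",
    stringsAsFactors = FALSE)
}

# Exhaustive ORF enumerator: every ATG..stop (or stop-to-stop stretch) in
# every frame of both strands.
oracle_orfs <- function(seq, requires_start = TRUE, stranded = FALSE,
                        min_len = 1L) {
  out <- list()
  strands <- if (stranded) "+" else c("+", "-")
  for (s in strands) {
    src <- if (s == "+") seq else oracle_revcomp(seq)
    for (off in 0:2) {
      frame <- off + if (s == "+") 0L else 3L
      aa <- oracle_translate(substr(src, off + 1L, nchar(src)))
      if (!nchar(aa)) next
      chars <- strsplit(aa, "")[[1L]]
      bounds <- c(0L, which(chars == "*"), length(chars) + 1L)
      for (b in seq_len(length(bounds) - 1L)) {
        lo <- bounds[b] + 1L; hi <- bounds[b + 1L] - 1L
        if (hi < lo) next
        starts <- if (requires_start) lo - 1L + which(chars[lo:hi] == "M") else lo
        for (a in starts) {
          prot <- paste(chars[a:hi], collapse = "")
          if (nchar(prot) < min_len) next
          out[[length(out) + 1L]] <- list(frame = frame, protein = prot,
                                          aa_start = a)
        }
      }
    }
  }
  out
}

# Exhaustive minimum set cover (instances with few proteins only).
oracle_min_cover <- function(pepsets, universe) {
  n <- length(pepsets)
  best <- n + 1L
  for (k in seq_len(n)) {
    combos <- utils::combn(n, k, simplify = FALSE)
    for (cmb in combos) {
      if (setequal(intersect(unique(unlist(pepsets[cmb])), universe), universe)) {
        return(k)
      }
    }
  }
  best
}

# A hand-built two-gene toy reference used by several unit tests: gene A on
# the plus strand (two exons), gene B on the minus strand (one exon).
toy_reference <- function() {
  # gene A coding sequence: ATG GCC GAT AAA TGA -> protein "MADK"
  cdsA <- "ATGGCCGATAAATGA"
  exA1 <- substr(cdsA, 1, 9); exA2 <- substr(cdsA, 10, 15)
  # gene B coding sequence: ATG AAA TGC CGC TAA -> protein "MKCR"
  cdsB <- "ATGAAATGCCGCTAA"
  lead <- "ACGTACGTAC"; intron <- "GGGGCCCCGGGG"; spacer <- "TTTTTTTTTT"
  tailseq <- "ACACACACAC"
  genomic <- paste0(lead, exA1, intron, exA2, spacer,
                    oracle_revcomp(cdsB), tailseq)
  off <- nchar(lead)
  exonsA <- data.frame(start = c(off, off + 9L + nchar(intron)),
                       end = c(off + 9L, off + 9L + nchar(intron) + 6L))
  startB <- off + 9L + nchar(intron) + 6L + nchar(spacer)
  exonsB <- data.frame(start = startB, end = startB + 15L)
  list(
    genome = stats::setNames(genomic, "chrT"),
    txA = transcript_model("txA", "geneA", "chrT", "+", exonsA, exonsA),
    txB = transcript_model("txB", "geneB", "chrT", "-", exonsB, exonsB),
    protA = "MADK", protB = "MKCR", cdsA = cdsA, cdsB = cdsB)
}

write_genome_fa <- function(genome, path) {
  writeLines(unlist(lapply(names(genome), function(n)
    c(paste0(">", n), genome[[n]]))), path)
  path
}

write_psm_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
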