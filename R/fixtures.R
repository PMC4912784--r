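#' Specification for synthetic pipeline inputs
#'
#' Defines the conditions of a fully synthetic, internally consistent input
#' set: a toy genome with annotated coding genes, RNA-Seq evidence (SNVs,
#' INDELs, exon-skipping junctions, intergenic novel transcripts, de novo
#' contigs) and a search-engine PSM table with planted ground truth. Score
#' defaults emulate a well-separated search: correct PSMs score around
#' `true_score_mean` (on the `-log2` e-value scale) and incorrect ones
#' `score_separation` units lower, both with spread `score_sd`.
#'
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @param n_genes,n_snv,n_indel,n_junction,n_novel_tx,n_denovo Evidence counts.
#' @param n_psms Total PSM count.
#' @param psm_true_fraction Fraction of PSMs planted as correct.
#' @param score_separation Mean score gap between correct and incorrect PSMs.
#' @param novel_psm_fraction Fraction of correct PSMs drawn from novel
#'   (VAR) peptides.
#' @param true_score_mean,score_sd Score distribution parameters.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 20L, n_snv = 15L, n_indel = 3L,
                         n_junction = 5L, n_novel_tx = 5L, n_denovo = 3L,
                         n_psms = 2000L, psm_true_fraction = 0.7,
                         score_separation = 10, novel_psm_fraction = 0.15,
                         true_score_mean = 30, score_sd = 2) {
  stopifnot(psm_true_fraction > 0, psm_true_fraction <= 1,
            novel_psm_fraction >= 0, novel_psm_fraction <= 1,
            n_genes >= 0, n_psms >= 0)
  structure(as.list(environment()), class = "fixture_spec")
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# Random coding sequence: ATG, n_aa - 1 non-stop non-start codons, stop.
.rand_cds <- function(n_aa) {
  codons <- names(.STANDARD_CODE)[!.STANDARD_CODE %in% "*"]
  body <- sample(codons, n_aa - 1L, replace = TRUE)
  stopc <- sample(c("TAA", "TAG", "TGA"), 1L)
  paste(c("ATG", body, stopc), collapse = "")
}

# Genomic position (0-based) of plus-orientation CDS offset o.
.genomic_pos <- function(cds, o) {
  for (i in seq_len(nrow(cds))) {
    w <- cds$end[i] - cds$start[i]
    if (o < w) return(cds$start[i] + o)
    o <- o - w
  }
  stop("CDS offset out of range")
}

#' Generate a toy reference (genome, annotation, proteome)
#'
#' Genes carry 1-4 exons on both strands (genes earmarked for junction
#' evidence get at least 3); coding sequences are in frame, start with ATG
#' and end with a stop; exons coincide with the CDS. The proteome is the
#' translation of each CDS. Output is byte-identical for a fixed seed.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Directory for `genome.fa`, `annotation.gtf`, `proteome.fa`.
#' @return List with the file `paths`, the in-memory `genome`, `models`,
#'   `proteins`, and the intergenic `gaps` available for novel transcripts.
#' @export
make_reference <- function(spec, outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  chrom <- "chrS"
  parts <- character(0)
  pos <- 0L
  models <- list()
  proteins <- character(0)
  gaps <- data.frame(start = integer(), end = integer())
  n_multi <- min(spec$n_genes, max(6L, spec$n_junction + 1L))
  for (g in seq_len(spec$n_genes)) {
    gap_len <- sample(150:400, 1L)
    parts <- c(parts, .rand_dna(gap_len))
    gaps <- rbind(gaps, data.frame(start = pos, end = pos + gap_len))
    pos <- pos + gap_len
    n_aa <- sample(40:80, 1L)
    cds_coding <- .rand_cds(n_aa)      # coding orientation, incl. stop
    strand <- sample(c("+", "-"), 1L)
    n_ex <- if (g <= n_multi) sample(3:4, 1L) else sample(1:4, 1L)
    L <- nchar(cds_coding)
    n_ex <- min(n_ex, L %/% 15L)
    cuts <- if (n_ex > 1L) sort(sample(seq(12L, L - 12L, by = 3L), n_ex - 1L))
            else integer(0)
    bounds <- c(0L, cuts, L)
    pieces <- substring(cds_coding, bounds[-length(bounds)] + 1L, bounds[-1L])
    # genomic (left-to-right) order: reverse and complement for minus strand
    genomic_pieces <- if (strand == "-")
      rev(vapply(pieces, reverse_complement, character(1), USE.NAMES = FALSE))
    else pieces
    exs <- data.frame(start = integer(), end = integer())
    for (k in seq_along(genomic_pieces)) {
      if (k > 1L) {
        intron <- sample(30:80, 1L)
        parts <- c(parts, .rand_dna(intron))
        pos <- pos + intron
      }
      w <- nchar(genomic_pieces[k])
      parts <- c(parts, genomic_pieces[k])
      exs <- rbind(exs, data.frame(start = pos, end = pos + w))
      pos <- pos + w
    }
    gid <- sprintf("gene%02d", g)
    tid <- sprintf("tx%02d", g)
    models[[tid]] <- transcript_model(tid, gid, chrom, strand, exs, exs)
    proteins[[paste0("P_", gid)]] <- translate(cds_coding,
                                               to_first_stop = TRUE)
  }
  tail_gap <- 500L
  parts <- c(parts, .rand_dna(tail_gap))
  gaps <- rbind(gaps, data.frame(start = pos, end = pos + tail_gap))
  genome <- stats::setNames(paste(parts, collapse = ""), chrom)

  genome_fa <- file.path(outdir, "genome.fa")
  gtf <- file.path(outdir, "annotation.gtf")
  proteome_fa <- file.path(outdir, "proteome.fa")
  writeLines(c(paste0(">", chrom),
               substring(genome, seq(1L, nchar(genome), 60L),
                         pmin(seq(1L, nchar(genome), 60L) + 59L, nchar(genome)))),
             genome_fa)
  write_gtf(models, gtf)
  if (length(proteins)) {
    writeLines(unlist(lapply(names(proteins), function(a)
      c(paste0(">", a), proteins[[a]]))), proteome_fa)
  } else writeLines(character(0), proteome_fa)
  list(paths = c(genome = genome_fa, gtf = gtf, proteome = proteome_fa),
       genome = genome, models = models, proteins = proteins, gaps = gaps)
}

#' Generate RNA-Seq evidence with known expected products
#'
#' Plants coding nonsynonymous SNVs, coding frameshift deletions,
#' exon-skipping junctions and intergenic novel transcripts, writing VCF,
#' BED12, GTF and de novo FASTA files plus a truth manifest recording each
#' planted variant's expected protein product (computed by direct editing of
#' the known coding sequence, independently of the projection code).
#'
#' @param spec A [fixture_spec()].
#' @param reference Output of [make_reference()].
#' @param outdir Output directory.
#' @return List with file `paths` and the `truth` manifest.
#' @export
make_evidence <- function(spec, reference, outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 1L)
  genome <- reference$genome
  models <- reference$models
  chrom <- names(genome)
  truth <- list(snv = list(), indel = list(), junction = list(),
                novel_tx = list(), denovo = list())
  vcf_rows <- character(0)
  used <- character(0)

  coding_ids <- names(models)
  # --- SNVs: nonsynonymous, non-stop, planted mid-protein -------------------
  for (i in seq_len(spec$n_snv)) {
    repeat {
      tid <- sample(coding_ids, 1L)
      tx <- models[[tid]]
      cds_coding <- cds_sequence(tx, genome)
      P <- translate(cds_coding, to_first_stop = TRUE)
      ai <- sample(2:nchar(P), 1L)          # spare the initiator
      codon <- substring(cds_coding, (ai - 1L) * 3L + 1L, ai * 3L)
      jpos <- sample(0:2, 1L)
      alts <- setdiff(c("A", "C", "G", "T"), substring(codon, jpos + 1L, jpos + 1L))
      found <- FALSE
      for (ab in sample(alts)) {
        new_codon <- codon
        substring(new_codon, jpos + 1L, jpos + 1L) <- ab
        new_aa <- unname(.STANDARD_CODE[new_codon])
        if (new_aa != substring(P, ai, ai) && new_aa != "*") {
          found <- TRUE; break
        }
      }
      key <- sprintf("%s:%d:%d", tid, ai, jpos)
      if (!found || key %in% used) next
      used <- c(used, key)
      o_c <- (ai - 1L) * 3L + jpos
      L <- nchar(cds_coding)
      o_p <- if (tx$strand == "-") L - 1L - o_c else o_c
      g <- .genomic_pos(tx$cds, o_p)
      ref_b <- substring(genome, g + 1L, g + 1L)
      alt_b <- if (tx$strand == "-") reverse_complement(ab) else ab
      vid <- sprintf("snv%02d", i)
      vcf_rows <- c(vcf_rows, sprintf("%s\t%d\t%s\t%s\t%s\t50\tPASS\t.",
                                      chrom, g + 1L, vid, ref_b, alt_b))
      expected <- P
      substring(expected, ai, ai) <- new_aa
      truth$snv[[vid]] <- list(variant_id = vid, transcript_id = tid,
                               protein_pos = ai,
                               ref_aa = substring(P, ai, ai), alt_aa = new_aa,
                               expected_protein = expected)
      break
    }
  }
  # --- INDELs: 1-bp coding deletions (frameshift) ---------------------------
  for (i in seq_len(spec$n_indel)) {
    repeat {
      tid <- sample(coding_ids, 1L)
      tx <- models[[tid]]
      cds_coding <- cds_sequence(tx, genome)
      L <- nchar(cds_coding)
      o_c <- sample(6:(L - 12L), 1L)        # deleted coding base, past codon 2
      o_p <- if (tx$strand == "-") L - 1L - o_c else o_c
      g_del <- .genomic_pos(tx$cds, o_p)
      g_anchor <- g_del - 1L
      # anchor must sit immediately left of the deleted base on the genome
      in_cds <- !is.na(.cds_offset(tx$cds, g_anchor)) &&
        .cds_offset(tx$cds, g_anchor) == .cds_offset(tx$cds, g_del) - 1L
      if (!in_cds) next
      mutated <- paste0(substring(cds_coding, 1L, o_c),
                        substring(cds_coding, o_c + 2L))
      product <- translate(mutated, to_first_stop = TRUE)
      if (nchar(product) < 7L) next
      key <- sprintf("%s:del%d", tid, o_c)
      if (key %in% used) next
      used <- c(used, key)
      vid <- sprintf("indel%02d", i)
      ref2 <- substring(genome, g_anchor + 1L, g_del + 1L)
      alt2 <- substring(genome, g_anchor + 1L, g_anchor + 1L)
      vcf_rows <- c(vcf_rows, sprintf("%s\t%d\t%s\t%s\t%s\t50\tPASS\t.",
                                      chrom, g_anchor + 1L, vid, ref2, alt2))
      truth$indel[[vid]] <- list(variant_id = vid, transcript_id = tid,
                                 coding_offset = o_c,
                                 expected_protein = product)
      break
    }
  }
  # --- junctions: skip one internal exon ------------------------------------
  multi <- Filter(function(tx) nrow(tx$exons) >= 3L, models)
  picks <- sample(names(multi), min(spec$n_junction, length(multi)))
  jrows <- character(0)
  for (i in seq_along(picks)) {
    tx <- multi[[picks[i]]]
    k <- sample(seq_len(nrow(tx$exons) - 2L), 1L)
    left <- tx$exons[k, ]; right <- tx$exons[k + 2L, ]
    strand <- if (stats::runif(1) < 0.2) "." else tx$strand
    nm <- sprintf("JUNC%02d", i)
    bed_strand <- if (strand == ".") "." else strand
    jrows <- c(jrows, sprintf(
      "%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0\t2\t%d,%d\t%d,%d",
      tx$chrom, left$start, right$end, nm, sample(5:50, 1L), bed_strand,
      left$start, right$end,
      left$end - left$start, right$end - right$start,
      0L, right$start - left$start))
    truth$junction[[nm]] <- list(name = nm, transcript_id = tx$transcript_id,
                                 skipped_exon = k + 1L, strand = strand)
  }
  # --- novel transcripts in intergenic gaps ---------------------------------
  gaps <- reference$gaps
  gaps <- gaps[order(-(gaps$end - gaps$start)), , drop = FALSE]
  ntx_models <- list()
  for (i in seq_len(min(spec$n_novel_tx, nrow(gaps)))) {
    gp <- gaps[i, ]
    avail <- gp$end - gp$start - 20L
    w <- min(avail, sample(120:240, 1L))
    s0 <- gp$start + 10L
    strand <- if (i %% 2L == 0L) "." else "+"
    tid <- sprintf("ntx%02d", i)
    ntx_models[[tid]] <- transcript_model(
      tid, paste0("novelgene", i), chrom, strand,
      data.frame(start = s0, end = s0 + w))
    truth$novel_tx[[tid]] <- list(transcript_id = tid, start = s0,
                                  end = s0 + w, strand = strand)
  }
  # --- de novo contigs with a guaranteed embedded ORF -----------------------
  denovo <- character(0)
  for (i in seq_len(spec$n_denovo)) {
    orf <- .rand_cds(sample(25:45, 1L))
    contig <- paste0(.rand_dna(sample(10:40, 1L)), orf,
                     .rand_dna(sample(10:40, 1L)))
    id <- sprintf("contig%02d", i)
    denovo[[id]] <- contig
    truth$denovo[[id]] <- list(id = id,
                               orf_protein = translate(orf, to_first_stop = TRUE))
  }

  vcf <- file.path(outdir, "variants.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", chrom, nchar(genome)),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               vcf_rows), vcf)
  bed <- file.path(outdir, "junctions.bed")
  writeLines(jrows, bed)
  ngtf <- file.path(outdir, "novel.gtf")
  write_gtf(ntx_models, ngtf, source = "assembler")
  dfa <- file.path(outdir, "denovo.fa")
  writeLines(as.character(unlist(lapply(names(denovo), function(a)
    c(paste0(">", a), denovo[[a]])))), dfa)
  tj <- file.path(outdir, "truth_evidence.json")
  jsonlite::write_json(truth, tj, auto_unbox = TRUE, pretty = TRUE)
  list(paths = c(vcf = vcf, junction_bed = bed, novel_gtf = ngtf,
                 denovo = dfa, truth = tj),
       truth = truth, ntx_models = ntx_models)
}

#' Generate a planted-truth PSM table against a built database
#'
#' Correct PSMs draw peptides from target entries (canonical windows of
#' reference proteins plus, per `novel_psm_fraction`, windows of VAR entries
#' verified to be novel and class-unique) with scores around
#' `true_score_mean`; incorrect PSMs are split between decoy windows and
#' mis-assigned target windows, scoring `score_separation` lower. E-values
#' are `2^(-score)`, so the score convention is exactly invertible. The
#' `proteins` column lists every database entry containing the peptide.
#'
#' @param spec A [fixture_spec()].
#' @param db The `custom_db` (with decoys) the PSMs are searched against.
#' @param outdir Output directory for `psms.tsv` and `truth_psms.tsv`.
#' @return List with `paths`, the PSM `table` and the `truth` table
#'   (spectrum_id, planted_true, planted_class, peptide).
#' @export
make_psms <- function(spec, db, outdir) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(db, "custom_db"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 2L)
  entries <- db$entries
  refs <- entries[entries$category == "REF", , drop = FALSE]
  vars <- entries[!entries$category %in% c("REF", "DECOY"), , drop = FALSE]
  decoys <- entries[entries$category == "DECOY", , drop = FALSE]
  ref_hay <- paste(refs$sequence, collapse = "#")
  target_hay <- paste(entries$sequence[entries$category != "DECOY"],
                      collapse = "#")

  window_of <- function(seqs) {
    w <- sample(8:15, 1L)
    if (nchar(seqs) < w) return(NULL)
    s <- sample(seq_len(nchar(seqs) - w + 1L), 1L)
    substring(seqs, s, s + w - 1L)
  }
  # class-unique novel windows of VAR entries, balanced across classes
  novel_windows <- list()
  for (cls in sort(unique(vars$category))) {
    rows <- which(vars$category == cls)
    found <- 0L
    for (attempt in seq_len(300L)) {
      if (found >= 6L) break
      e <- rows[1L + (attempt - 1L) %% length(rows)]
      pep <- window_of(vars$sequence[e])
      if (is.null(pep) || grepl(pep, ref_hay, fixed = TRUE)) next
      classes <- unique(vars$category[grepl(pep, vars$sequence, fixed = TRUE)])
      if (length(classes) != 1L || classes != cls) next
      if (!is.null(novel_windows[[pep]])) next
      novel_windows[[pep]] <- cls
      found <- found + 1L
    }
  }
  canonical_windows <- character(0)
  while (length(canonical_windows) < 60L && nrow(refs)) {
    pep <- window_of(refs$sequence[sample(seq_len(nrow(refs)), 1L)])
    if (!is.null(pep)) canonical_windows <- unique(c(canonical_windows, pep))
  }
  decoy_windows <- character(0)
  for (attempt in seq_len(400L)) {
    if (length(decoy_windows) >= 40L) break
    pep <- window_of(decoys$sequence[sample(seq_len(nrow(decoys)), 1L)])
    if (is.null(pep) || grepl(pep, target_hay, fixed = TRUE)) next
    decoy_windows <- unique(c(decoy_windows, pep))
  }

  n_true <- round(spec$n_psms * spec$psm_true_fraction)
  n_novel_true <- if (length(novel_windows))
    round(n_true * spec$novel_psm_fraction) else 0L
  n_can_true <- n_true - n_novel_true
  n_false <- spec$n_psms - n_true
  n_false_decoy <- if (length(decoy_windows)) n_false %/% 2L else 0L
  n_false_target <- n_false - n_false_decoy

  pick <- function(pool, n) pool[sample.int(length(pool), n, replace = TRUE)]
  peptides <- c(pick(canonical_windows, n_can_true),
                if (n_novel_true) pick(names(novel_windows), n_novel_true),
                if (n_false_target) pick(canonical_windows, n_false_target),
                if (n_false_decoy) pick(decoy_windows, n_false_decoy))
  planted_true <- rep(c(TRUE, FALSE), c(n_true, n_false))
  planted_class <- c(rep("canonical", n_can_true),
                     if (n_novel_true)
                       vapply(peptides[n_can_true + seq_len(n_novel_true)],
                              function(p) novel_windows[[p]], character(1)),
                     rep("false_target", n_false_target),
                     rep("false_decoy", n_false_decoy))
  scores <- c(stats::rnorm(n_true, spec$true_score_mean, spec$score_sd),
              stats::rnorm(n_false, spec$true_score_mean - spec$score_separation,
                           spec$score_sd))
  scores <- pmax(scores, 0.5)
  # map every peptide to all containing database entries
  uniq <- unique(peptides)
  prot_map <- stats::setNames(vapply(uniq, function(p) {
    paste(entries$accession[grepl(p, entries$sequence, fixed = TRUE)],
          collapse = ";")
  }, character(1)), uniq)
  tab <- data.frame(
    spectrum = sprintf("spec%05d", seq_along(peptides)),
    peptide = peptides,
    proteins = unname(prot_map[peptides]),
    evalue = 2^(-scores),
    charge = sample(2:3, length(peptides), replace = TRUE),
    stringsAsFactors = FALSE)
  truth <- data.frame(spectrum_id = tab$spectrum, peptide = tab$peptide,
                      planted_true = planted_true,
                      planted_class = planted_class,
                      stringsAsFactors = FALSE)
  pt <- file.path(outdir, "psms.tsv")
  tt <- file.path(outdir, "truth_psms.tsv")
  utils::write.table(tab, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
  list(paths = c(psms = pt, truth = tt), table = tab, truth = truth)
}

#' Generate a complete synthetic input set
#'
#' Convenience wrapper: reference, evidence, customized database (built with
#' [build_custom_db()]) and planted-truth PSM table, all under one directory.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory.
#' @return List with `reference`, `evidence`, `db`, `psms` components.
#' @export
make_fixtures <- function(spec, outdir) {
  reference <- make_reference(spec, outdir)
  evidence <- make_evidence(spec, reference, outdir)
  db <- build_custom_db(
    genome_fa = reference$paths[["genome"]], gtf = reference$paths[["gtf"]],
    proteome_fa = reference$paths[["proteome"]],
    vcf = evidence$paths[["vcf"]],
    junction_bed = evidence$paths[["junction_bed"]],
    novel_gtf = evidence$paths[["novel_gtf"]],
    denovo_fa = evidence$paths[["denovo"]],
    out = file.path(outdir, "custom.fa"))
  psms <- make_psms(spec, db, outdir)
  list(reference = reference, evidence = evidence, db = db, psms = psms)
}
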