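#' Read splice junctions from a BED12 file
#'
#' Reads junction records in the two-block BED12 dialect written by spliced
#' aligners: each record has exactly two blocks flanking one intron, and the
#' score column carries the supporting read count. Records with a block count
#' other than two are skipped with a warning. BED coordinates are already
#' 0-based half-open and are kept as-is.
#'
#' @param path Path to a BED12 file.
#' @return Data frame with columns `chrom`, `left_start`, `left_end`,
#'   `right_start`, `right_end`, `strand`, `name`, `read_count`.
#' @export
read_junction_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  rows <- lapply(seq_along(gr), function(i) {
    blocks <- gr$blocks[[i]]
    if (is.null(blocks) || length(blocks) != 2L) {
      warning("skipping junction record ", i, " with blockCount != 2")
      return(NULL)
    }
    chrom_start <- GenomicRanges::start(gr[i]) - 1L  # back to BED 0-based
    bs <- IRanges::start(blocks) - 1L               # block offsets, 0-based
    be <- IRanges::end(blocks)
    nm <- if (!is.null(gr$name) && !is.na(gr$name[i])) gr$name[i]
          else paste0("JUNC", i)
    sc <- if (!is.null(gr$score) && !is.na(gr$score[i])) as.integer(gr$score[i])
          else 0L
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr[i])),
               left_start = chrom_start + bs[1L], left_end = chrom_start + be[1L],
               right_start = chrom_start + bs[2L], right_end = chrom_start + be[2L],
               strand = chartr("*", ".", as.character(GenomicRanges::strand(gr[i]))),
               name = nm, read_count = sc, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(chrom = character(), left_start = integer(),
                      left_end = integer(), right_start = integer(),
                      right_end = integer(), strand = character(),
                      name = character(), read_count = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  bad <- out$left_end > out$right_start
  if (any(bad)) stop("junction block(s) out of order in ", path)
  out
}

#' Translate a splice junction into candidate peptide entries
#'
#' Takes up to `flank_nt` nucleotides ending at the left block end and up to
#' `flank_nt` starting at the right block start (clipped at the block length),
#' concatenates them across the junction, and translates: stranded records in
#' the three frames of their strand, unstranded records in all six frames.
#' Each frame's translation is cut at stop codons and only fragments whose
#' codons cover at least one nucleotide on each side of the junction are
#' emitted. Accessions follow
#' `VAR|JUC|<name>|<chrom>:<left_end>-<right_start>|frame<k>|strand<s>`.
#'
#' @param j One-row data frame as returned by [read_junction_bed()].
#' @param genome Named character vector from [read_genome()].
#' @param flank_nt Maximum nucleotides taken from each side (default 66,
#'   i.e. up to 22 residues per side).
#' @param min_len Minimum emitted fragment length in residues.
#' @param code Codon table.
#' @return Data frame of database entries with extra columns
#'   `junction_offset` (0-based index of the last residue whose codon starts
#'   left of the junction) and `frame`.
#' @export
junction_to_entries <- function(j, genome, flank_nt = 66L, min_len = 7L,
                                code = genetic_code()) {
  stopifnot(flank_nt >= 3L, flank_nt %% 3L == 0L)
  # clip at block length, then round down to whole codons so that reading
  # frames stay aligned to the junction whatever the flank length
  lf_len <- min(flank_nt, j$left_end - j$left_start)
  lf_len <- lf_len - lf_len %% 3L
  rt_len <- min(flank_nt, j$right_end - j$right_start)
  rt_len <- rt_len - rt_len %% 3L
  lf_start <- j$left_end - lf_len
  rt_end <- j$right_start + rt_len
  left <- .extract(genome, j$chrom, lf_start, j$left_end)
  right <- .extract(genome, j$chrom, j$right_start, rt_end)
  fwd <- paste0(left, right)
  jpos_fwd <- nchar(left)   # junction boundary in the forward concatenation

  strands <- if (j$strand %in% c("+", "-")) j$strand else c("+", "-")
  rows <- list()
  for (s in strands) {
    if (s == "+") { seqr <- fwd; jpos <- jpos_fwd }
    else { seqr <- reverse_complement(fwd); jpos <- nchar(fwd) - jpos_fwd }
    for (f in 0:2) {
      aa <- translate(substring(seqr, f + 1L), code)
      if (!nchar(aa)) next
      frags <- .split_at_stops(aa)
      for (fr in frags) {
        # codon i (0-based within the frame) spans nt [f+3i, f+3i+3)
        nt_start <- f + 3L * fr$start
        nt_end <- f + 3L * (fr$start + nchar(fr$seq))
        if (!(nt_start < jpos && nt_end > jpos)) next  # must straddle
        if (nchar(fr$seq) < min_len) next
        codon_starts <- nt_start + 3L * (seq_len(nchar(fr$seq)) - 1L)
        junction_offset <- max(which(codon_starts < jpos)) - 1L
        acc <- sprintf("VAR|JUC|%s|%s:%d-%d|frame%d|strand%s",
                       j$name, j$chrom, j$left_end, j$right_start, f, s)
        rows[[length(rows) + 1L]] <- data.frame(
          accession = acc, sequence = fr$seq, category = "JUC",
          provenance = sprintf("junction=%s;coords=%s:%d-%d;frame=%d;strand=%s;junction_offset=%d;reads=%d",
                               j$name, j$chrom, j$left_end, j$right_start,
                               f, s, junction_offset, j$read_count),
          junction_offset = junction_offset, frame = f,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    out <- .empty_entries()
    out$junction_offset <- integer(0)
    out$frame <- integer(0)
    return(out)
  }
  do.call(rbind, rows)
}

# Split a translated frame at stop codons, keeping the 0-based residue offset
# of each fragment within the frame.
.split_at_stops <- function(aa) {
  parts <- strsplit(aa, "*", fixed = TRUE)[[1L]]
  out <- list()
  off <- 0L
  for (p in parts) {
    if (nchar(p)) out[[length(out) + 1L]] <- list(seq = p, start = off)
    off <- off + nchar(p) + 1L
  }
  out
}
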