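#' Translation policy for novel and de novo transcripts
#'
#' @param mode `"three_frame"` (stranded sequences), `"six_frame"` (unknown
#'   strand) or `"longest_orf"`.
#' @param min_protein_len Minimum emitted protein length (residues).
#' @param orf_requires_start Must an ORF begin with ATG (`longest_orf` mode)?
#' @return A `translation_policy` list.
#' @export
translation_policy <- function(mode = c("three_frame", "six_frame", "longest_orf"),
                               min_protein_len = 7L, orf_requires_start = TRUE) {
  mode <- match.arg(mode)
  stopifnot(min_protein_len >= 1L)
  structure(list(mode = mode, min_protein_len = as.integer(min_protein_len),
                 orf_requires_start = isTRUE(orf_requires_start)),
            class = "translation_policy")
}

#' Reading frames of a nucleotide sequence
#'
#' Frames 0-2 read the given sequence at offsets 0, 1, 2; when the strand is
#' unknown (`stranded = FALSE`) frames 3-5 additionally read the reverse
#' complement at the same offsets.
#'
#' @param seq DNA string.
#' @param stranded Is the orientation known?
#' @return Data frame with columns `frame` (0-5) and `reading` (the frame's
#'   reading sequence, i.e. the oriented sequence trimmed to the frame offset).
#' @export
frames_of <- function(seq, stranded = TRUE) {
  rc <- if (stranded) NULL else reverse_complement(seq)
  frames <- if (stranded) 0:2 else 0:5
  reading <- vapply(frames, function(f) {
    src <- if (f < 3L) seq else rc
    substring(src, (f %% 3L) + 1L)
  }, character(1))
  data.frame(frame = frames, reading = reading, stringsAsFactors = FALSE)
}

#' Stop-to-stop protein fragments of a transcript
#'
#' Translates every reading frame of `seq`, splits the translations at stop
#' codons and emits every fragment of at least `policy$min_protein_len`
#' residues as a database entry with accession
#' `VAR|NTX|<id>|frame<k>|frag<i>`.
#'
#' @param seq DNA string (a spliced novel transcript or an assembled contig).
#' @param id Transcript identifier used in accessions.
#' @param policy A [translation_policy()] with mode `three_frame` or
#'   `six_frame`.
#' @param code Codon table.
#' @param provenance_extra Optional `key=value` string appended to each
#'   entry's provenance (e.g. gene-overlap metadata).
#' @return Data frame of database entries.
#' @export
stop_to_stop_fragments <- function(seq, id, policy = translation_policy("six_frame"),
                                   code = genetic_code(), provenance_extra = "") {
  stopifnot(policy$mode %in% c("three_frame", "six_frame"))
  fr <- frames_of(seq, stranded = policy$mode == "three_frame")
  rows <- list()
  for (i in seq_len(nrow(fr))) {
    aa <- translate(fr$reading[i], code)
    if (!nchar(aa)) next
    frags <- .split_at_stops(aa)
    fi <- 0L
    for (f in frags) {
      if (nchar(f$seq) < policy$min_protein_len) next
      fi <- fi + 1L
      prov <- sprintf("transcript_id=%s;frame=%d;frag=%d;aa_offset=%d",
                      id, fr$frame[i], fi, f$start)
      if (nzchar(provenance_extra)) prov <- paste0(prov, ";", provenance_extra)
      rows[[length(rows) + 1L]] <- data.frame(
        accession = sprintf("VAR|NTX|%s|frame%d|frag%d", id, fr$frame[i], fi),
        sequence = f$seq, category = "NTX", provenance = prov,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_entries())
  do.call(rbind, rows)
}

#' Longest open reading frame
#'
#' Scans all reading frames (three when `stranded`, six otherwise) and returns
#' the maximal-length ORF. With `orf_requires_start` an ORF runs from an ATG
#' to the next stop (or the end of the frame if no stop follows); otherwise
#' any open stop-to-stop stretch counts. Ties are broken by lower frame index,
#' then smaller nucleotide start.
#'
#' @param seq DNA string.
#' @param policy A [translation_policy()] with mode `longest_orf`.
#' @param stranded Is the orientation known?
#' @param code Codon table.
#' @return List with `frame`, `nt_start`, `nt_end` (0-based half-open within
#'   the frame's oriented parent sequence; the span includes the stop codon
#'   when present), and `protein`; or `NULL` when no ORF qualifies.
#' @export
longest_orf <- function(seq, policy = translation_policy("longest_orf"),
                        stranded = FALSE, code = genetic_code()) {
  stopifnot(policy$mode == "longest_orf")
  fr <- frames_of(seq, stranded = stranded)
  best <- NULL
  for (i in seq_len(nrow(fr))) {
    f <- fr$frame[i]
    off <- f %% 3L
    aa <- translate(fr$reading[i], code)
    if (!nchar(aa)) next
    aavec <- strsplit(aa, "", fixed = TRUE)[[1L]]
    stops <- which(aavec == "*")
    seg_starts <- c(1L, stops + 1L)
    seg_ends <- c(stops - 1L, length(aavec))   # codon indices, stop excluded
    for (sgi in seq_along(seg_starts)) {
      a <- seg_starts[sgi]; b <- seg_ends[sgi]
      if (b < a) next
      if (policy$orf_requires_start) {
        m <- which(aavec[a:b] == "M")
        if (!length(m)) next
        a <- a + m[1L] - 1L
      }
      prot <- paste(aavec[a:b], collapse = "")
      if (nchar(prot) < policy$min_protein_len) next
      has_stop <- sgi <= length(stops)
      nt_start <- off + 3L * (a - 1L)
      nt_end <- off + 3L * (b + as.integer(has_stop))
      cand <- list(frame = f, nt_start = nt_start, nt_end = nt_end,
                   protein = prot)
      if (is.null(best) ||
          nchar(cand$protein) > nchar(best$protein) ||
          (nchar(cand$protein) == nchar(best$protein) &&
           (cand$frame < best$frame ||
            (cand$frame == best$frame && cand$nt_start < best$nt_start))))
        best <- cand
    }
  }
  best
}

#' Database entries for novel transcripts
#'
#' Translates novel (assembler-reconstructed) transcripts resolved against the
#' genome, or de novo assembled contig sequences, into database entries.
#' Stranded transcripts default to three-frame translation, unstranded ones to
#' six-frame; `longest_orf` mode emits one entry per transcript instead. Each
#' entry records whether the source transcript overlaps an annotated gene,
#' which drives the novel-gene classification downstream.
#'
#' @param novel_tx List of [transcript_model()] for novel transcripts (may be
#'   empty).
#' @param genome Named character vector from [read_genome()].
#' @param annotation List of [transcript_model()] for the annotated genes used
#'   to flag gene overlap.
#' @param denovo Named character vector of assembled transcript sequences
#'   (may be empty); always treated as unstranded.
#' @param mode `"auto"` (three-frame when stranded, six-frame otherwise),
#'   `"six_frame"`, or `"longest_orf"`.
#' @param min_len Minimum protein length.
#' @param orf_requires_start Passed to [translation_policy()] for ORF mode.
#' @param code Codon table.
#' @return Data frame of database entries (category `NTX`).
#' @export
novel_transcript_entries <- function(novel_tx = list(), genome,
                                     annotation = list(),
                                     denovo = character(),
                                     mode = c("auto", "six_frame", "longest_orf"),
                                     min_len = 7L, orf_requires_start = TRUE,
                                     code = genetic_code()) {
  mode <- match.arg(mode)
  ann <- .gene_intervals(annotation)
  one <- function(seqs, id, stranded, overlap) {
    prov_extra <- paste0("gene_overlap=", if (overlap) "yes" else "no")
    if (mode == "longest_orf") {
      pol <- translation_policy("longest_orf", min_len, orf_requires_start)
      orf <- longest_orf(seqs, pol, stranded = stranded, code = code)
      if (is.null(orf)) return(.empty_entries())
      data.frame(accession = sprintf("VAR|NTX|%s|frame%d|orf", id, orf$frame),
                 sequence = orf$protein, category = "NTX",
                 provenance = sprintf("transcript_id=%s;frame=%d;nt_start=%d;nt_end=%d;%s",
                                      id, orf$frame, orf$nt_start, orf$nt_end,
                                      prov_extra),
                 stringsAsFactors = FALSE)
    } else {
      pol_mode <- if (mode == "auto" && stranded) "three_frame" else "six_frame"
      pol <- translation_policy(pol_mode, min_len)
      stop_to_stop_fragments(seqs, id, pol, code, provenance_extra = prov_extra)
    }
  }
  out <- list()
  for (tx in novel_tx) {
    seqs <- spliced_sequence(tx, genome)
    overlap <- .overlaps_gene(tx, ann)
    out[[length(out) + 1L]] <- one(seqs, tx$transcript_id,
                                   stranded = tx$strand %in% c("+", "-"),
                                   overlap = overlap)
  }
  for (i in seq_along(denovo)) {
    id <- names(denovo)[i]
    if (is.null(id) || !nzchar(id)) id <- paste0("contig", i)
    # de novo contigs have no genomic placement: never gene-overlapping
    out[[length(out) + 1L]] <- one(toupper(denovo[[i]]), id,
                                   stranded = FALSE, overlap = FALSE)
  }
  if (!length(out)) return(.empty_entries())
  do.call(rbind, out)
}

.gene_intervals <- function(annotation) {
  if (!length(annotation)) return(NULL)
  do.call(rbind, lapply(annotation, function(tx) {
    data.frame(chrom = tx$chrom, start = min(tx$exons$start),
               end = max(tx$exons$end), stringsAsFactors = FALSE)
  }))
}

.overlaps_gene <- function(tx, ann) {
  if (is.null(ann)) return(FALSE)
  s <- min(tx$exons$start); e <- max(tx$exons$end)
  any(ann$chrom == tx$chrom & ann$start < e & ann$end > s)
}
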