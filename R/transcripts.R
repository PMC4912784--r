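#' Transcript model
#'
#' A strand-aware exon/CDS structure for one transcript. All coordinates are
#' internal convention: 0-based, half-open. GTF (1-based closed) and BED
#' (0-based half-open) are converted at the parser boundary.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand One of `"+"`, `"-"`, `"."` (unknown).
#' @param exons Data frame with integer columns `start`, `end` (0-based
#'   half-open), non-overlapping; sorted by start on construction.
#' @param cds Data frame like `exons` (possibly zero rows); must lie within
#'   the exon union.
#' @return Object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exons, cds = exons[0, , drop = FALSE]) {
  stopifnot(strand %in% c("+", "-", "."))
  exons <- .check_intervals(exons, transcript_id, "exon")
  cds <- .check_intervals(cds, transcript_id, "CDS", allow_empty = TRUE)
  if (nrow(cds)) {
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
    }, logical(1))
    if (!all(inside))
      stop("CDS intervals of ", transcript_id, " extend outside exons")
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds),
            class = "transcript_model")
}

.check_intervals <- function(x, id, what, allow_empty = FALSE) {
  x <- as.data.frame(x)[, c("start", "end")]
  if (!nrow(x)) {
    if (allow_empty) return(x)
    stop("no ", what, " intervals for transcript ", id)
  }
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  if (any(x$start < 0L) || any(x$end <= x$start))
    stop("invalid ", what, " interval in transcript ", id)
  x <- x[order(x$start), , drop = FALSE]
  rownames(x) <- NULL
  if (nrow(x) > 1L && any(x$start[-1L] < x$end[-nrow(x)]))
    stop("overlapping ", what, " intervals in transcript ", id)
  x
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%s  %d exon(s), %d CDS segment(s)\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

#' Read transcript models from a GTF file
#'
#' Accepts GTF2.2 in the style written by transcript assemblers: `exon` (and
#' optionally `CDS`) features carrying `transcript_id` and `gene_id`
#' attributes. 1-based closed GTF coordinates are converted to the internal
#' 0-based half-open convention; exons are sorted by start.
#'
#' @param path Path to a GTF file.
#' @return List of [transcript_model()] objects, one per `transcript_id`.
#' @export
read_gtf <- function(path) {
  if (file.size(path) == 0L) return(list())  # valid empty annotation
  gr <- rtracklayer::import(path, format = "gtf")
  feat <- as.character(gr$type)
  keep <- feat %in% c("exon", "CDS")
  gr <- gr[keep]
  feat <- feat[keep]
  if (!length(gr)) return(list())
  tid <- as.character(gr$transcript_id)
  if (any(is.na(tid) | !nzchar(tid)))
    stop("exon/CDS feature without transcript_id in ", path)
  gid <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else tid
  gid[is.na(gid)] <- tid[is.na(gid)]
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # GTF 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = chartr("*", ".", as.character(GenomicRanges::strand(gr))),
    feature = feat, transcript_id = tid, gene_id = gid,
    stringsAsFactors = FALSE)
  lapply(split(df, df$transcript_id), function(d) {
    if (length(unique(d$chrom)) != 1L || length(unique(d$strand)) != 1L)
      stop("transcript ", d$transcript_id[1L], " spans chromosomes or strands")
    ex <- d[d$feature == "exon", c("start", "end")]
    cd <- d[d$feature == "CDS", c("start", "end")]
    if (!nrow(ex)) ex <- cd  # CDS-only annotations
    transcript_model(d$transcript_id[1L], d$gene_id[1L], d$chrom[1L],
                     d$strand[1L], ex, cd)
  })
}

#' Write transcript models as GTF
#'
#' Inverse of [read_gtf()] for the features it reads; used by the fixture
#' generator and for coordinate round-trip checks.
#'
#' @param models List of [transcript_model()].
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @export
write_gtf <- function(models, path, source = "pgtools") {
  lines <- unlist(lapply(models, function(tx) {
    fmt <- function(iv, feat) {
      if (!nrow(iv)) return(character(0))
      sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
              tx$chrom, source, feat, iv$start + 1L, iv$end, tx$strand,
              tx$gene_id, tx$transcript_id)
    }
    c(fmt(tx$exons, "exon"), fmt(tx$cds, "CDS"))
  }), use.names = FALSE)
  writeLines(as.character(lines), path)
  invisible(path)
}

.extract <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not present in genome")
  n <- nchar(genome[[chrom]])
  if (start < 0L || end > n)
    stop(sprintf("interval %s:%d-%d outside chromosome bounds (length %d)",
                 chrom, start, end, n))
  substring(genome[[chrom]], start + 1L, end)
}

.concat_intervals <- function(iv, genome, chrom, strand) {
  s <- paste(vapply(seq_len(nrow(iv)), function(i) {
    .extract(genome, chrom, iv$start[i], iv$end[i])
  }, character(1)), collapse = "")
  if (strand == "-") reverse_complement(s) else s
}

#' Spliced transcript sequence
#'
#' Concatenates exon sequences in genomic order; minus-strand transcripts are
#' reverse-complemented so the result reads 5' to 3' on the coding strand.
#'
#' @param tx A [transcript_model()].
#' @param genome Named character vector from [read_genome()].
#' @return DNA string.
#' @export
spliced_sequence <- function(tx, genome) {
  .concat_intervals(tx$exons, genome, tx$chrom, tx$strand)
}

#' Spliced coding sequence
#'
#' As [spliced_sequence()] but over the CDS intervals only.
#'
#' @inheritParams spliced_sequence
#' @return DNA string (empty if the transcript has no CDS).
#' @export
cds_sequence <- function(tx, genome) {
  if (!nrow(tx$cds)) return("")
  .concat_intervals(tx$cds, genome, tx$chrom, tx$strand)
}
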