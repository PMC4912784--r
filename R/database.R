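#' Read a reference proteome FASTA as database entries
#'
#' @param path Path to a protein FASTA file.
#' @return Data frame of entries with category `REF`; the accession is the
#'   header up to the first whitespace.
#' @export
read_proteome <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  acc <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(acc))
    stop("duplicate accession(s) in proteome: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  data.frame(accession = acc, sequence = unname(toupper(as.character(set))),
             category = rep("REF", length(acc)),
             provenance = rep(sprintf("source=%s", basename(path)), length(acc)),
             stringsAsFactors = FALSE)
}

#' Assemble a customized search database
#'
#' Concatenates the reference proteome with variant-derived entries. With
#' `dedup` (the default) variant entries whose sequence is an exact substring
#' of some reference protein are dropped — such products are indistinguishable
#' from reference peptides and would inflate the novel search space.
#'
#' @param reference Data frame of `REF` entries ([read_proteome()]).
#' @param variants Data frame of variant entries (categories `SAP`, `INDEL`,
#'   `JUC`, `NTX`).
#' @param dedup Drop variant entries that are substrings of the reference?
#' @return A `custom_db` object: `entries` data frame plus a build `manifest`.
#' @export
assemble <- function(reference, variants, dedup = TRUE) {
  reference <- reference[, c("accession", "sequence", "category", "provenance")]
  if (nrow(variants)) {
    variants <- variants[, c("accession", "sequence", "category", "provenance")]
  } else variants <- .empty_entries()
  if (anyDuplicated(reference$accession) || anyDuplicated(variants$accession))
    stop("duplicate accessions within an input list")
  clash <- intersect(reference$accession, variants$accession)
  if (length(clash))
    stop("accession collision across lists: ", paste(clash, collapse = ", "))
  n_dropped <- 0L
  if (dedup && nrow(variants)) {
    haystack <- paste(reference$sequence, collapse = "#")
    redundant <- vapply(variants$sequence, function(s)
      grepl(s, haystack, fixed = TRUE), logical(1), USE.NAMES = FALSE)
    n_dropped <- sum(redundant)
    variants <- variants[!redundant, , drop = FALSE]
  }
  entries <- rbind(reference, variants)
  rownames(entries) <- NULL
  manifest <- list(
    n_reference = nrow(reference),
    n_variant = nrow(variants),
    n_redundant_dropped = n_dropped,
    counts_by_category = as.list(table(entries$category)),
    dedup = dedup,
    tool = paste0("pgtools ", as.character(utils::packageVersion("pgtools"))))
  structure(list(entries = entries, manifest = manifest), class = "custom_db")
}

#' @export
print.custom_db <- function(x, ...) {
  tab <- table(x$entries$category)
  cat("<custom_db> ", nrow(x$entries), " entries (",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Append reversed-sequence decoys
#'
#' Adds one decoy per target: the full sequence reversed, accession prefixed
#' `REV_`, category `DECOY`. Target order is preserved and decoys are
#' appended after all targets. Palindromic sequences (whose reversal equals
#' the target) are still emitted and flagged in the manifest.
#'
#' @param db A `custom_db` without decoys.
#' @param prefix Decoy accession prefix.
#' @return The `custom_db` with decoys appended.
#' @export
add_decoys <- function(db, prefix = "REV_") {
  stopifnot(inherits(db, "custom_db"))
  if (any(db$entries$category == "DECOY"))
    stop("database already contains decoys")
  targets <- db$entries
  rev_seq <- vapply(strsplit(targets$sequence, "", fixed = TRUE),
                    function(x) paste(rev(x), collapse = ""), character(1))
  decoys <- data.frame(
    accession = paste0(prefix, targets$accession),
    sequence = rev_seq, category = "DECOY",
    provenance = sprintf("decoy_of=%s;parent_category=%s",
                         targets$accession, targets$category),
    stringsAsFactors = FALSE)
  db$entries <- rbind(targets, decoys)
  rownames(db$entries) <- NULL
  db$manifest$n_decoys <- nrow(decoys)
  db$manifest$decoy_prefix <- prefix
  db$manifest$palindromic_targets <- targets$accession[rev_seq == targets$sequence]
  db
}

#' Write a customized database as FASTA
#'
#' Writes 60-column wrapped FASTA; each header is the accession followed by a
#' space and the serialized provenance. The build manifest is written
#' alongside as `<path>.manifest.json`.
#'
#' @param db A `custom_db`.
#' @param path Output FASTA path.
#' @export
write_fasta <- function(db, path) {
  stopifnot(inherits(db, "custom_db"))
  if (!nrow(db$entries)) stop("refusing to write an empty database")
  set <- Biostrings::AAStringSet(db$entries$sequence)
  names(set) <- paste(db$entries$accession, db$entries$provenance)
  Biostrings::writeXStringSet(set, path, width = 60L)
  jsonlite::write_json(db$manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read back a customized database FASTA
#'
#' Inverse of [write_fasta()]: recovers accession, sequence, provenance and
#' category (from the accession convention: `REV_` prefix is `DECOY`,
#' `VAR|<class>|` carries the class, anything else is `REF`).
#'
#' @param path FASTA path written by [write_fasta()].
#' @return A `custom_db` (manifest reloaded when present).
#' @export
read_custom_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  header <- names(set)
  acc <- sub("\\s.*$", "", header)
  prov <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header), "")
  category <- ifelse(startsWith(acc, "REV_"), "DECOY",
                ifelse(startsWith(acc, "VAR|"),
                       vapply(strsplit(acc, "|", fixed = TRUE), `[`, character(1), 2L),
                       "REF"))
  entries <- data.frame(accession = acc, sequence = unname(as.character(set)),
                        category = category, provenance = prov,
                        stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  mpath <- paste0(path, ".manifest.json")
  manifest <- if (file.exists(mpath)) jsonlite::read_json(mpath) else list()
  structure(list(entries = entries, manifest = manifest), class = "custom_db")
}

# Pull one key=value field out of a provenance string; NA when absent.
.prov_field <- function(provenance, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(provenance, regexec(pat, provenance))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
         character(1))
}

#' Build a customized proteogenomic search database
#'
#' One-call composer over the construction modules: reads the genome,
#' annotation and reference proteome, projects VCF variants onto coding
#' transcripts, translates BED12 junctions and novel/de novo transcripts, and
#' assembles everything with reversed decoys.
#'
#' @param genome_fa,gtf,proteome_fa Reference inputs (FASTA / GTF / FASTA).
#' @param vcf,junction_bed,novel_gtf,denovo_fa Optional evidence inputs; pass
#'   `NULL` to skip a source.
#' @param out Optional output FASTA path; when given the database is written
#'   with [write_fasta()].
#' @param flank_nt Junction flank length in nucleotides.
#' @param min_len Minimum emitted protein/fragment length (residues).
#' @param mode Translation mode for novel transcripts (see
#'   [novel_transcript_entries()]).
#' @param dedup Drop variant entries redundant with the reference?
#' @param keep_filters VCF FILTER values to keep.
#' @param code Codon table.
#' @return A `custom_db` with decoys.
#' @export
build_custom_db <- function(genome_fa, gtf, proteome_fa, vcf = NULL,
                            junction_bed = NULL, novel_gtf = NULL,
                            denovo_fa = NULL, out = NULL, flank_nt = 66L,
                            min_len = 7L, mode = "auto", dedup = TRUE,
                            keep_filters = c("PASS", "."),
                            code = genetic_code()) {
  genome <- read_genome(genome_fa)
  annotation <- read_gtf(gtf)
  reference <- read_proteome(proteome_fa)
  variant_entries <- .empty_entries()

  if (!is.null(vcf)) {
    recs <- read_vcf(vcf, keep_filters = keep_filters)
    coding <- Filter(function(tx) nrow(tx$cds) > 0L, annotation)
    for (tx in coding) {
      hits <- recs[recs$chrom == tx$chrom, , drop = FALSE]
      if (!nrow(hits)) next
      effects <- lapply(seq_len(nrow(hits)), function(i)
        project_variant(hits[i, ], tx, genome, code))
      variant_entries <- rbind(variant_entries,
                               build_variant_entries(effects, tx, genome, min_len))
    }
  }
  if (!is.null(junction_bed)) {
    juncs <- read_junction_bed(junction_bed)
    for (i in seq_len(nrow(juncs))) {
      je <- junction_to_entries(juncs[i, ], genome, flank_nt, min_len, code)
      variant_entries <- rbind(variant_entries,
                               je[, c("accession", "sequence", "category", "provenance")])
    }
  }
  novel_tx <- if (!is.null(novel_gtf)) read_gtf(novel_gtf) else list()
  denovo <- if (!is.null(denovo_fa)) {
    s <- Biostrings::readDNAStringSet(denovo_fa)
    stats::setNames(as.character(s), sub("\\s.*$", "", names(s)))
  } else character()
  if (length(novel_tx) || length(denovo)) {
    variant_entries <- rbind(variant_entries,
      novel_transcript_entries(novel_tx, genome, annotation, denovo,
                               mode = mode, min_len = min_len, code = code))
  }
  # identical products reached through different evidence keep one entry each
  variant_entries <- variant_entries[!duplicated(variant_entries$accession), ,
                                     drop = FALSE]
  db <- assemble(reference, variant_entries, dedup = dedup)
  db <- add_decoys(db)
  if (!is.null(out)) write_fasta(db, out)
  db
}
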