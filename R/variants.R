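#' Read variant records from a VCF file
#'
#' Multi-allelic lines are split into one record per ALT allele. Records with
#' symbolic ALT alleles (`<...>`, breakends) are skipped with a warning, as are
#' equal-length multi-nucleotide substitutions, which have no single-residue
#' product model here. By default only records with FILTER `PASS` or `.` are
#' kept.
#'
#' @param path Path to a VCF 4.x file.
#' @param keep_filters FILTER values to keep; set to `NULL` to keep everything.
#' @return Data frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `variant_id`, `var_type` (`SNV`/`INS`/`DEL`).
#' @export
read_vcf <- function(path, keep_filters = c("PASS", ".")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  m <- vcfR::getFIX(v)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L,
                                   dimnames = list(NULL, names(m)))
  fix <- as.data.frame(m, stringsAsFactors = FALSE)
  if (!nrow(fix))
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), variant_id = character(),
                      var_type = character(), stringsAsFactors = FALSE))
  fix$FILTER[is.na(fix$FILTER)] <- "."
  fix$ID[is.na(fix$ID) | fix$ID == "."] <-
    paste0("var", seq_len(nrow(fix)))[is.na(fix$ID) | fix$ID == "."]
  out <- list()
  for (i in seq_len(nrow(fix))) {
    pos <- suppressWarnings(as.integer(fix$POS[i]))
    if (is.na(pos) || pos < 1L)
      stop("malformed coordinate in VCF record ", i, " of ", path)
    if (!is.null(keep_filters) && !fix$FILTER[i] %in% keep_filters) next
    ref <- toupper(fix$REF[i])
    if (is.na(ref) || !grepl("^[ACGTN]+$", ref))
      stop("malformed REF allele in VCF record ", i, " of ", path)
    for (alt in strsplit(toupper(fix$ALT[i]), ",", fixed = TRUE)[[1L]]) {
      if (grepl("[][<>]", alt)) {
        warning("skipping symbolic ALT '", alt, "' in VCF record ", i)
        next
      }
      if (alt == "*" || alt == ".") next  # spanning-deletion / missing allele
      if (!grepl("^[ACGTN]+$", alt))
        stop("malformed ALT allele in VCF record ", i, " of ", path)
      type <- if (nchar(ref) == 1L && nchar(alt) == 1L) "SNV"
              else if (nchar(alt) > nchar(ref)) "INS"
              else if (nchar(alt) < nchar(ref)) "DEL"
              else NA_character_
      if (is.na(type)) {
        warning("skipping equal-length substitution in VCF record ", i)
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = pos, ref = ref, alt = alt,
        variant_id = fix$ID[i], var_type = type, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), variant_id = character(),
                      var_type = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Map a genomic position (0-based) to its offset in the plus-orientation
# spliced CDS, or NA when the position falls outside the CDS.
.cds_offset <- function(cds, gpos) {
  off <- 0L
  for (i in seq_len(nrow(cds))) {
    if (gpos >= cds$start[i] && gpos < cds$end[i])
      return(off + (gpos - cds$start[i]))
    off <- off + (cds$end[i] - cds$start[i])
  }
  NA_integer_
}

#' Project a variant onto a coding transcript
#'
#' Determines the protein-level consequence of one SNV or INDEL on one
#' transcript. Returns `NULL` when the variant does not touch the spliced CDS.
#' Variants that only partially overlap the CDS (spanning a CDS/intron
#' boundary) are classified `noncoding` with a warning; their product is not
#' defined. Positions and amino acids are strand-aware: on minus-strand
#' transcripts the CDS offset counts from the coding 5' end and alleles are
#' reverse-complemented internally.
#'
#' @param v One-row data frame (or list) as returned by [read_vcf()].
#' @param tx A [transcript_model()] with non-empty CDS.
#' @param genome Named character vector from [read_genome()].
#' @param code Codon table.
#' @return A `variant_effect` list with fields `transcript_id`, `variant_id`,
#'   `var_type`, `cds_position` (0-based, coding orientation), `ref_aa`,
#'   `alt_aa`, `effect_class`, `ref_protein`, `alt_protein`; or `NULL`.
#' @export
project_variant <- function(v, tx, genome, code = genetic_code()) {
  if (!nrow(tx$cds)) stop("transcript ", tx$transcript_id, " has no CDS")
  if (v$chrom != tx$chrom) return(NULL)
  p0 <- as.integer(v$pos) - 1L
  ref <- v$ref; alt <- v$alt
  obs <- .extract(genome, v$chrom, p0, p0 + nchar(ref))
  if (obs != ref)
    stop(sprintf("REF allele mismatch for %s at %s:%d (VCF '%s', genome '%s')",
                 v$variant_id, v$chrom, v$pos, ref, obs))
  # strip the shared leading context (VCF anchor base) -> replacement region
  k <- 0L
  while (k < min(nchar(ref), nchar(alt)) &&
         substring(ref, k + 1L, k + 1L) == substring(alt, k + 1L, k + 1L))
    k <- k + 1L
  ref2 <- substring(ref, k + 1L)
  alt2 <- substring(alt, k + 1L)
  g_start <- p0 + k
  g_end <- p0 + nchar(ref)          # replaced genomic bases: [g_start, g_end)
  cds <- tx$cds
  L <- sum(cds$end - cds$start)

  mk <- function(cds_position, ref_aa, alt_aa, effect_class,
                 ref_protein = NA_character_, alt_protein = NA_character_) {
    structure(list(transcript_id = tx$transcript_id, variant_id = v$variant_id,
                   var_type = v$var_type, cds_position = cds_position,
                   ref_aa = ref_aa, alt_aa = alt_aa,
                   effect_class = effect_class, ref_protein = ref_protein,
                   alt_protein = alt_protein), class = "variant_effect")
  }

  if (g_end > g_start) {
    offs <- vapply(seq.int(g_start, g_end - 1L), function(p)
      .cds_offset(cds, p), integer(1))
    if (all(is.na(offs))) return(NULL)
    if (any(is.na(offs)) || (length(offs) > 1L && any(diff(offs) != 1L))) {
      warning(v$variant_id, " overlaps a CDS/intron boundary on ",
              tx$transcript_id, "; classified noncoding")
      return(mk(NA_integer_, NA_character_, NA_character_, "noncoding"))
    }
    o1 <- offs[1L]; o2 <- offs[length(offs)] + 1L
  } else {
    # pure insertion: anchor after the base left of the insertion point
    o_anchor <- .cds_offset(cds, g_start - 1L)
    if (is.na(o_anchor)) return(NULL)
    o1 <- o2 <- o_anchor + 1L
  }

  cds_plus <- .concat_intervals(cds, genome, tx$chrom, "+")
  alt_cds_plus <- paste0(substring(cds_plus, 1L, o1),
                         alt2,
                         substring(cds_plus, o2 + 1L))
  if (tx$strand == "-") {
    ref_cds <- reverse_complement(cds_plus)
    alt_cds <- reverse_complement(alt_cds_plus)
    cds_position <- if (v$var_type == "SNV") L - 1L - o1 else L - o2
  } else {
    ref_cds <- cds_plus
    alt_cds <- alt_cds_plus
    cds_position <- o1
  }

  ref_t <- translate(ref_cds, code)
  alt_t <- translate(alt_cds, code)
  ref_protein <- translate(ref_cds, code, to_first_stop = TRUE)
  alt_protein <- translate(alt_cds, code, to_first_stop = TRUE)

  if (nchar(ref2) != nchar(alt2)) {
    cls <- if ((nchar(alt2) - nchar(ref2)) %% 3L == 0L) "inframe_indel"
           else "frameshift"
    return(mk(cds_position, "", "", cls, ref_protein, alt_protein))
  }
  ci <- cds_position %/% 3L
  ref_aa <- substring(ref_t, ci + 1L, ci + 1L)
  alt_aa <- substring(alt_t, ci + 1L, ci + 1L)
  cls <- if (ref_aa == alt_aa) "synonymous"
         else if (ref_aa == "*") "stop_loss"
         else if (alt_aa == "*") "stop_gain"
         else "missense"
  mk(cds_position, ref_aa, alt_aa, cls, ref_protein, alt_protein)
}

#' Variant protein database entries
#'
#' Emits one database entry per non-synonymous coding effect: full-length
#' variant proteins for missense and stop-loss SNVs, the truncated protein for
#' stop-gain SNVs, and the protein translated from the CDS start through the
#' new first stop for frameshift and in-frame INDELs. Synonymous and noncoding
#' effects emit nothing. Accessions are `VAR`-prefixed:
#' `VAR|SAP|<variant_id>|<transcript_id>|<cds_position>:<ref_aa>><alt_aa>` for
#' SNV products and `VAR|INDEL|<variant_id>|<transcript_id>|<cds_position>:<class>`
#' for INDEL products.
#'
#' @param effects List of `variant_effect` objects for one transcript.
#' @param tx The [transcript_model()] the effects refer to.
#' @param genome Named character vector from [read_genome()].
#' @param min_len Minimum emitted protein length (residues); shorter products
#'   (e.g. early stop-gain truncations) are suppressed.
#' @return Data frame of database entries (`accession`, `sequence`,
#'   `category`, `provenance`).
#' @export
build_variant_entries <- function(effects, tx, genome, min_len = 7L) {
  rows <- lapply(effects, function(e) {
    if (is.null(e) || e$effect_class %in% c("synonymous", "noncoding"))
      return(NULL)
    if (!identical(e$transcript_id, tx$transcript_id))
      stop("effect does not refer to transcript ", tx$transcript_id)
    seq <- e$alt_protein
    if (is.na(seq) || nchar(seq) < min_len) return(NULL)
    if (e$var_type == "SNV") {
      acc <- sprintf("VAR|SAP|%s|%s|%d:%s>%s", e$variant_id, e$transcript_id,
                     e$cds_position, e$ref_aa, e$alt_aa)
      cat_ <- "SAP"
    } else {
      acc <- sprintf("VAR|INDEL|%s|%s|%d:%s", e$variant_id, e$transcript_id,
                     e$cds_position, e$effect_class)
      cat_ <- "INDEL"
    }
    data.frame(accession = acc, sequence = seq, category = cat_,
               provenance = sprintf("variant_id=%s;transcript_id=%s;cds_position=%d;effect=%s",
                                    e$variant_id, e$transcript_id,
                                    e$cds_position, e$effect_class),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.empty_entries())
  do.call(rbind, rows)
}

.empty_entries <- function() {
  data.frame(accession = character(), sequence = character(),
             category = character(), provenance = character(),
             stringsAsFactors = FALSE)
}
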