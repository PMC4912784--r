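#' @keywords internal
"_PACKAGE"

# Standard genetic code (NCBI translation table 1), written out so the
# translation path shares no code with packages used as test oracles.
.STANDARD_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' Genetic code table
#'
#' Returns a codon-to-amino-acid map used by [translate()]. The default is the
#' standard code (NCBI table 1); a custom map may be supplied to override
#' individual codons, e.g. for organisms with non-standard codes.
#'
#' @param overrides Named character vector of codon -> amino acid overrides
#'   (codons in DNA alphabet, `"*"` for stop).
#' @return Named character vector of length 64 (class `genetic_code`).
#' @export
#' @examples
#' code <- genetic_code()
#' code[["ATG"]]
genetic_code <- function(overrides = NULL) {
  code <- .STANDARD_CODE
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!names(overrides) %in% names(code)))
      stop("overrides must be named by valid DNA codons")
    code[names(overrides)] <- unname(overrides)
  }
  stopifnot(length(code) == 64L)
  class(code) <- c("genetic_code", class(code))
  code
}

#' Reverse complement of a DNA string
#'
#' @param seq Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("ATGC")  # "GCAT"
reverse_complement <- function(seq) {
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Translate a DNA string to protein
#'
#' Codons are read left to right; a trailing partial codon is ignored. Codons
#' containing an ambiguous base (anything outside A/C/G/T) translate to `"X"`.
#' Stops are rendered as `"*"` unless `to_first_stop` is set, in which case the
#' protein is truncated at the first stop.
#'
#' @param seq Character scalar (DNA, upper case).
#' @param code Codon table from [genetic_code()].
#' @param to_first_stop Truncate at the first stop codon?
#' @return Amino-acid string (possibly empty).
#' @export
#' @examples
#' translate("ATGGCC")              # "MA"
#' translate("ATGTAAATG", to_first_stop = TRUE)  # "M"
translate <- function(seq, code = genetic_code(), to_first_stop = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (n < 3L) return("")
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # ambiguous base in codon
  if (to_first_stop) {
    stop_at <- match("*", aa)
    if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1L)]
  }
  paste(aa, collapse = "")
}

#' Read a genome FASTA into named sequences
#'
#' Loads every record, uppercases the sequence, maps U to T and collapses IUPAC
#' ambiguity codes other than N to N. Record names are truncated at the first
#' whitespace and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase DNA string per chromosome.
#' @export
read_genome <- function(path) {
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop("duplicate FASTA header(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  bad <- regexpr("[^ACGTNRYSWKMBDHV]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-IUPAC character '%s' in record '%s' at position %d",
                 substring(seqs[i], bad[i], bad[i]), nm[i], bad[i]))
  }
  # ambiguity codes other than N carry no codon information here
  seqs <- gsub("[RYSWKMBDHV]", "N", seqs)
  if (any(!nzchar(seqs))) stop("empty sequence in FASTA record")
  names(seqs) <- nm
  seqs
}
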