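#' Read peptide-spectrum matches
#'
#' Reads PSMs either from a tab-delimited table with columns `spectrum`,
#' `peptide`, `proteins` (`;`-separated accessions), `evalue`, `charge`, or
#' from a subset of mzIdentML 1.1 (SpectrumIdentificationResult/Item with
#' peptide sequences, protein references and an e-value cvParam). Scores are
#' computed as `-log2(evalue)`; only the best PSM (lowest e-value) per
#' spectrum is retained. A PSM is a decoy when all of its accessions carry
#' the decoy prefix.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"mzid"`.
#' @param decoy_prefix Accession prefix marking decoy entries.
#' @return Data frame with columns `spectrum_id`, `peptide`, `proteins`,
#'   `evalue`, `score`, `charge`, `is_decoy`, `is_novel` (`NA` until
#'   [flag_novelty()]), `novel_class`, `gene_status`.
#' @export
read_psm_table <- function(path, dialect = c("tsv", "mzid"),
                           decoy_prefix = "REV_") {
  dialect <- match.arg(dialect)
  raw <- if (dialect == "tsv") .read_psm_tsv(path) else .read_psm_mzid(path)
  if (any(is.na(raw$evalue)) || any(raw$evalue <= 0))
    stop("e-values must be positive")
  raw$peptide <- toupper(raw$peptide)
  raw$score <- -log2(raw$evalue)
  # best PSM per spectrum (lowest e-value; first row wins ties)
  raw <- raw[order(raw$evalue), , drop = FALSE]
  raw <- raw[!duplicated(raw$spectrum_id), , drop = FALSE]
  raw <- raw[order(raw$spectrum_id), , drop = FALSE]
  accs <- strsplit(raw$proteins, ";", fixed = TRUE)
  raw$is_decoy <- vapply(accs, function(a) length(a) > 0L &&
                           all(startsWith(a, decoy_prefix)), logical(1))
  raw$is_novel <- NA
  raw$novel_class <- "none"
  raw$gene_status <- "none"
  rownames(raw) <- NULL
  raw
}

.read_psm_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("spectrum", "peptide", "proteins", "evalue", "charge")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("PSM table is missing column(s): ", paste(miss, collapse = ", "))
  data.frame(spectrum_id = as.character(d$spectrum),
             peptide = as.character(d$peptide),
             proteins = as.character(d$proteins),
             evalue = as.numeric(d$evalue),
             charge = as.integer(d$charge), stringsAsFactors = FALSE)
}

.read_psm_mzid <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pep_seq <- stats::setNames(
    xml2::xml_text(xml2::xml_find_all(doc, ".//Peptide/PeptideSequence")),
    xml2::xml_attr(xml2::xml_find_all(doc, ".//Peptide"), "id"))
  ev_nodes <- xml2::xml_find_all(doc, ".//PeptideEvidence")
  ev_db <- stats::setNames(xml2::xml_attr(ev_nodes, "dBSequence_ref"),
                           xml2::xml_attr(ev_nodes, "id"))
  db_nodes <- xml2::xml_find_all(doc, ".//DBSequence")
  db_acc <- stats::setNames(xml2::xml_attr(db_nodes, "accession"),
                            xml2::xml_attr(db_nodes, "id"))
  results <- xml2::xml_find_all(doc, ".//SpectrumIdentificationResult")
  rows <- list()
  for (res in results) {
    spec <- xml2::xml_attr(res, "spectrumID")
    for (item in xml2::xml_find_all(res, "./SpectrumIdentificationItem")) {
      pref <- xml2::xml_attr(item, "peptide_ref")
      charge <- as.integer(xml2::xml_attr(item, "chargeState"))
      cvs <- xml2::xml_find_all(item, "./cvParam")
      cvacc <- xml2::xml_attr(cvs, "accession")
      cvname <- tolower(xml2::xml_attr(cvs, "name"))
      sel <- which(cvacc %in% c("MS:1002053", "MS:1001330", "MS:1001172") |
                     grepl("e-?value|expect", cvname))
      if (!length(sel)) stop("SpectrumIdentificationItem without e-value cvParam")
      ev <- as.numeric(xml2::xml_attr(cvs[sel[1L]], "value"))
      refs <- xml2::xml_attr(
        xml2::xml_find_all(item, "./PeptideEvidenceRef"), "peptideEvidence_ref")
      accs <- unique(unname(db_acc[ev_db[refs]]))
      rows[[length(rows) + 1L]] <- data.frame(
        spectrum_id = spec, peptide = unname(pep_seq[pref]),
        proteins = paste(accs, collapse = ";"), evalue = ev,
        charge = charge, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no SpectrumIdentificationItem records in ", path)
  do.call(rbind, rows)
}

.fold_il <- function(x) chartr("I", "L", x)

#' Flag novel peptides by reference-proteome mapping
#'
#' A target peptide is novel when it is not a substring of any reference
#' protein (optionally after folding I to L, which are isobaric). The novel
#' class is taken from the categories of the `VAR` entries containing the
#' peptide (`none` when the matches span several classes). Decoy PSMs are
#' assigned to the novel decoy class when any of their decoy accessions
#' derives from a `VAR` entry.
#'
#' @param psms Data frame from [read_psm_table()].
#' @param db A `custom_db` (with decoys) used for the search.
#' @param equate_il Treat I and L as equivalent when mapping?
#' @return `psms` with `is_novel`, `novel_class` and `matched_classes` filled
#'   in.
#' @export
flag_novelty <- function(psms, db, equate_il = FALSE) {
  stopifnot(inherits(db, "custom_db"))
  entries <- db$entries
  refs <- entries$sequence[entries$category == "REF"]
  vars <- entries[!entries$category %in% c("REF", "DECOY"), , drop = FALSE]
  fold <- if (equate_il) .fold_il else identity
  ref_hay <- paste(fold(refs), collapse = "#")
  target_hay <- paste(fold(entries$sequence[entries$category != "DECOY"]),
                      collapse = "#")
  var_seq <- fold(vars$sequence)

  uniq <- unique(psms$peptide)
  res_novel <- logical(length(uniq))
  res_class <- character(length(uniq))
  res_matched <- character(length(uniq))
  for (i in seq_along(uniq)) {
    pep <- fold(uniq[i])
    in_ref <- grepl(pep, ref_hay, fixed = TRUE)
    res_novel[i] <- !in_ref
    if (in_ref) { res_class[i] <- "none"; res_matched[i] <- ""; next }
    hit <- grepl(pep, var_seq, fixed = TRUE)
    classes <- sort(unique(vars$category[hit]))
    res_matched[i] <- paste(classes, collapse = ";")
    res_class[i] <- if (length(classes) == 1L) classes else "none"
  }
  idx <- match(psms$peptide, uniq)
  decoy <- psms$is_decoy
  psms$is_novel <- res_novel[idx]
  psms$novel_class <- res_class[idx]
  psms$matched_classes <- res_matched[idx]

  # decoy novelty: any accession whose parent entry is a VAR entry
  if (any(decoy)) {
    dec_entries <- entries[entries$category == "DECOY", , drop = FALSE]
    parent_cat <- stats::setNames(.prov_field(dec_entries$provenance,
                                              "parent_category"),
                                  dec_entries$accession)
    psms$is_novel[decoy] <- vapply(
      strsplit(psms$proteins[decoy], ";", fixed = TRUE),
      function(a) any(parent_cat[a] %in% c("SAP", "INDEL", "JUC", "NTX"),
                      na.rm = TRUE), logical(1))
    psms$novel_class[decoy] <- "none"
    psms$matched_classes[decoy] <- ""
  }
  # a target peptide absent from the whole target space means inputs disagree
  target_pep <- unique(psms$peptide[!decoy])
  unmatched <- target_pep[!vapply(fold(target_pep), grepl, logical(1),
                                  x = target_hay, fixed = TRUE)]
  if (length(unmatched))
    stop("peptide(s) not found in any database entry: ",
         paste(utils::head(unmatched, 5L), collapse = ", "))
  psms
}

#' Class-separate FDR for novel peptides
#'
#' Estimates the false discovery rate of novel-peptide identifications at a
#' score threshold as `D+ * (Dn / D) / Tn+`, where `D+` is the number of
#' decoy PSMs at or above the threshold, `Tn+` the number of novel target
#' PSMs at or above the threshold, and `Dn / D` the fraction of all
#' identified decoy PSMs whose entries derive from the novel (VAR) part of
#' the search space. The estimate is defined as 0 when `D = 0` or `Tn+ = 0`
#' and is capped at 1.
#'
#' @param psms Scored, novelty-flagged PSMs ([flag_novelty()]).
#' @param threshold_score Score threshold (PSMs with `score >=` it count).
#' @return List with `tally` (integers `D_plus`, `T_n_plus`, `D_n`, `D`) and
#'   `fdr_n`.
#' @export
novel_fdr <- function(psms, threshold_score) {
  if (any(is.na(psms$is_novel))) stop("run flag_novelty() first")
  above <- psms$score >= threshold_score
  D_plus <- sum(psms$is_decoy & above)
  D <- sum(psms$is_decoy)
  D_n <- sum(psms$is_decoy & psms$is_novel)
  T_n_plus <- sum(!psms$is_decoy & psms$is_novel & above)
  fdr_n <- if (D == 0L || T_n_plus == 0L) 0 else
    min(1, D_plus * (D_n / D) / T_n_plus)
  list(tally = list(D_plus = D_plus, T_n_plus = T_n_plus, D_n = D_n, D = D),
       fdr_n = fdr_n)
}

#' Global target-decoy FDR at a threshold
#'
#' The classical estimate `D+ / T+` over all target PSMs, defined as 0 when
#' no targets pass and capped at 1.
#'
#' @inheritParams novel_fdr
#' @return A number in `[0, 1]`.
#' @export
global_fdr <- function(psms, threshold_score) {
  above <- psms$score >= threshold_score
  D_plus <- sum(psms$is_decoy & above)
  T_plus <- sum(!psms$is_decoy & above)
  if (T_plus == 0L) 0 else min(1, D_plus / T_plus)
}

#' Monotone (step-down) FDR envelope over candidate thresholds
#'
#' Raw target-decoy FDR estimates need not decrease monotonically with the
#' score threshold; the step-down envelope assigns each threshold the minimum
#' raw estimate achievable at any threshold at or below it (the q-value of
#' the threshold), which is non-increasing by construction and is what
#' reports display.
#'
#' @param psms Scored (and, for `scope = "novel"`, novelty-flagged) PSMs.
#' @param scope `"global"` or `"novel"`.
#' @return Data frame with `threshold` (ascending unique scores), `fdr_raw`,
#'   `fdr` (monotone envelope).
#' @export
fdr_step_down <- function(psms, scope = c("global", "novel")) {
  scope <- match.arg(scope)
  thr <- sort(unique(psms$score))
  raw <- vapply(thr, function(t)
    if (scope == "global") global_fdr(psms, t) else novel_fdr(psms, t)$fdr_n,
    numeric(1))
  data.frame(threshold = thr, fdr_raw = raw, fdr = cummin(raw))
}

#' Filter PSMs at a target FDR
#'
#' Chooses the smallest (most permissive) score threshold among the observed
#' scores whose estimated FDR is at or below `target_fdr` — the global
#' `D+/T+` estimator for the canonical scope, the class-separate [novel_fdr()]
#' for the novel scope — and returns the surviving target PSMs of that scope.
#' When no threshold reaches the target an empty set is returned with a
#' warning.
#'
#' @param psms Scored, novelty-flagged PSMs.
#' @param target_fdr Nominal FDR, in (0, 1); conventionally 0.01.
#' @param class_scope `"global"` (all target PSMs) or `"novel"` (novel target
#'   PSMs only).
#' @return List with `threshold`, `fdr_at_threshold`, and `psms` (the
#'   surviving target PSMs of the scope).
#' @export
filter_at_fdr <- function(psms, target_fdr = 0.01,
                          class_scope = c("global", "novel")) {
  class_scope <- match.arg(class_scope)
  stopifnot(target_fdr > 0, target_fdr < 1)
  est <- function(t) if (class_scope == "global") global_fdr(psms, t)
                     else novel_fdr(psms, t)$fdr_n
  thr <- sort(unique(psms$score))
  ok <- which(vapply(thr, function(t) est(t) <= target_fdr, logical(1)))
  if (!length(ok)) {
    warning("no score threshold reaches FDR ", target_fdr,
            " for scope '", class_scope, "'")
    return(list(threshold = Inf, fdr_at_threshold = NA_real_,
                psms = psms[0, , drop = FALSE]))
  }
  t_star <- thr[ok[1L]]
  in_scope <- !psms$is_decoy
  if (class_scope == "novel") in_scope <- in_scope & psms$is_novel
  keep <- in_scope & psms$score >= t_star
  if (!any(keep) && any(in_scope))
    warning("no PSMs survive at FDR ", target_fdr,
            " for scope '", class_scope, "'")
  list(threshold = t_star, fdr_at_threshold = est(t_star),
       psms = psms[keep, , drop = FALSE])
}

#' Classify surviving novel peptides
#'
#' A novel peptide uniquely matching variant-derived entries (`SAP`, `INDEL`,
#' `JUC`) is a peptide variant of an existing gene. A novel peptide uniquely
#' matching `NTX` entries whose source transcript overlaps no annotated gene
#' is the product of a novel gene. Peptides matching entries of several
#' classes, or `NTX` entries of gene-overlapping transcripts, are left
#' unclassified (`gene_status = "none"`) with a message.
#'
#' @param psms Novelty-flagged (typically FDR-surviving) PSMs.
#' @param db The `custom_db` used for the search (carries gene-overlap
#'   metadata on `NTX` entries).
#' @return `psms` with `gene_status` filled in.
#' @export
classify_novel <- function(psms, db) {
  stopifnot(inherits(db, "custom_db"))
  entries <- db$entries
  ntx <- entries[entries$category == "NTX", , drop = FALSE]
  ntx_overlap <- .prov_field(ntx$provenance, "gene_overlap")
  novel_idx <- which(!psms$is_decoy & psms$is_novel)
  for (i in novel_idx) {
    classes <- strsplit(psms$matched_classes[i], ";", fixed = TRUE)[[1L]]
    if (length(classes) != 1L) {
      if (length(classes) > 1L)
        message("ambiguous novel peptide ", psms$peptide[i],
                " matches classes ", paste(classes, collapse = ","))
      psms$gene_status[i] <- "none"
      next
    }
    if (classes %in% c("SAP", "INDEL", "JUC")) {
      psms$gene_status[i] <- "existing_gene_variant"
    } else if (classes == "NTX") {
      hit <- grepl(psms$peptide[i], ntx$sequence, fixed = TRUE)
      if (any(hit) && all(ntx_overlap[hit] == "no", na.rm = TRUE)) {
        psms$gene_status[i] <- "novel_gene_product"
      } else {
        message("novel-transcript peptide ", psms$peptide[i],
                " overlaps an annotated gene; left unclassified")
        psms$gene_status[i] <- "none"
      }
    }
  }
  psms
}

#' Minimal protein list by parsimony
#'
#' Greedy set cover over the surviving canonical PSMs: proteins with
#' identical peptide sets are merged into one group, then groups are selected
#' iteratively by most unexplained peptides (ties: larger total peptide set,
#' then lexicographically smallest accession) until every peptide is covered.
#'
#' @param canonical_psms Surviving canonical (non-novel, non-decoy) PSMs.
#' @param decoy_prefix Accessions with this prefix are ignored.
#' @return List of protein groups, each a list with `representative`,
#'   `members`, `peptides`.
#' @export
infer_proteins <- function(canonical_psms, decoy_prefix = "REV_") {
  if (!nrow(canonical_psms)) return(list())
  pairs <- unique(do.call(rbind, lapply(seq_len(nrow(canonical_psms)),
    function(i) {
      accs <- strsplit(canonical_psms$proteins[i], ";", fixed = TRUE)[[1L]]
      accs <- accs[!startsWith(accs, decoy_prefix)]
      if (!length(accs)) return(NULL)
      data.frame(peptide = canonical_psms$peptide[i], accession = accs,
                 stringsAsFactors = FALSE)
    })))
  pepsets <- lapply(split(pairs$peptide, pairs$accession),
                    function(p) sort(unique(p)))
  # merge indistinguishable proteins (identical peptide sets)
  key <- vapply(pepsets, paste, character(1), collapse = "\r")
  groups <- lapply(split(names(pepsets), key), sort)
  group_peps <- lapply(groups, function(g) pepsets[[g[1L]]])
  uncovered <- sort(unique(pairs$peptide))
  selected <- list()
  remaining <- seq_along(groups)
  while (length(uncovered) && length(remaining)) {
    gain <- vapply(remaining, function(g)
      sum(group_peps[[g]] %in% uncovered), integer(1))
    if (max(gain) == 0L) break
    total <- vapply(remaining, function(g) length(group_peps[[g]]), integer(1))
    rep_acc <- vapply(remaining, function(g) groups[[g]][1L], character(1))
    ord <- order(-gain, -total, rep_acc)
    pick <- remaining[ord[1L]]
    selected[[length(selected) + 1L]] <- list(
      representative = groups[[pick]][1L],
      members = groups[[pick]],
      peptides = group_peps[[pick]])
    uncovered <- setdiff(uncovered, group_peps[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  # prune: a group picked early can be made redundant by later picks
  repeat {
    drop <- NA_integer_
    for (k in seq_along(selected)) {
      rest <- unique(unlist(lapply(selected[-k], `[[`, "peptides")))
      if (all(selected[[k]]$peptides %in% rest)) { drop <- k; break }
    }
    if (is.na(drop)) break
    selected <- selected[-drop]
  }
  selected
}

#' Post-process search results end to end
#'
#' Composes the post-processing stages: novelty flagging against the search
#' database, separate FDR filtering of canonical (global estimator) and novel
#' (class-separate estimator) PSMs at the same nominal level, novel-peptide
#' classification, and parsimonious protein inference over the canonical
#' survivors.
#'
#' @param psms PSM data frame ([read_psm_table()]) or a path to a PSM table.
#' @param db The `custom_db` used for the search.
#' @param fdr Nominal FDR for both classes.
#' @param equate_il Treat I/L as equivalent in novelty mapping?
#' @param dialect Passed to [read_psm_table()] when `psms` is a path.
#' @return Object of class `pg_results`: list with `psms` (all, flagged),
#'   `canonical`, `novel` (surviving sets), `thresholds`, `tally`
#'   (novel-FDR counters at the novel threshold), `groups`, `fdr`.
#' @export
postprocess_psms <- function(psms, db, fdr = 0.01, equate_il = FALSE,
                             dialect = "tsv") {
  if (is.character(psms)) psms <- read_psm_table(psms, dialect = dialect)
  psms <- flag_novelty(psms, db, equate_il = equate_il)
  fg <- filter_at_fdr(psms, fdr, "global")
  fn <- filter_at_fdr(psms, fdr, "novel")
  canonical <- fg$psms[!fg$psms$is_novel, , drop = FALSE]
  novel <- classify_novel(fn$psms, db)
  groups <- infer_proteins(canonical)
  structure(list(psms = psms, canonical = canonical, novel = novel,
                 thresholds = c(global = fg$threshold, novel = fn$threshold),
                 tally = if (is.finite(fn$threshold))
                   novel_fdr(psms, fn$threshold)$tally else NULL,
                 groups = groups, fdr = fdr),
            class = "pg_results")
}

#' @export
print.pg_results <- function(x, ...) {
  cat("<pg_results>\n")
  cat(sprintf("  canonical peptides: %d (threshold %.3f)\n",
              length(unique(x$canonical$peptide)), x$thresholds[["global"]]))
  tab <- table(factor(x$novel$novel_class[!duplicated(x$novel$peptide)],
                      levels = c("SAP", "INDEL", "JUC", "NTX", "none")))
  cat(sprintf("  novel peptides: %d (threshold %.3f) [%s]\n",
              length(unique(x$novel$peptide)), x$thresholds[["novel"]],
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  cat(sprintf("  protein groups: %d\n", length(x$groups)))
  invisible(x)
}
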