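#' Peptide-level result table
#'
#' One row per distinct surviving peptide: sequence, class (`canonical` or
#' the novel class), best score, number of spectra, matched accessions.
#' Rows are sorted by class, then descending best score, then sequence, so
#' identical inputs always produce identical files.
#'
#' @param results A `pg_results` object from [postprocess_psms()].
#' @return Data frame.
#' @export
peptide_table <- function(results) {
  stopifnot(inherits(results, "pg_results"))
  mk <- function(d, cls) {
    if (!nrow(d)) return(NULL)
    sp <- split(d, d$peptide)
    out <- do.call(rbind, lapply(sp, function(x) data.frame(
      sequence = x$peptide[1L],
      class = if (is.null(cls)) x$novel_class[1L] else cls,
      gene_status = x$gene_status[1L],
      best_score = max(x$score),
      n_spectra = nrow(x),
      accessions = paste(sort(unique(unlist(
        strsplit(x$proteins, ";", fixed = TRUE)))), collapse = ";"),
      stringsAsFactors = FALSE)))
    out
  }
  tab <- rbind(mk(results$canonical, "canonical"), mk(results$novel, NULL))
  if (is.null(tab))
    return(data.frame(sequence = character(), class = character(),
                      gene_status = character(), best_score = numeric(),
                      n_spectra = integer(), accessions = character(),
                      stringsAsFactors = FALSE))
  tab <- tab[order(tab$class, -tab$best_score, tab$sequence), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Protein-group result table
#'
#' @param results A `pg_results` object.
#' @return Data frame with one row per inferred protein group.
#' @export
protein_table <- function(results) {
  stopifnot(inherits(results, "pg_results"))
  if (!length(results$groups))
    return(data.frame(representative = character(), members = character(),
                      n_peptides = integer(), peptides = character(),
                      stringsAsFactors = FALSE))
  tab <- do.call(rbind, lapply(results$groups, function(g) data.frame(
    representative = g$representative,
    members = paste(g$members, collapse = ";"),
    n_peptides = length(g$peptides),
    peptides = paste(g$peptides, collapse = ";"),
    stringsAsFactors = FALSE)))
  tab <- tab[order(-tab$n_peptides, tab$representative), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write the tab-delimited result tables
#'
#' Writes `peptides.tsv` and `proteins.tsv` into `outdir` with a stable
#' column order and deterministic row sort.
#'
#' @param results A `pg_results` object.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_tables <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(outdir, "peptides.tsv")
  rp <- file.path(outdir, "proteins.tsv")
  utils::write.table(peptide_table(results), pp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(protein_table(results), rp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(peptides = pp, proteins = rp))
}

#' Run summary for reporting
#'
#' Tallies the surviving identifications: novel peptide counts by class,
#' canonical peptide count, protein group count, thresholds used, and binned
#' score histograms contrasting novel and canonical PSMs.
#'
#' @param results A `pg_results` object.
#' @param bins Number of histogram bins.
#' @return A `run_summary` list.
#' @export
run_summary <- function(results, bins = 20L) {
  stopifnot(inherits(results, "pg_results"))
  ptab <- peptide_table(results)
  novel <- ptab[ptab$class != "canonical", , drop = FALSE]
  class_counts <- vapply(c("SAP", "INDEL", "JUC", "NTX", "none"),
                         function(k) sum(novel$class == k), integer(1))
  scores <- c(results$canonical$score, results$novel$score)
  if (length(scores)) {
    breaks <- pretty(range(scores), n = bins)
    h_can <- graphics::hist(results$canonical$score, breaks = breaks,
                            plot = FALSE)$counts
    h_nov <- if (nrow(results$novel))
      graphics::hist(results$novel$score, breaks = breaks, plot = FALSE)$counts
    else rep(0L, length(breaks) - 1L)
  } else {
    breaks <- numeric(0); h_can <- integer(0); h_nov <- integer(0)
  }
  structure(list(
    class_counts = class_counts,
    n_novel_peptides = nrow(novel),
    n_canonical_peptides = sum(ptab$class == "canonical"),
    n_protein_groups = length(results$groups),
    thresholds = results$thresholds,
    fdr = results$fdr,
    hist_breaks = breaks, hist_canonical = h_can, hist_novel = h_nov),
    class = "run_summary")
}

#' Write a self-contained HTML summary report
#'
#' Emits a single HTML file (no external assets) with the novel-class
#' breakdown, the canonical/novel score-distribution histogram rendered as
#' inline SVG, the thresholds and the counts — all taken from the same
#' `run_summary`, so every displayed number equals the corresponding tally of
#' the TSV tables.
#'
#' @param summary A [run_summary()] object.
#' @param outdir Output directory.
#' @param filename Report file name.
#' @return Invisibly, the report path.
#' @export
write_html_report <- function(summary, outdir, filename = "report.html") {
  stopifnot(inherits(summary, "run_summary"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(outdir, filename)
  cc <- summary$class_counts
  class_rows <- paste(sprintf(
    "<tr><td>%s</td><td id=\"count-%s\">%d</td></tr>",
    c("SAP", "INDEL", "Junction", "Novel transcript", "Unclassified"),
    c("SAP", "INDEL", "JUC", "NTX", "none"),
    as.integer(cc[c("SAP", "INDEL", "JUC", "NTX", "none")])), collapse = "\n")
  svg <- .hist_svg(summary)
  html <- sprintf(
'<!DOCTYPE html>
<html><head><meta charset="utf-8"><title>Proteogenomic identification summary</title>
<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}
td,th{border:1px solid #999;padding:4px 10px}h2{margin-top:1.5em}</style></head>
<body>
<h1>Proteogenomic identification summary</h1>
<h2>Identifications</h2>
<table>
<tr><th>Quantity</th><th>Count</th></tr>
<tr><td>Canonical peptides</td><td id="count-canonical">%d</td></tr>
<tr><td>Novel peptides</td><td id="count-novel">%d</td></tr>
<tr><td>Protein groups</td><td id="count-groups">%d</td></tr>
</table>
<h2>Novel peptides by class</h2>
<table>
<tr><th>Class</th><th>Count</th></tr>
%s
</table>
<h2>Score distribution (-log2 e-value)</h2>
%s
<h2>Parameters</h2>
<table>
<tr><td>Nominal FDR</td><td>%g</td></tr>
<tr><td>Canonical score threshold</td><td>%.4f</td></tr>
<tr><td>Novel score threshold</td><td>%.4f</td></tr>
</table>
</body></html>',
    summary$n_canonical_peptides, summary$n_novel_peptides,
    summary$n_protein_groups, class_rows, svg, summary$fdr,
    summary$thresholds[["global"]], summary$thresholds[["novel"]])
  writeLines(html, path)
  invisible(path)
}

.hist_svg <- function(summary, width = 640L, height = 240L) {
  k <- length(summary$hist_canonical)
  if (!k) return("<p>No surviving PSMs.</p>")
  maxc <- max(c(summary$hist_canonical, summary$hist_novel, 1L))
  bw <- width / k
  bar <- function(counts, fill, off) paste(vapply(seq_len(k), function(i) {
    h <- round(height * counts[i] / maxc, 1)
    sprintf('<rect x="%.1f" y="%.1f" width="%.1f" height="%.1f" fill="%s" opacity="0.7"/>',
            (i - 1) * bw + off, height - h, bw / 2 - 1, h, fill)
  }, character(1)), collapse = "")
  sprintf(paste0(
    '<svg width="%d" height="%d" xmlns="http://www.w3.org/2000/svg">%s%s</svg>',
    '<p><span style="color:#36c">&#9632;</span> canonical&nbsp;&nbsp;',
    '<span style="color:#c33">&#9632;</span> novel; x: %.1f&#8211;%.1f</p>'),
    width, height + 2L,
    bar(summary$hist_canonical, "#3366cc", 0),
    bar(summary$hist_novel, "#cc3333", bw / 2),
    min(summary$hist_breaks), max(summary$hist_breaks))
}
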