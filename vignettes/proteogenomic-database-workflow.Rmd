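---
title: "Customized proteogenomic databases and class-separate FDR: methods"
author: "pgtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Customized proteogenomic databases and class-separate FDR: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgtools)
```

## The problem

Database search engines can only identify peptides whose sequences are in the
search database. Sample-specific events — nonsynonymous variants, unannotated
splicing, transcription outside annotated genes — therefore stay invisible
against a reference proteome. `pgtools` builds a sample-specific search
database from RNA-Seq evidence and then controls the error rate of the novel
identifications separately from the canonical ones, because the novel part of
the search space is small and its identifications are disproportionately
at risk of being false.

## Database construction

**Coordinates.** Everything internal is 0-based, half-open. VCF and GTF
(1-based closed) and BED (0-based half-open) are converted at the parser
boundary and nowhere else; this removes the classic off-by-one bug class at
the cost of one conversion per parser.

**Variant projection.** A VCF record is reduced to a replacement region by
stripping the shared allele prefix (the VCF anchor base). SNVs whose
replacement region lies in the spliced CDS are classified by comparing the
reference and mutated translations at the affected codon (synonymous,
missense, stop-gain, stop-loss); length-changing variants are frameshift or
in-frame INDELs by the mod-3 rule. On minus-strand transcripts the CDS offset
counts from the coding 5' end and alleles are reverse-complemented
internally, so effects are strand-symmetric (a property the tests verify on
mirrored fixtures). Emitted products are full-length variant proteins —
enzyme digestion assumptions are kept out of the database; novelty is decided
downstream at the peptide level. Choices where the field's conventions
genuinely vary:

* Variants only partially overlapping the CDS (spanning a CDS/intron
  boundary) have no defined product and are dropped with a warning.
* One variant per entry; co-occurring variants are not haplotype-phased.
* Stop-loss products are translated to the first stop within the CDS;
  readthrough into 3' UTR sequence is not modelled because the transcript
  model carries the CDS only.
* Products shorter than `min_len` (default 7 residues, about the shortest
  confidently detectable tryptic peptide) are suppressed; this mainly
  affects early stop-gains and fast-terminating frameshifts.
* Multi-sample genotypes are ignored: any ALT allele present is projected.
  The FILTER policy defaults to keeping `PASS` and `.` records.

**Junction translation.** For a two-block junction record, up to `flank_nt`
nucleotides are taken from each side (default 66, i.e. up to 22 residues —
enough to cover typical tryptic peptides spanning the junction), clipped at
the block length and then rounded down to whole codons. The codon rounding
matters: it pins the reading frames to the junction position, which makes
the emitted fragment set grow monotonically with the flank length instead of
shifting. Stranded records are translated in the three frames of their
strand, unstranded records in all six; each frame is cut at stop codons and
only fragments covering at least one nucleotide on each side of the junction
are kept. Junctions identical to annotated introns are *not* removed at
build time — novelty is a property of the identified peptide, decided by
reference mapping after the search.

**Novel transcripts.** Assembler-reconstructed transcripts (GTF, resolved
against the genome) default to three-frame translation when stranded and
six-frame otherwise; de novo contigs are always six-frame. All stop-to-stop
fragments of at least `min_len` residues are emitted, not only the longest
per frame — short unannotated coding regions would otherwise be lost.
A longest-ORF mode is available instead; an ORF requires an ATG by default
(`orf_requires_start`), may end at the sequence end if no stop follows, and
ties are broken deterministically by lower frame index then smaller start.
Each entry records whether its source transcript overlaps an annotated gene;
that flag drives the novel-gene classification later.

**Assembly and decoys.** Reference proteome and evidence entries are
concatenated; by default variant entries whose sequence is an exact
substring of a reference protein are dropped (`dedup`), because such
products are indistinguishable from reference peptides and only inflate the
novel search space — which would bias the Dₙ/D term below. Decoys are
full-sequence reversals (`REV_` prefix), one per target, appended after all
targets; reversal is an involution, so decoy counts and lengths match the
target space exactly. Palindromic targets whose reversal equals themselves
are kept but flagged in the build manifest.

**Translation details.** The standard genetic code (table 1) is hardcoded
and overridable per codon. Codons containing an ambiguous base translate to
`X` instead of aborting, so draft assemblies survive; trailing partial
codons are ignored. IUPAC ambiguity codes other than N are collapsed to N on
genome input since they carry no codon information here.

## Post-processing

PSM scores are −log2(e-value); one best PSM (lowest e-value) is kept per
spectrum before any counting — standard practice, applied consistently to
targets and decoys. A PSM is a decoy when all of its accessions carry the
decoy prefix. A target peptide is *novel* when it is not a substring of any
reference protein; I/L folding is off by default (the two residues are
isobaric but the mapping here is sequence-level) and available via
`equate_il`. Peptides carrying modifications are expected stripped.

The novel-class FDR at score threshold t is

$$\mathrm{FDR}_n(t) = \frac{D^{+}(t)\,\cdot\,D_n/D}{T_n^{+}(t)}$$

with D⁺(t) the decoy PSMs scoring ≥ t, Tₙ⁺(t) the novel target PSMs scoring
≥ t, and Dₙ/D computed over **all** identified (best-per-spectrum) decoy
PSMs, not only those above the threshold: the ratio estimates the novel
fraction of the search space, which is a property of the database, and
computing it on the full identified decoy set keeps it stable where
thresholded decoy counts are tiny. A decoy PSM belongs to the novel decoy
class (Dₙ) when any of its accessions derives from a `VAR` entry. The
estimate is defined as 0 when D = 0 or Tₙ⁺ = 0 (no identifications implies
no false identifications) and capped at 1.

**Monotonicity.** Raw target-decoy FDR estimates are not monotone in the
threshold — a novel target can drop out of the counting window before the
next decoy does, making the raw estimate rise. `fdr_step_down()` therefore
provides the step-down envelope (each threshold gets the minimum raw
estimate achievable at or below it — its q-value), which is non-increasing
by construction and is what reports should display. Threshold *selection*
does not need the envelope: `filter_at_fdr()` picks the smallest observed
score whose raw estimate meets the target, which directly guarantees that
the estimate at the chosen threshold respects the target and that raising
the target never shrinks the surviving set. Canonical and novel PSMs are
filtered at the same nominal level (default 1%) but with their own
estimators and thresholds.

**Classification.** A surviving novel peptide uniquely matching variant
entries (SAP/INDEL/JUC) is a peptide variant of an existing gene; one
uniquely matching novel-transcript entries whose transcript overlaps no
annotated gene is the product of a novel gene. Matches spanning several
classes, or novel-transcript entries inside annotated genes, are left
unclassified and logged — uniqueness is evaluated at the entry-category
level, the most conservative reading.

**Protein inference.** Canonical peptides are explained by a minimal protein
list via greedy set cover: proteins with identical peptide sets are merged
first (they are indistinguishable by the data), groups are selected by most
unexplained peptides (ties: larger total peptide set, then lexicographic
accession — fully deterministic), and a final pruning pass removes groups
made redundant by later selections, so the output is always irredundant:
removing any reported group uncovers at least one peptide. Greedy cover is
not guaranteed minimal; on small instances the tests compare it against the
exhaustive minimum and report any excess.

## What the synthetic data emulates — and what it does not

`fixture_spec()` defines the study conditions; its defaults are 20 genes of
1–4 exons on both strands (40–80 residues each), 15 nonsynonymous SNVs,
3 frameshift deletions, 5 exon-skipping junctions, 5 intergenic novel
transcripts, 3 de novo contigs, and 2,000 PSMs of which 70% are planted
true, 15% of those novel. Planted-true scores are N(30, 2) on the −log2
e-value scale and planted-false scores sit `score_separation` = 10 units
lower — a cleanly separated search of the kind a well-calibrated engine
produces on good spectra. E-values are exactly 2^(−score), so the score
convention is invertible in tests. Everything is deterministic in the seed.

The generator emulates the pipeline's *direct inputs* (post-alignment
artifacts), not their upstream reality: no spectra or fragment ions, no
modifications or missed cleavages (peptides are random protein windows, not
tryptic digests), no read-level noise, exons coincide with the CDS, and
score distributions are Gaussian by construction. Passing tests therefore
demonstrate the correctness of database construction, counting, filtering,
classification and inference — not search-engine behaviour or the
calibration of real e-values.

## Numerical and scale choices

Test and acceptance scales were chosen so the whole suite runs in well under
a minute on one core while keeping the statistics meaningful: translation
and ORF oracles run on 500 random sequences, the FDR estimator is compared
with a literal brute-force recount on 100 random PSM sets at 20 thresholds
each, monotonicity properties on 50 sets, and the end-to-end planted-truth
run uses the full 2,000-PSM default. At that size, with a score gap of 10
and spread 2, the expected survival of planted-true PSMs at a 1% FDR is
above 99.5% and the realized false proportion among survivors is near the
nominal level, comfortably inside the asserted 99%/2% bounds under binomial
sampling error.

## Known limitations

* No haplotype phasing; compound variant products are absent from the
  database.
* Splice-site-disrupting SNVs, fusion junctions and junctions with more than
  two blocks are out of scope (the latter are skipped with a warning).
* Protein-level FDR is not estimated; inference is peptide-parsimony only.
* The mzIdentML reader covers the identification subset (results, items,
  peptide sequences, evidence/protein references, e-value cvParam), not the
  full schema.
* Stop-loss readthrough products and incomplete terminal codons are
  truncated at the CDS boundary; trailing partial codons are ignored.
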