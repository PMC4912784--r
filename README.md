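# pgtools

Proteogenomic search databases and novel-peptide FDR from RNA-Seq evidence.

Shotgun proteomics identifies peptides by matching MS/MS spectra against a
reference protein database, so peptides absent from that database — products
of coding variants, unannotated splice junctions, or novel transcripts — can
never be identified, however good the spectra. `pgtools` closes that gap with
a two-stage workflow:

1. **Customized database construction.** RNA-Seq evidence is layered onto a
   reference genome and proteome: SNVs and INDELs from a VCF are projected
   onto coding transcripts and emitted as variant proteins (single amino acid
   polymorphisms, frameshift and in-frame INDEL products); splice junctions
   from a BED12 file are translated across the junction in three frames
   (six when the strand is unknown); novel transcripts from a GTF and de novo
   assembled contigs are translated in three/six frames or by longest open
   reading frame. All evidence-derived entries carry `VAR`-prefixed FASTA
   accessions to distinguish them from reference proteins, and one reversed
   decoy is appended per target.

2. **Post-processing of search results.** Peptide-spectrum matches (PSMs)
   from an external search engine are scored as −log2(e-value), novelty is
   decided by mapping each peptide against the reference proteome, and novel
   identifications are filtered with a class-separate FDR estimator:

   FDRₙ = D⁺ · (Dₙ / D) / Tₙ⁺

   where D⁺ is the number of decoy PSMs at or above the score threshold,
   Tₙ⁺ the number of novel target PSMs at or above it, and Dₙ/D the fraction
   of all identified decoy PSMs whose entries derive from the novel (VAR)
   part of the search space — an approximation of the novel share of the
   search space. Canonical PSMs are filtered with the classical global D⁺/T⁺
   estimator at the same nominal level. Surviving novel peptides are
   classified as variants of existing genes or products of novel genes, and
   canonical peptides are assembled into a minimal protein list by greedy
   parsimony (set cover). Results are exported as deterministic TSV tables
   and a self-contained HTML report.

A synthetic-data module generates internally consistent toy inputs (genome,
GTF, proteome, VCF, BED12, novel GTF, de novo FASTA, PSM table) with planted
ground truth, so the whole pipeline is testable without any downloads.

## Header conventions

| Category | Accession pattern |
|---|---|
| SAP (nonsynonymous SNV) | `VAR\|SAP\|<variant_id>\|<transcript_id>\|<cds_position>:<ref_aa>><alt_aa>` |
| INDEL product | `VAR\|INDEL\|<variant_id>\|<transcript_id>\|<cds_position>:<effect>` |
| Junction peptide | `VAR\|JUC\|<name>\|<chrom>:<left_end>-<right_start>\|frame<k>\|strand<s>` |
| Novel transcript | `VAR\|NTX\|<transcript_id>\|frame<k>\|frag<i>` |
| Decoy | `REV_<target accession>` (full-sequence reversal) |

Coordinates in accessions are 0-based half-open (the package's internal
convention); VCF/GTF 1-based and BED 0-based coordinates are converted at the
parser boundary.

## Worked example

```r
library(pgtools)

# synthetic inputs with planted ground truth (deterministic in the seed)
spec <- fixture_spec(seed = 7)          # 20 genes, 15 SNVs, 3 INDELs,
fx <- make_fixtures(spec, "demo")       # 5 junctions, 5 novel tx, 2000 PSMs
fx$db
#> <custom_db> 286 entries (DECOY=143, INDEL=2, JUC=17, NTX=89, REF=20, SAP=15)

res <- postprocess_psms(fx$psms$paths[["psms"]], fx$db, fdr = 0.01)
res
#> <pg_results>
#>   canonical peptides: 60 (threshold 23.193)
#>   novel peptides: 24 (threshold 25.005) [SAP=6, INDEL=6, JUC=6, NTX=6, none=0]
#>   protein groups: 19

head(peptide_table(res)[peptide_table(res)$class != "canonical",
                        c("sequence", "class", "gene_status")], 3)
#>      sequence class           gene_status
#> 61 LVKLNYRAGH INDEL existing_gene_variant
#> 62  ADSVQLKRL INDEL existing_gene_variant
#> 63 SMLVKLNYRA INDEL existing_gene_variant

write_tables(res, "demo/out")                    # peptides.tsv, proteins.tsv
write_html_report(run_summary(res), "demo/out")  # self-contained report.html
```

The 286-entry database holds the 20 reference proteins, 123 evidence-derived
target entries and one reversed decoy per target. At a nominal 1% FDR the
canonical and novel classes are filtered with their own estimators (note the
stricter novel threshold), and every surviving novel peptide carries the
class of the database entry it maps to.

Real inputs are passed the same way: `build_custom_db(genome_fa, gtf,
proteome_fa, vcf =, junction_bed =, novel_gtf =, denovo_fa =, out =)`
builds and writes the search FASTA, and `postprocess_psms()` accepts either
the documented five-column PSM TSV (`spectrum`, `peptide`, `proteins`,
`evalue`, `charge`) or an mzIdentML 1.1 subset (`dialect = "mzid"`).

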