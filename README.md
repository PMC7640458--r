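# sjquant

Splice-junction-based quantification of a gene's alternative splice
variants from RNA-seq alignments.

## The problem

Minor splice variants of a highly expressed gene — the motivating case is
the P4HB gene coding the protein disulfide isomerase PDIA1, with ten
annotated protein-coding variants — sit orders of magnitude below the
canonical isoform. Rather than deconvolving full transcripts, `sjquant`
quantifies each variant only by the reads that physically span a splice
junction *unique* to it within the gene's transcript set. For variant
*v* with discriminating junction set *D(v)* in a library of *N* filtered
reads,

    SJ TPM(v) = (reads spanning a junction in D(v)) / N * 1e6

(Splice Junction Tags Per Million), and the gene-relative fraction divides
by the filtered reads overlapping the gene span instead. Junctions are
extracted from the skipped-region (`N`) CIGAR operations of SAM/BAM
records under stringent filters: exact coordinate match and at least 8
aligned bases anchoring the junction on each side (mirroring the 8-base
junction-overlap rule for isoform-specific qPCR primers), primary
non-duplicate records only.

The package covers the full chain:

* **gene models** — GTF/GFF3 parsing for one gene, per-transcript junction
  derivation, discriminating-junction catalogues (variants with no unique
  junction are reported as unquantifiable, not dropped);
* **junction counting** — SAM/BAM (or in-memory record) counting with
  anchor/MAPQ/flag filters and the denominators needed for normalization;
* **quantification** — SJ TPM and gene-relative fractions in a
  `SummarizedExperiment` subclass, replicate averaging, per-group
  mean ± SD, presence summaries;
* **isoform features** — projection of the canonical protein's domain map
  through each variant via exact-block alignment, CGHC motif counting,
  KDEL / start / stop flags;
* **primer tools** — the 8+8 junction-overlap rule and exact-match
  in-silico PCR with amplicon sizes;
* **simulator** — seeded spliced-read generator with per-junction ground
  truth, backing every stage with parameter-recovery tests;
* **workflow** — `runPipeline()` from annotation + sample sheet to
  reproducible TSV reports (a thin CLI lives in `inst/scripts/sjquant.R`).

## Worked example

Simulate one library over a toy 4-exon gene with an exon-3-skipping
variant whose junction is carried by 0.7% of reads, then count and
quantify:

```r
library(sjquant)

cfg <- simulationConfig(nReads = 1e5, seed = 11,
                        junctionProb = c(skip3 = 0.007),
                        anchorRange = c(8, 92))
s  <- simulateSample(cfg)
tb <- countJunctions(s$records, s$catalogue, s$gene, filterConfig(),
                     "sample1")
tb
#> JunctionCountTable: sample1
#>   4 junctions; totalReads 100000; geneReads 100000
#>   filters: minAnchor 8, minMapq 0
junctionCounts(tb)
#>   chrom donor_end acceptor_start count
#> 1  chrT       283           1055     0
#> 2  chrT      1347           1921     0
#> 3  chrT      2182           2595     0
#> 4  chrT      1347           2595   688
```

The three canonical junctions (rows 1–3) are unspliced-background only;
the skip junction joining exon 2's end (1347) to exon 4's start (2595)
collected 688 reads against a simulated truth of 688 realized
(700 intended, binomial sampling). Normalizing:

```r
skip <- variantJunctions(s$catalogue, "skip3")
k <- junctionCounts(tb)$count[junctionCounts(tb)$donor_end == skip$donor_end &
                              junctionCounts(tb)$acceptor_start == skip$acceptor_start]
sjTPM(k, totalReads(tb))                      # 6880  SJ TPM
100 * variantFraction(k, geneReads(tb))       # 0.688 % of gene reads
```

6880 SJ TPM against an expected 0.007 × 1e6 = 7000, and 0.688% of the
gene's reads against the simulated 0.7% — both within binomial error at
this depth.

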