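---
title: "Quantifying splice variants from junction-spanning reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying splice variants from junction-spanning reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sjquant)
```

## The problem

Most genes express several splice variants, and for a highly expressed gene
the minor variants can sit two to three orders of magnitude below the
canonical isoform. Full-transcript quantifiers (EM-based isoform
deconvolution) spread ambiguous reads across isoforms and struggle in that
regime. `sjquant` takes the opposite, deliberately conservative route used
in gene-focused splice-variant studies such as the analysis of the P4HB /
PDIA1 splice-variant landscape: quantify each variant *only* by the reads
that span a splice junction unique to it. A junction-spanning read is
unambiguous evidence — the read physically bridges two exons that are
joined in exactly one transcript of the gene.

The price is that variants with no unique junction are invisible. `sjquant`
reports them (`unquantifiableVariants()`) instead of dropping them
silently, because knowing which variants the method cannot see is part of
the result.

## The model

For a gene with transcript set $T$, the junctions of transcript $t$ are the
pairs $(d, a)$ where $d$ is the last base of a genomically-left exon and
$a$ the first base of the adjacent genomically-right exon (1-based,
inclusive, as in GTF). The *discriminating* set of $t$ is

$$D(t) = J(t) \setminus \bigcup_{t' \neq t} J(t'),$$

computed over the supplied transcript set only. Uniqueness is scoped to the
transcripts the user provides: genome-wide uniqueness is not assessed, so
the choice of $T$ (for example, protein-coding transcripts only versus all
annotated transcripts including retained introns) is an analysis decision
that changes which junctions discriminate. Junction identity is
strand-agnostic — counting operates in genomic coordinates — while exon
numbering in reports follows transcript orientation (for a minus-strand
gene, exon 1 is the genomically rightmost).

Expression of variant $v$ in a library of $N$ reads is the Splice Junction
Tag Per Million:

$$\mathrm{SJ\,TPM}(v) = \frac{k_v}{N} \times 10^6,$$

where $k_v$ is the number of filtered reads spanning a junction in $D(v)$.
If a variant has several discriminating junctions, their counts are summed
before normalizing, so each variant gets one number; the per-junction
breakdown is retained in the outputs. The gene-relative fraction divides
$k_v$ instead by the filtered reads overlapping the gene's genomic span.
Because discriminating-junction counts are not a partition of the gene's
reads, fractions are comparable across variants but are not forced to sum
to 1; the report headers say so.

### Assumptions

* Alignments are spliced (CIGAR `N` operations encode introns) and
  coordinates match the annotation's assembly exactly; junction matching is
  exact, with no positional tolerance.
* A read is the unit of evidence. Paired-end mates are counted as
  independent records — libraries mixing single- and paired-end data are
  then treated uniformly, at the cost of up to two counts per fragment.
* Library depth $N$ is the number of records passing the record-level
  filters (mapped, primary, non-duplicate, MAPQ), not the raw record count,
  so secondary-alignment inflation does not depress SJ TPM. This is
  configurable.

## Filters

The junction-level filter is the anchor rule: a read supports a junction
only if it has at least `minAnchor` reference-consuming bases on *each*
side of it, bounded by the adjacent skip or the read end. Soft clips and
insertions never count. The default is 8 nt, deliberately mirroring the
junction-overlap rule used when designing isoform-specific qPCR primers
(at least 8 bases on each arm of the junction): the same logic — too short
an overlap cannot distinguish the spliced from the unspliced template —
applies to a read anchor. "At least" is inclusive: an 8/8 read passes at
`minAnchor = 8`.

Record-level defaults are primary, non-duplicate, non-supplementary
records at any MAPQ (`minMapq = 0`). All filters are carried inside the
`FilterConfig` object and embedded in every count table, so a report is
self-describing. Raising `minAnchor` or `minMapq` can only remove reads;
the test suite asserts this monotonicity.

Reads that span a catalogue junction *and* additional unannotated
junctions still count: the method matches specific junctions, not whole
read structures.

## The simulator

The generator emulates the data regime the method is built for: deep
short-read RNA-seq over one gene.

* **Structure** — a canonical transcript of `nExons` exons (default 4,
  lengths 150–300 nt, introns 200–800 nt) plus exon-skipping variants;
  the default variant skips exon 3, joining exon 2 to exon 4, the classic
  skip topology.
* **Reads** — 100 nt single-end by default (the common deep-library read
  length; 75–200 nt accepted), at $10^5$ reads per sample. Real studies of
  this kind run at $\sim 2 \times 10^8$ reads per library; the simulator
  emulates that depth *in ratio, not volume* — per-junction read
  probabilities are kept at realistic values while the read count is scaled
  to desk size.
* **Signal** — each read spans a configured junction with probability
  $p_j$ (default 0.007: a minor variant carried by ~0.7% of the gene-level
  signal, the order of magnitude reported for minor splice variants of a
  highly expressed gene) or is emitted unspliced. The realized per-junction
  count is therefore exactly Binomial$(n, p_j)$, which is what makes the
  parameter-recovery bound ($\pm 3\sqrt{p(1-p)/n} \times 10^6$ SJ TPM)
  a theorem about the generator rather than a tuned tolerance.
* **Anchors** — the left anchor of a junction read is uniform over the
  feasible range by default. Recovery analyses set
  `anchorRange = c(8, 92)` so that every simulated junction read is
  detectable under the default anchor filter and the binomial identity is
  preserved end to end; the complementary setting `anchorRange = c(1, 7)`
  is used to verify that the filter drives counts to exactly zero.
* **Strand** — minus-strand genes are exercised with reverse-complemented
  sequences (FLAG 16) at identical coordinates, matching how aligners
  report them.
* **Determinism** — every draw derives from the config seed; identical
  configs give byte-identical GTF, FASTA, SAM and truth tables. Reads are
  emitted as already-aligned records rather than FASTQ: the pipeline
  consumes alignments, and skipping the aligner keeps ground truth exact
  and runs download-free.

What the simulator does **not** model: sequencing errors, mapping
ambiguity or misalignment near junctions, fragment-length structure for
paired ends, expression of full transcripts (reads come from the
configured junctions and the canonical exons only), and biases such as GC
or positional coverage. Passing the recovery tests therefore demonstrates
that the counting and normalization chain is correct and unbiased given
correct alignments; it does not certify robustness to alignment artifacts
in real data, which is exactly what the stringent anchor filter exists to
mitigate.

### Problem sizes used by the checks

The bundled checks run 20 simulated libraries of $10^5$ reads for the
counting-versus-text-recount comparison, and 100 replicates of a
four-variant gene at $p \in \{10^{-2}, 7\times10^{-3}, 3\times10^{-3},
10^{-3}\}$ for parameter recovery — sizes chosen so the whole suite runs
on a laptop in minutes while the binomial bounds remain tight enough to
detect an off-by-one in the counting logic.

## Downstream statistics

* **Replicate averaging** collapses samples of one donor to their
  arithmetic mean, per variant (the convention used when triplicate
  libraries from one donor are reported as one sample).
* **Group summaries** report the mean and the *sample* standard deviation
  ($n-1$ denominator; 0 for singleton groups) of SJ TPM per group.
* **Presence** means at least one filtered junction-spanning read by
  default; the threshold is a parameter, and presence counts are
  non-increasing in it.
* **Fraction of total isoform expression** (the share of summed variant
  SJ TPM attributable to each variant) is offered in two readings —
  pooled over samples, and per-sample-then-averaged — because a
  whole-cohort isoform pie can reasonably mean either; both sum to 100%.

## Domain projection

Splice variants differ from their canonical protein by whole exonic
blocks, so variant-to-canonical residue mapping uses exact shared blocks
(at least 5 aa) chained colinearly to maximize total matched length — no
substitution scoring, which would only add free parameters for sequences
that are locally identical. When the sequence repeats around an excision
point the placement is ambiguous; ties are broken toward the leftmost
placement, implemented by trimming the overlap off the later block.
Canonical positions absent from the chained map are the variant's
deletions; each canonical domain is then classified intact / truncated /
absent, a CGHC redox motif counts as retained only when all four residues
are, and KDEL is flagged only when terminal. Domain coordinates are
user-supplied input: the canonical architectures in the literature are
published as figures, and inventing coordinates in code would fabricate
precision the source does not offer.

## In-silico PCR

Primer annealing is exact-match only, case-insensitive, plain ACGT
(ambiguity codes are rejected rather than half-supported); there is no
melting-temperature model. The amplicon is inclusive of both primer sites,
matching how product sizes are read off a gel. The junction-overlap rule
for isoform-specific primers (≥ 8 bases on both arms, inclusive) is
symmetric in the two arms and available as a standalone validator.

The bundled primer table carries published junction-spanning primer pairs
for three P4HB splice variants with expected products of 89, 148 and
211 bp. The real spliced transcript sequences are not redistributable with
the package, so `syntheticAmpliconTemplates()` builds *synthetic* stand-in
templates embedding each pair at exactly its expected geometry, with a
uniqueness check on the primer sites. Running the PCR engine against them
validates the matching and length arithmetic — not the real transcript
sequences; the `_synthetic` suffix in the template names is there so
nobody mistakes one for the other.

## Degenerate inputs and numerical choices

* `total_reads = 0` is an explicit "empty library" error, never a silent
  0/0; `gene_reads = 0` likewise errors as "gene not expressed".
* Empty alignment streams produce all-zero tables (a valid observation);
  unreadable files are errors.
* Single-exon transcripts have no junctions; two identical transcripts are
  both unquantifiable — both are legal inputs with well-defined outputs.
* SJ TPM is exactly invariant under a common integer scaling of all
  counts (pure ratio arithmetic; no pseudocounts anywhere).
* Per-sample failures abort a pipeline run by default (`keep_going`
  opt-in), because silently dropping a sample would bias group summaries;
  dropped samples are flagged `INCOMPLETE` in the run log.

## Known limitations

* Variants without a unique junction cannot be quantified — by design;
  they are listed, not estimated.
* Intron-retention variants are only detectable through the junctions they
  *lack*, which this method does not exploit.
* Fractions are junction-based and not a partition of gene expression;
  comparing them across genes requires care.
* Exact junction matching means a one-base annotation/assembly mismatch
  gives zero counts rather than approximate ones — loud failure was chosen
  over silent miscounting.
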