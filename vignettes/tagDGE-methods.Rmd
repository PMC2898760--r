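---
title: "Tag-based digital gene expression analysis with tagDGE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-based digital gene expression analysis with tagDGE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagDGE)
```

## The measurement model

Tag-based digital gene expression (DGE) is a SAGE-derived protocol:
cDNA is digested with NlaIII, which recognises CATG, and MmeI then
releases a fragment 17 bp downstream of that site. Each sequenced read
is therefore a 21 nt *tag* — the CATG anchor plus 17 variable bases —
originating, under complete digestion, from the 3'-most CATG site of a
transcript. Expression is measured by absolute tag counts rather than
hybridisation intensities, so a library is fully described by its
distinct tag sequences and their copy numbers.

tagDGE implements the complete analysis around this measurement:

1. **Virtual tag reference** (`buildTagReference`): every CATG site of
   every transcript with at least 17 nt downstream yields one virtual
   CATG+17 tag; the 3'-most usable site is flagged *canonical*. An
   inverted index maps each distinct tag sequence to the set of genes
   carrying it. Tags shared by several genes are *ambiguous* and are
   never used for quantification.
2. **Library filtering** (`filterTags`): a fixed cascade removes
   adaptor-only/structurally invalid reads, tags containing `N`,
   low-complexity tags, and — after aggregation over the whole
   library — distinct tags with copy number 1, which are
   overwhelmingly sequencing errors at DGE depths. The cascade order is
   part of the contract so audit counts are reproducible, and the audit
   conserves occurrences exactly: kept + removed = raw total.
3. **Mapping** (`countUnambiguous`): distinct tags map against the
   index with at most one substitution. Exact hits shadow one-mismatch
   hits; at the minimal mismatch level the gene set is the union of
   genes hit, and only single-gene tags contribute counts. A tag
   hitting two sites of the *same* gene stays unambiguous at gene
   level; its 3'-most site is used for the canonical-fraction
   statistic.
4. **Quantification** (`expressionTable`): per-gene counts are
   normalised to transcripts per million tags, TPM =
   count / clean library total × 10^6, stored in a
   `SummarizedExperiment` with assays `counts` and `tpm`.
5. **Differential expression** (`callDE`): for each gene with counts
   x, y in two libraries of clean totals N1, N2, the Audic–Claverie
   conditional model gives

   P(y | x) = (N2/N1)^y (x+y)! / ( x! y! (1 + N2/N1)^(x+y+1) ),

   i.e. y | x ~ NegBinomial(size = x+1, prob = N1/(N1+N2)). The
   two-sided p-value doubles the smaller tail sum (each tail including
   the observed point) and caps at 1. Benjamini–Hochberg q-values
   control the FDR across genes; a gene is called up-regulated when
   FDR < 0.001 and log2(TPM2/TPM1) ≥ 1, down-regulated symmetrically,
   with 0.001 TPM substituted for zeros before forming the ratio.

## Design choices where the field's conventions are open

**Sidedness of the exact test.** We default to the doubling-of-the-
smaller-tail two-sided p-value, the standard convention for exact count
tests; one-sided tails are available via `alternative=`. Because the
observed point is counted in both tails, swapping the two libraries can
change the p-value by up to `2·max(1, N2/N1)` times the observed-point
probability — a discreteness effect that vanishes for the moderate-to-
large counts where calls are made. The tail sums themselves obey the
exact symmetry `P(X' ≤ x | y, N1/N2) = 1 − P(Y' ≤ y | x, N2/N1)`.

**FDR procedure.** Benjamini–Hochberg step-up q-values, the standard
choice for DGE-era count testing; `bhFdr` fronts `stats::p.adjust`.

**Mismatch policy.** The one-mismatch budget applies to the 17 variable
positions only and the CATG anchor must match exactly (default): an
anchor mismatch cannot arise from NlaIII chemistry, only from a
sequencing error that simultaneously destroys the read's structural
validity, and the restriction keeps the substitution neighbourhood at
3 × 17 = 51 variants. `anchorExact = FALSE` widens the budget to all
21 positions.

**Low-complexity rule.** The filtering literature names the category
without defining it; we reject a tag when any single base occupies
≥ 15 of the 17 variable positions or the variable region is a pure
period-2 repeat (which subsumes homopolymers). The threshold is a
parameter (`maxMono`).

**Zeros in ratios.** Genes absent from one library receive the 0.001
TPM pseudo-value only when the log2 ratio is formed, never in the
stored TPM; such genes are flagged `one_sample_only`. Genes with zero
counts in both libraries are excluded from testing.

**Counting denominators.** TPM and the exact test use the *clean*
library totals, not the mapped totals: the clean total is the
sequencing effort actually spent, and using it keeps TPM comparable
across libraries with different mapping rates.

**Tag-level mode.** `callDETags` tests each unambiguous distinct tag
entity and calls a gene DE when at least one of its tags is significant
and all significant tags agree in direction; conflicting genes are
reported separately rather than counted. Gene-level aggregation
(`callDE`) is the default because summing a gene's unambiguous tags
uses the full evidence in one test.

## The synthetic-data generator

Every stage is testable without external data through a ground-truthed
generator (`simulationConfig`, `simulateTranscriptome`,
`simulateTagLibrary`, `simulateExperiment`) that emulates:

- **Transcriptome**: i.i.d. uniform-base DNA with log-normal lengths
  (meanlog 5.5, sdlog 0.7, clamped to 60–5000 nt), matching the short
  de novo assembled distinct sequences (a few hundred bp) such
  references typically contain. With `guaranteeCatg` every transcript
  gets a planted canonical CATG exactly 21 nt from its 3' end *and*
  one uniformly placed upstream usable site. The second planting makes
  the digestion-completeness parameter identifiable: a transcript
  whose only site is canonical would emit canonical tags regardless of
  digestion, biasing the realised canonical fraction above the
  configured probability.
- **Expression**: per-gene log-normal abundance with sdlog 1.5
  (roughly four orders of magnitude of dynamic range over ±3 sd, the
  skew typical of bulk transcriptomes); a planted fraction (default
  10%) of genes receives a ±2 log2-fold change in condition 2.
- **Tag sampling**: each read picks a gene ∝ abundance, then the
  canonical site with probability `digestion` (default 0.6, the
  classical-site fraction reported for insect, mouse and zebrafish DGE
  libraries) or a uniformly chosen upstream usable site otherwise.
- **Noise**: each of the 21 bases substitutes independently with
  probability `errorRate` (default 0.01, early-Illumina scale),
  uniformly over the three alternatives; contaminant reads are
  injected at configured fractions (default 5% N-containing, 2%
  adaptor-only). Per-read provenance (gene, site, canonical origin,
  error count, anchor integrity, contaminant class) is recorded so
  filter audits and mapping statistics can be reconciled against
  ground truth exactly.
- **Depth**: default 2 × 10^6 tags per library, the depth at which
  detected-gene counts saturate in this protocol.

What the generator deliberately does *not* model: alternative
polyadenylation and splicing (real upstream-tag fractions mix
incomplete digestion with isoform structure), quality-score profiles
beyond `N` injection, between-replicate technical correlation, and any
dispersion beyond multinomial counting noise. Passing tests therefore
demonstrate the correctness of the algorithms under the stated
sampling model, not robustness to biological overdispersion — with one
library per condition the Audic–Claverie test, like any single-library
exact test, treats biological variability as signal.

## Numerical choices

The exact-test tails are accumulated term-by-term in the log domain
with 80-bit extended precision, using the pmf recurrences from the
observed point outward, rescaling the accumulator before it can
overflow, and truncating once the running term has passed the
distribution mode and fallen below 10^-18 of the accumulated mass.
Against an independent closed-form oracle (the negative-binomial tail
identity, evaluated with `pnbinom`) the implementation agrees to
better than 10^-12 relative error for counts up to 200 and library
ratios 0.5–2; the test suite enforces 10^-10. Cost is O(√count) per
tail, so genome-scale tables with counts in the tens of thousands
remain fast.

Saturation subsampling permutes the occurrence multiset once and reads
nested prefixes (not independent re-draws), which guarantees monotone
curves and bit-reproducibility under a fixed seed. Between-library
correlation is computed over the union of tag entities on the
log10(count+1) scale by default (raw scale via `logScale = FALSE`);
absent entities count as zero.

Degenerate inputs are contracts, not surprises: an empty transcript
yields no tags; transcripts shorter than 21 nt are censused as
untaggable; an empty clean library maps to an all-zero table; a
zero-variance library is a correlation error; `libraryTotal = 0` is a
TPM error; overlapping abundance bins are rejected.

## Problem sizes used in the validation suite

The shipped tests exercise the pipeline at desk scale, chosen as the
smallest sizes at which each property is statistically crisp: the
exact-test grid runs 3 × 201 × 201 evaluations; type-I control uses
2,000 null genes in two one-million-tag libraries; power uses the
generator defaults (2,000 genes, 10% DE at |log2FC| = 2, two
two-million-tag libraries), where ≥ 90% of planted genes are recovered
with correct direction and the false-call rate among nulls stays below
the 0.001 FDR target; digestion-parameter recovery uses 5 × 10^5 tags,
where the binomial standard error of the canonical fraction is well
under the ±0.01 assertion; saturation uses a 10×-overdeep 5 × 10^5-tag
library over 500 genes. `scripts/acceptance.R` re-runs the same
computations from scratch for any seed.

## A worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(nGenes = 300, librarySize = 1e5, seed = 7)
sim <- simulateExperiment(cfg)
ref <- buildTagReference(sim$transcriptome)
libs <- lapply(sim$libs, filterTags, adaptor = cfg$adaptor)
se <- expressionTable(libs, ref)
de <- callDE(se, "cond1", "cond2")
S4Vectors::metadata(de)$summary
```

Or end-to-end with artifact output:

```{r pipeline, eval = FALSE}
pcfg <- pipelineConfig(reference = sim$transcriptome, libraries = sim$libs,
                       outdir = "dge-report", adaptor = cfg$adaptor,
                       saturationStep = 10000, seed = 7)
res <- runPipeline(pcfg)
res$libraryStats
```

## Known limitations

- One library per condition: no replicate-based dispersion estimation;
  for replicated designs a negative-binomial framework (DESeq2, edgeR)
  is the right tool, and this package intentionally does not duplicate
  it.
- Ambiguous tags are dropped, not probabilistically rescued; genes
  whose every tag is shared with another gene are invisible.
- Sense-strand tags only by default; `bothStrands = TRUE` indexes
  reverse-complement tags for de novo contigs of unknown orientation
  at the cost of extra ambiguity.
- The canonical-fraction statistic is computed over unambiguously
  mapped occurrences; heavily ambiguous references bias it toward
  whatever survives the ambiguity filter.
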