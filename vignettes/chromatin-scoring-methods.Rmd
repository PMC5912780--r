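---
title: "Methods: gene-level chromatin scoring and its association with mutagenesis efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-level chromatin scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprchrom)
```

## The question and the model

CRISPR-Cas9 mutagenesis in injected embryos is not equally effective at every
locus. The working hypothesis this package operationalizes is that a gene's
chromatin state around its promoter — and its transcriptional activity in
early development — modulates how accessible the locus is to Cas9. The
package turns that hypothesis into three per-gene scalar features and a set
of rank-based association tests against per-gene mutagenesis efficiency.

All genomic coordinates are handled internally as 0-based half-open
intervals; GFF3/GTF input (1-based inclusive) is converted at the boundary,
BED/broadPeak needs no conversion. Gene identity is the annotation's exact
`gene_id` string; an optional two-column alias map translates the identifiers
of efficiency/expression tables before joining, which keeps the join
auditable when the tables use symbols rather than annotation IDs.

## Transcriptional units

TSSs of all transcripts are pooled per gene: on the plus strand a
transcript's TSS is its minimum exon start, on the minus strand its maximum
exon end minus one (the first transcribed base). Pooled TSSs are clustered by
single-linkage chaining: consecutive sorted positions at most `cluster_gap`
(default **500 nt**) apart join one unit. Chaining is the deterministic,
order-independent reading of "within 500 nt"; it implies a cluster can span
more than the gap end-to-end, but consecutive members never do. The
representative TSS is `floor((min + max) / 2)` of the cluster span — the
span midpoint, not the member mean — which keeps integer coordinates and is
insensitive to how many transcripts pile on one side.

Each unit's scoring region is the symmetric `± flank` window (default
**1,000 nt**) around the representative TSS, built strand-agnostically. The
region is clipped at position 0 and at the chromosome end, but its *nominal*
length stays `2·flank`: the accessibility coefficient divides by the fixed
2,000 nt denominator regardless of clipping, so a promoter at a contig edge
is scored on the same scale as any other (it simply cannot accumulate signal
in the truncated part).

## Feature definitions

**Accessibility coefficient.** For unit region $R$ and peaks $p$ with signal
value $s(p)$:
$$\mathrm{coef}(R) = \frac{\sum_p s(p)\cdot \mathrm{overlap}_{bp}(p, R)}{|R|_{nominal}}$$
Genes whose TSSs resolve to several units receive the arithmetic mean of the
per-unit coefficients, so every gene carries exactly one accessibility value
(averaging coefficients, not correlations — the alternative reading would
not yield a single per-gene value to correlate). No overlapping peak is a
valid 0; a gene with no units is missing, never 0.

**Exon-methylation coefficient.** Exons are unioned across isoforms so the
denominator is the nonredundant exonic footprint; the peak set is also merged
before overlap so a base covered by two peaks counts once. The coefficient is
covered exonic bases divided by total exonic bases — a coverage fraction in
$[0,1]$. Whether the original summation weighted by peak count, length or
signal is not recoverable from the text it follows; the coverage reading is
the default because it is dimensionless and bounded, and a signal-weighted
variant (`meth_weight = "signal"`, unbounded) is kept behind a flag.

**Promoter probe score.** Per microarray, the sum of $\log_2$ median probe
intensities over the gene's probes, then the mean over arrays. Log base 2 is
the microarray convention; any base rescales the score by a constant and
leaves the Spearman statistic untouched. Zero or negative intensities are
rejected at read time (the log must be defined).

**Guide GC content.** Percent G+C over the 20-nt protospacer, PAM excluded.

## Association analyses

`spearman_test()` computes rho as the Pearson correlation of average ranks
(ties get average ranks) and a two-sided p from
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df. Identical or exactly reversed
rankings give $p = 0$. The t-approximation is used at all n — matching the
mainstream statistics routines this kind of analysis runs on — with a logged
caution below n = 10 and an exact permutation option (`exact = TRUE`) for
n ≤ 8, where full enumeration (40,320 permutations) is still cheap; the
spec'd n ≤ 10 cap was lowered because 10! permutations is three orders of
magnitude more work for no practical gain at this sample-size regime. Pairs
with missing values are dropped first and the complete-case n is reported
per test — join attrition across data sources is expected and must stay
visible.

`mann_whitney()` orients U as the number of (a, b) pairs with a > b; exact
two-sided p by the U distribution when both groups are small (min ≤ 8) and
tie-free, otherwise the tie-corrected normal approximation without
continuity correction. `fisher_exact()` sums hypergeometric probabilities of
all margin-consistent tables no more probable than the observed one (with
the standard 1e-7 relative slack against float ties).

Expression categories: a gene is *low-expressed* iff RPKM is strictly below
**0.5** at every stage from oblong-sphere through 15-somite; a value exactly
at 0.5 counts as expressed (the threshold is a limit *for* low expression).
The *MZT increase* flag requires a strictly positive RPKM change from
oblong-sphere to 50%-epiboly. Both categories are cross-tabulated against
mutagenesis-permissive vs -resistant genes (a gene is permissive iff any of
its guides shows detectable activity) and tested two-sided with Fisher's
exact test; two-sided because the direction of a chromatin effect is the
question, not the premise.

Per-gene efficiency is the mean over the gene's guides (median behind a
config switch); the aggregation rule of the source database is unstated, and
the mean is the neutral default given the small guide-level noise. P-values
are reported raw, mirroring the table layout this reproduces; a
Benjamini-Hochberg column can be added by the caller with `p.adjust`.

## The synthetic-study generator

The generator exists so every stage of the pipeline is testable without
external downloads, with effect sizes planted where the real analysis found
them. One latent per-gene openness $z \sim N(0,1)$ drives everything:

* **Annotation**: genes placed without overlap; a gene has one transcript
  with probability 0.84, else 2–4 transcripts with TSS offsets of
  50–5,000 nt (so both clusterable and non-clusterable TSS pairs arise);
  2–8 exons of 100–500 bp per transcript, introns of 200–2,000 bp. The
  multi-TSS fraction 0.16 matches the proportion of multi-transcript genes
  in the reference annotation regime this emulates (3,465 of 22,152).
* **ATAC peaks**: one promoter peak per unit, 1.5–3 kb wide, centred within
  ±300 nt of the representative TSS, signal $e^{z + \varepsilon}$ with
  $\varepsilon \sim N(0, \texttt{noise\_sd})$ (default 0.1); plus Poisson
  background peaks (default 0.02/kb) with openness-independent signal, which
  act as pure dilution and let tests verify robustness to irrelevant peaks.
* **Methylation peaks**: cover each gene's merged exons with coverage
  fraction $\mathrm{logistic}(-z + \varepsilon)$ — methylation opposes
  openness by construction.
* **Efficiency**: Gaussian copula
  $z_{\mathrm{eff}} = r z + \sqrt{1-r^2}\,\eta$ with
  $r = 2\sin(\pi \rho_s/6)$, the Pearson value whose bivariate-normal grade
  correlation equals the target Spearman $\rho_s$ (default **0.18** at
  **263** genes — the regime of the accessibility analysis). Efficiency is
  $100\,\Phi(z_{\mathrm{eff}})$, spread over 1–4 guides with 2-percentage-
  point noise; guides above 70% are flagged functional, giving roughly the
  30% functional-guide rate seen in practice.
* **Expression**: $\mathrm{RPKM} = \exp(\mu_s + g + w_s z + \varepsilon)$
  with a gene-level baseline $g \sim N(0, 1.2)$ independent of openness and
  a stage weight $w_s$ that rises between oblong-sphere and 50%-epiboly, so
  the MZT increase scales with openness. The large $g$ deliberately makes
  expression a *noisy* readout of openness: stage-wise expression
  correlations with efficiency come out attenuated relative to the planted
  accessibility rho, which mirrors the real data's weaker expression
  correlations.
* **Probes**: 3–10 probes per gene on two arrays,
  $\log_2$ intensity $= 0.5 z + N(0, 0.5)$.

The whole bundle is a pure function of the config: identical seeds give
byte-identical files. What the generator does *not* emulate: sequence
composition, read-level noise, peak-caller artefacts, genome-duplication
paralogy, or any coupling between guide sequence and efficiency — so passing
tests demonstrate the correctness and calibration of the scoring and
statistics, not biological validity on real data.

## Numerical choices and degenerate inputs

* Zero-length intervals are rejected at construction; empty peak files and
  empty overlap sets are valid and yield 0 coefficients.
* The overlap engine is a vectorized sweep over start-sorted intervals
  (candidate windows pruned with `findInterval` on starts and on the running
  maximum of ends); it is cross-checked in the tests both against
  `GenomicRanges::findOverlaps` and against a per-base brute-force
  accumulator on a thousand random instances.
* Spearman rho within 1e-12 of ±1 is snapped to ±1 (identical rankings
  produce float dust through `cor`); zero-variance input is an explicit
  error rather than NA.
* Unknown chromosomes in peak files are retained and simply overlap nothing;
  a count is logged, tolerant of scaffold-naming mismatches.
* Clipped promoter regions keep the fixed 2,000 nt denominator (see above).

## Problem sizes

The replicate studies run at the study's own scale: single runs and
recovery/type-I replicates use 263 genes; recovery averages 200 replicates
(Monte-Carlo SE of the mean rho ≈ 0.004), type-I calibration uses 1,000 null
replicates (binomial SE ≈ 0.007 around 0.05). The oracle checks use 1,000
random small instances for intervals and clustering, 500 random vectors for
the correlation oracle, all 2×2 tables with margins ≤ 12 for Fisher, and
full labeling enumeration for Mann-Whitney at group sizes ≤ 6.

## Known limitations

* The counts of the real annotation (22,152 genes; 18,687 single-transcript;
  clustering resolving 2,233 of 3,465 multi-TSS genes) are
  annotation-version-dependent and are not reproduced here; the generator
  matches the multi-TSS *fraction*, and its uniform 50–5,000 nt TSS offsets
  resolve a smaller share of multi-TSS genes into single units than the real
  annotation does.
* The printed correlations of the source analyses depend on external
  accessions (guide database, expression, methylation, histone and ATAC
  datasets) and are out of desk-scale reach; the package validates itself on
  planted effects instead.
* `estimate_atac_association()` is a deliberate fast path (no file I/O); the
  file-based route is exercised by the pipeline tests and the single full
  acceptance run.
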