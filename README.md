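# crisprchrom

Gene-level chromatin and expression covariates of CRISPR-Cas9 mutagenesis
efficiency in early zebrafish-style embryos.

CRISPR-Cas9 mutagenesis in injected embryos does not succeed equally at every
locus: guides with good in-vitro activity can fail in vivo, and one proposed
reason is that the developing embryo's chromatin limits Cas9's access to its
target. This package implements the gene-level scoring and rank-association
analyses used to ask that question quantitatively. It is written for
computational biologists who have per-gene guide efficiencies (a CRISPRz-style
table) and standard epigenomic inputs — ATAC-seq and ChIP-seq peak calls
(broadPeak), a stage-wise RNA-seq RPKM table, a promoter microarray probe
table — and want per-gene chromatin features plus calibrated rank statistics
relating them to mutagenesis efficiency.

## What it computes

**Transcriptional units.** TSSs of all annotated transcripts are pooled per
gene; TSSs within 500 nt are chained into a single transcriptional unit, and
the midpoint of the cluster span is its representative TSS. Each unit carries
a symmetric ±1,000 nt scoring region.

**Accessibility (ATAC) coefficient.** For a unit with region *R* (nominal
length |R| = 2,000 nt) and peaks *p* with signal value *s(p)*,

```
coef(R) = Σ_p s(p) · overlap(p, R) / |R|
```

A gene whose TSSs resolve to several units gets the mean of its unit
coefficients, so every gene carries a single accessibility value.

**Exon-methylation coefficient.** Exons are unioned across isoforms; the
coefficient is the fraction of merged-exonic bases covered by the (merged)
methylation peak footprint — a number in [0, 1]. A signal-weighted variant is
available behind `meth_weight = "signal"`.

**Promoter probe score.** Per array, the sum of log2 median probe intensities
over a gene's probes; the score is the mean of the per-array sums.

**Associations.** Spearman rank correlation (rho via Pearson on average
ranks, two-sided p from the t-approximation on n − 2 df) of each feature and
each developmental stage's RPKM against per-gene efficiency (mean over
guides); Fisher's exact tests on low-expression (< 0.5 RPKM across
oblong-sphere…15-somite) and MZT-increase (oblong-sphere → 50 %-epiboly)
categories split by mutagenesis-permissive vs -resistant genes; Mann-Whitney
U comparison of guide GC content between functional and non-functional
guides.

**Synthetic studies.** `simulate_study()` generates a complete input bundle —
annotation, peak files, expression, probes, efficiencies — from one seed. A
latent per-gene "openness" drives promoter ATAC signal, methylation coverage
(negatively), probe intensity and the expression trajectory; efficiency is
tied to openness through a Gaussian copula whose Pearson parameter
`r = 2·sin(π·ρ/6)` plants an exact target Spearman rho (default 0.18 at
n = 263 genes, the regime of the accessibility analysis this emulates).

## Worked example

The `analysis/` scripts run the whole study in order:

```sh
Rscript analysis/01_simulate.R           # writes results/sim/
Rscript analysis/02_score_and_correlate.R  # writes results/run/
Rscript analysis/03_replicate_calibration.R
```

Step 2 prints, for the default seed:

```
Association with mutagenesis efficiency (Spearman):
                 feature          stage statistic   n p_value significant
              expression        64-cell     0.049 263 0.42400       FALSE
              expression  oblong-sphere     0.068 263 0.27500       FALSE
              ...
        atac_coefficient           4hpf     0.200 263 0.00114        TRUE
 methylation_coefficient         1-cell    -0.192 263 0.00173        TRUE
          promoter_score 75-80%-epiboly     0.153 263 0.01310        TRUE
```

Read: on this synthetic study the accessibility coefficient recovers the
planted positive association with efficiency (rho 0.200 against a planted
0.18, p ≈ 0.001 at n = 263); methylation coverage, built to oppose openness,
comes out negative; stage-wise expression correlations are attenuated because
per-gene expression heterogeneity is deliberately much larger than the
openness effect. Step 3 repeats the study across seeds and reports the mean
recovered rho (0.182, SD 0.055 over 50 replicates) and the null false-positive
rate (0.045 at alpha 0.05 over 200 null replicates).

The same `run_pipeline()` call accepts real files in the same formats; an
optional two-column alias map translates efficiency-table gene symbols into
annotation gene IDs before joining.

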