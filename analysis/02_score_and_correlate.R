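#!/usr/bin/env Rscript
# Step 2: run the full scoring + association pipeline over the files written
# by 01_simulate.R. Produces results/run/feature_table.tsv (one row per gene:
# ATAC coefficient, methylation coefficient, promoter score, stage RPKMs,
# aggregated efficiency), results/run/associations.tsv (Spearman rho / p / n
# per feature and stage), the contingency report, the guide GC comparison,
# and a manifest with input checksums and per-analysis n.

suppressMessages(library(crisprchrom))

sim <- "results/sim"
stopifnot(file.exists(file.path(sim, "genome.gff3")))

cfg <- run_config(
  annotation = file.path(sim, "genome.gff3"),
  efficiency = file.path(sim, "efficiency.tsv"),
  atac = file.path(sim, "atac.broadPeak"),
  meth = file.path(sim, "meth.broadPeak"),
  expression = file.path(sim, "expression.tsv"),
  probes = file.path(sim, "probes.tsv"),
  chrom_sizes = file.path(sim, "chrom.sizes"),
  seed = 20180423)

res <- run_pipeline(cfg, "results/run")

cat("\nAssociation with mutagenesis efficiency (Spearman):\n")
a <- res$associations
a$statistic <- round(a$statistic, 3)
a$p_value <- signif(a$p_value, 3)
print(a[, c("feature", "stage", "statistic", "n", "p_value", "significant")],
      row.names = FALSE)

cat("\nExpression-category contingency (Fisher's exact):\n")
k <- res$contingency
k$statistic <- round(k$statistic, 3)
k$p_value <- signif(k$p_value, 3)
print(k[, c("feature", "statistic", "p_value", "a", "b", "c", "d")],
      row.names = FALSE)

cat("\nGuide GC content, functional vs non-functional (Mann-Whitney):\n")
print(transform(res$gc_test, p_value = signif(p_value, 3)),
      row.names = FALSE)

cat("\nThe accessibility coefficient carries the planted effect;",
    "methylation opposes it by construction.\n")
cat("Tables written under results/run/\n")
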