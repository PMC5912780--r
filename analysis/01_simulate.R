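#!/usr/bin/env Rscript
# Step 1: generate the synthetic study at the default conditions and write it
# under results/sim/. The bundle emulates the inputs of the real analysis:
# a GRCz10-style annotation, ATAC and methylation broadPeak files, a
# stage-wise RPKM table, a promoter probe table, and a CRISPRz-style guide
# efficiency table, all driven by one latent per-gene "openness".

suppressMessages(library(crisprchrom))

cfg <- sim_config(seed = 20180423)
bundle <- simulate_study(cfg)
paths <- write_bundle(bundle, "results/sim")

models <- bundle$models
n_tx <- tapply(models$transcript_id, models$gene_id,
               function(x) length(unique(x)))
units <- build_units(models, chrom_sizes = bundle$chrom_sizes)
units_per_gene <- table(units$gene_id)
multi_tss <- names(n_tx)[n_tx > 1]

cat("Synthetic study written to results/sim/\n")
cat(sprintf("  genes: %d on %d chromosomes (seed %d)\n",
            cfg$n_genes, cfg$n_chromosomes, cfg$seed))
cat(sprintf("  single-transcript genes: %d; multi-TSS genes: %d\n",
            sum(n_tx == 1), length(multi_tss)))
cat(sprintf("  clustering resolved %d of %d multi-TSS genes to one unit\n",
            sum(units_per_gene[multi_tss] == 1), length(multi_tss)))
cat(sprintf("  transcriptional units: %d; ATAC peaks: %d (promoter + background); methylation peaks: %d\n",
            nrow(units), nrow(bundle$atac), nrow(bundle$meth)))
cat(sprintf("  guides: %d over %d genes; functional: %.0f%%\n",
            nrow(bundle$efficiency),
            length(unique(bundle$efficiency$gene_id)),
            100 * mean(bundle$efficiency$functional)))
cat("  planted Spearman rho (openness vs efficiency):",
    cfg$planted_rho, "\n")
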