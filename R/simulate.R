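# Seeded synthetic-study generator. One latent standard-normal "openness" per
# gene drives promoter ATAC signal (positively), exon-methylation coverage
# (negatively), probe intensity and the stage-wise expression trajectory;
# mutagenesis efficiency is tied to openness through a Gaussian copula at a
# chosen Spearman rho, so the full pipeline can be checked against the
# planted effect size.

#' Configuration of a synthetic study
#'
#' Defaults encode the study conditions of the accessibility analysis this
#' generator emulates: 263 genes with recorded efficiencies, a planted
#' Spearman rho of 0.18 between accessibility and efficiency, a multi-TSS
#' gene fraction of 0.16 (the proportion of multi-transcript genes in the
#' reference annotation), and guide-level noise of 2 percentage points.
#'
#' @param n_genes number of genes (>= 10).
#' @param n_chromosomes chromosomes the genes are spread over.
#' @param multi_tss_fraction fraction of genes with 2-4 transcripts whose
#'   TSSs are offset by 50-5,000 nt.
#' @param planted_rho target Spearman correlation between openness-derived
#'   features and efficiency, `|rho| < 1`.
#' @param noise_sd SD of the lognormal noise on peak signal, methylation
#'   coverage (logit scale) and expression (log scale).
#' @param peak_density background ATAC peaks per kb, unlinked to openness.
#' @param seed integer seed; the whole bundle is a pure function of the
#'   config.
#' @param stages developmental stage vocabulary for the expression table.
#' @param atac_slope,meth_slope,expr_slope effect of openness on log ATAC
#'   signal, logit methylation coverage (negated) and log RPKM.
#' @param guide_sd SD (percentage points) of guide-level efficiency noise.
#' @param max_guides guides per gene drawn uniformly from `1:max_guides`.
#' @param functional_threshold guide efficiency (%) above which a guide is
#'   flagged functional; 70 yields about the 30% functional-guide rate seen
#'   in practice.
#' @param cluster_gap,flank unit-building parameters used when placing
#'   promoter peaks.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 263, n_chromosomes = 5,
                       multi_tss_fraction = 0.16, planted_rho = 0.18,
                       noise_sd = 0.1, peak_density = 0.02, seed = 1,
                       stages = DEV_STAGES, atac_slope = 1, meth_slope = 1,
                       expr_slope = 1, guide_sd = 2, max_guides = 4,
                       functional_threshold = 70, cluster_gap = 500,
                       flank = 1000) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_chromosomes = as.integer(n_chromosomes),
              multi_tss_fraction = multi_tss_fraction,
              planted_rho = planted_rho, noise_sd = noise_sd,
              peak_density = peak_density, seed = as.integer(seed),
              stages = stages, atac_slope = atac_slope,
              meth_slope = meth_slope, expr_slope = expr_slope,
              guide_sd = guide_sd, max_guides = as.integer(max_guides),
              functional_threshold = functional_threshold,
              cluster_gap = cluster_gap, flank = flank)
  if (cfg$n_genes < 10) stop("n_genes must be >= 10")
  if (abs(cfg$planted_rho) >= 1) stop("|planted_rho| must be < 1")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$multi_tss_fraction < 0 || cfg$multi_tss_fraction > 1)
    stop("multi_tss_fraction must be in [0, 1]")
  if (cfg$n_chromosomes < 1) stop("need at least one chromosome")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a gene annotation
#'
#' Genes are placed left to right without overlap on `n_chromosomes`
#' chromosomes. Each gene carries one transcript with probability
#' `1 - multi_tss_fraction`, otherwise 2-4 transcripts whose TSSs are offset
#' by 50-5,000 nt (so clustered and unclustered TSS pairs both arise);
#' transcripts have 2-8 exons of 100-500 bp separated by 200-2,000 bp
#' introns. Draws come from the current RNG state; seed via
#' [simulate_study()] or `set.seed()` for standalone use.
#'
#' @param config `sim_config`.
#' @return list with `models` (exon-level gene-model table) and
#'   `chrom_sizes` (named vector).
#' @export
simulate_genome <- function(config) {
  n <- config$n_genes
  gene_ids <- sprintf("g%04d", seq_len(n))
  chrom_of <- sort(rep_len(seq_len(config$n_chromosomes), n))
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  multi <- stats::runif(n) < config$multi_tss_fraction
  n_tx <- ifelse(multi, sample(2:4, n, replace = TRUE), 1L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  cursor <- stats::setNames(rep(10000L, config$n_chromosomes), chroms)
  g_id <- list(); t_id <- list(); chr <- list(); std <- list()
  st <- list(); en <- list()
  k <- 0L
  for (g in seq_len(n)) {
    cn <- chroms[chrom_of[g]]
    anchor <- cursor[[cn]]
    anchor_r <- anchor + 24000L   # right anchor for minus-strand TSSs
    offs <- c(0L, if (n_tx[g] > 1)
      sample(50:5000, n_tx[g] - 1, replace = TRUE))
    gmax <- anchor
    for (t in seq_len(n_tx[g])) {
      ne <- sample(2:8, 1)
      w <- sample(100:500, ne, replace = TRUE)
      intr <- if (ne > 1) sample(200:2000, ne - 1, replace = TRUE) else
        integer(0)
      rel <- cumsum(c(0L, w[-ne] + intr))   # exon starts relative to chain
      chainlen <- rel[ne] + w[ne]
      if (strand[g] == "+") {
        L <- anchor + offs[t]
      } else {
        L <- anchor_r - offs[t] - chainlen
      }
      k <- k + 1L
      g_id[[k]] <- rep(gene_ids[g], ne)
      t_id[[k]] <- rep(sprintf("%s.t%d", gene_ids[g], t), ne)
      chr[[k]] <- rep(cn, ne)
      std[[k]] <- rep(strand[g], ne)
      st[[k]] <- L + rel
      en[[k]] <- L + rel + w
      gmax <- max(gmax, L + chainlen)
    }
    cursor[[cn]] <- gmax + sample(5000:20000, 1)
  }
  models <- data.frame(gene_id = unlist(g_id), transcript_id = unlist(t_id),
                       chrom = unlist(chr), strand = unlist(std),
                       start = as.integer(unlist(st)),
                       end = as.integer(unlist(en)),
                       stringsAsFactors = FALSE)
  models <- validate_gene_models(models)
  chrom_sizes <- cursor + 10000L
  list(models = models, chrom_sizes = chrom_sizes)
}

#' Simulate ATAC and methylation peak calls
#'
#' Every transcriptional unit receives a promoter ATAC peak spanning most of
#' its scoring region with `signal = exp(atac_slope * openness + eps)`,
#' `eps ~ N(0, noise_sd)`, plus Poisson background peaks (density
#' `peak_density` per kb) whose signal is unlinked to openness. Methylation
#' peaks cover each gene's merged exons with per-gene coverage fraction
#' `plogis(-meth_slope * openness + eps)`.
#'
#' @param models exon-level gene-model table from [simulate_genome()].
#' @param chrom_sizes named chromosome lengths.
#' @param openness per-gene latent values, named by `gene_id`.
#' @param config `sim_config`.
#' @return list with peak tables `atac` and `meth`.
#' @export
simulate_chromatin <- function(models, chrom_sizes, openness, config) {
  units <- build_units(models, cluster_gap = config$cluster_gap,
                       flank = config$flank, chrom_sizes = chrom_sizes)
  m <- nrow(units)
  op_u <- unname(openness[units$gene_id])
  center <- units$representative_tss + sample(-300:300, m, replace = TRUE)
  width <- sample(1500:3000, m, replace = TRUE)
  a_start <- pmax(0L, as.integer(center - width %/% 2))
  a_end <- a_start + width
  a_sig <- exp(config$atac_slope * op_u +
                 stats::rnorm(m, 0, config$noise_sd))
  nbg_lambda <- config$peak_density * unname(chrom_sizes) / 1000
  nbg <- stats::rpois(length(chrom_sizes), nbg_lambda)
  bg_chrom <- rep(names(chrom_sizes), nbg)
  bg_start <- as.integer(floor(stats::runif(sum(nbg)) *
                                 (rep(unname(chrom_sizes), nbg) - 1200)))
  bg_width <- sample(200:1000, sum(nbg), replace = TRUE)
  bg_sig <- exp(stats::rnorm(sum(nbg), 0, 1))
  atac <- data.frame(
    chrom = c(units$chrom, bg_chrom),
    start = c(a_start, bg_start),
    end = c(a_end, bg_start + bg_width),
    name = sprintf("atac_%05d", seq_len(m + sum(nbg))),
    score = as.integer(pmin(1000, round(100 * c(a_sig, bg_sig)))),
    strand = ".",
    signal_value = c(a_sig, bg_sig),
    p_value = -1, q_value = -1,
    stringsAsFactors = FALSE)
  atac <- atac[order(atac$chrom, atac$start, atac$end), , drop = FALSE]
  rownames(atac) <- NULL

  ex <- merged_exons(models)
  op_e <- unname(openness[ex$gene_id])
  frac <- stats::plogis(-config$meth_slope * op_e +
                          stats::rnorm(nrow(ex), 0, config$noise_sd))
  cov_len <- as.integer(round(frac * interval_width(ex)))
  keep <- cov_len >= 1L
  meth <- data.frame(
    chrom = ex$chrom[keep],
    start = ex$start[keep],
    end = ex$start[keep] + cov_len[keep],
    name = sprintf("meth_%05d", seq_len(sum(keep))),
    score = 100L,
    strand = ".",
    signal_value = exp(stats::rnorm(sum(keep), 0, 0.25)),
    p_value = -1, q_value = -1,
    stringsAsFactors = FALSE)
  meth <- meth[order(meth$chrom, meth$start, meth$end), , drop = FALSE]
  rownames(meth) <- NULL
  list(atac = atac, meth = meth)
}

#' Simulate guide efficiencies tied to openness by a Gaussian copula
#'
#' Gene-level efficiency is `100 * pnorm(z)` with
#' `z = r * openness + sqrt(1 - r^2) * eta`, where
#' `r = 2 * sin(pi * planted_rho / 6)` is the Pearson correlation whose
#' bivariate-normal Spearman correlation equals `planted_rho`. Each gene
#' gets 1-`max_guides` guides with iid noise of `guide_sd` percentage
#' points, random 20-mer protospacers, and a functional flag at
#' `functional_threshold`.
#'
#' @param openness named per-gene latent vector.
#' @param config `sim_config`.
#' @return list with `records` (guide-level efficiency table) and
#'   `gene_efficiency` (named per-gene copula values, before guide noise).
#' @export
simulate_efficiency <- function(openness, config) {
  n <- length(openness)
  r <- 2 * sin(pi * config$planted_rho / 6)
  z <- r * unname(openness) + sqrt(1 - r^2) * stats::rnorm(n)
  eff_gene <- 100 * stats::pnorm(z)
  n_guides <- sample(seq_len(config$max_guides), n, replace = TRUE)
  gene_id <- rep(names(openness), n_guides)
  eff <- pmin(100, pmax(0, rep(eff_gene, n_guides) +
                          stats::rnorm(sum(n_guides), 0, config$guide_sd)))
  bases <- matrix(sample(c("A", "C", "G", "T"), 20 * sum(n_guides),
                         replace = TRUE), ncol = 20)
  seqs <- do.call(paste0, as.data.frame(bases, stringsAsFactors = FALSE))
  records <- data.frame(gene_id = gene_id, guide_sequence = seqs,
                        efficiency = eff,
                        functional = eff > config$functional_threshold,
                        stringsAsFactors = FALSE)
  list(records = records,
       gene_efficiency = stats::setNames(eff_gene, names(openness)))
}

# Stage trajectory: log-RPKM baseline per stage and the stage-specific
# openness slope weight. The weight rises between oblong-sphere and
# 50%-epiboly so high-openness genes switch on around the MZT.
stage_mu <- c(0.8, 0.6, 0.6, 0.5, 0.5, 0.6, 0.6, 0.6)
stage_w <- c(0.2, 0.3, 0.7, 0.9, 1.0, 1.0, 1.0, 1.0)

#' Simulate the stage-wise expression table
#'
#' `RPKM = exp(mu_stage + g + expr_slope * w_stage * openness + eps)` with a
#' gene-level baseline `g ~ N(0, 1.2)` (expression heterogeneity independent
#' of openness) and `eps ~ N(0, noise_sd)`; the stage weight `w` rises from
#' oblong-sphere onward so the MZT increase scales with openness.
#'
#' @param openness named per-gene latent vector.
#' @param config `sim_config`.
#' @return long data.frame `gene_id`, `stage`, `rpkm`.
#' @export
simulate_expression <- function(openness, config) {
  n <- length(openness)
  stages <- config$stages
  ns <- length(stages)
  g <- stats::rnorm(n, 0, 1.2)
  log_rpkm <- rep(stage_mu[seq_len(ns)], each = n) +
    rep(g, ns) +
    config$expr_slope * rep(stage_w[seq_len(ns)], each = n) *
      rep(unname(openness), ns) +
    stats::rnorm(n * ns, 0, config$noise_sd)
  data.frame(gene_id = rep(names(openness), ns),
             stage = rep(stages, each = n),
             rpkm = exp(log_rpkm),
             stringsAsFactors = FALSE)
}

#' Simulate the promoter microarray probe table
#'
#' 3-10 probes per gene, each on one of two arrays, with
#' `log2(median_intensity) = 0.5 * openness + N(0, 0.5)`.
#'
#' @param openness named per-gene latent vector.
#' @param config `sim_config`.
#' @return data.frame `gene_id`, `probe_id`, `array_id`, `median_intensity`.
#' @export
simulate_probes <- function(openness, config) {
  n <- length(openness)
  n_probes <- sample(3:10, n, replace = TRUE)
  gene_id <- rep(names(openness), n_probes)
  total <- sum(n_probes)
  log2_mi <- 0.5 * rep(unname(openness), n_probes) +
    stats::rnorm(total, 0, 0.5)
  data.frame(gene_id = gene_id,
             probe_id = sprintf("probe_%05d", seq_len(total)),
             array_id = sample(c("array_1", "array_2"), total, replace = TRUE),
             median_intensity = 2^log2_mi,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic study
#'
#' Seeds the RNG from `config$seed` and generates, in a fixed order, the
#' latent openness, annotation, peak files, efficiency, expression and probe
#' tables. The result is a pure function of the config.
#'
#' @param config `sim_config` (default [sim_config()]).
#' @param expression,probes set `FALSE` to skip those tables (the chromatin
#'   path does not need them).
#' @return list (`sim_bundle`): `config`, `models`, `chrom_sizes`, `atac`,
#'   `meth`, `efficiency`, `expression`, `probes`, `latent` (data.frame of
#'   per-gene openness and copula efficiency).
#' @export
simulate_study <- function(config = sim_config(), expression = TRUE,
                           probes = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  openness <- stats::setNames(stats::rnorm(config$n_genes),
                              sprintf("g%04d", seq_len(config$n_genes)))
  genome <- simulate_genome(config)
  chrom <- simulate_chromatin(genome$models, genome$chrom_sizes, openness,
                              config)
  eff <- simulate_efficiency(openness, config)
  expr <- if (expression) simulate_expression(openness, config) else NULL
  prob <- if (probes) simulate_probes(openness, config) else NULL
  latent <- data.frame(gene_id = names(openness),
                       openness = unname(openness),
                       efficiency = unname(eff$gene_efficiency),
                       stringsAsFactors = FALSE)
  structure(list(config = config, models = genome$models,
                 chrom_sizes = genome$chrom_sizes, atac = chrom$atac,
                 meth = chrom$meth, efficiency = eff$records,
                 expression = expr, probes = prob, latent = latent),
            class = "sim_bundle")
}

#' Write a simulated study to disk
#'
#' Emits `genome.gff3`, `chrom.sizes`, `atac.broadPeak`, `meth.broadPeak`,
#' `efficiency.tsv`, `expression.tsv`, `probes.tsv` and `latent_truth.tsv`
#' with deterministic formatting (identical seeds give byte-identical
#' files).
#'
#' @param bundle `sim_bundle` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(annotation = file.path(dir, "genome.gff3"),
             chrom_sizes = file.path(dir, "chrom.sizes"),
             atac = file.path(dir, "atac.broadPeak"),
             meth = file.path(dir, "meth.broadPeak"),
             efficiency = file.path(dir, "efficiency.tsv"),
             latent = file.path(dir, "latent_truth.tsv"))
  write_gff3(bundle$models, paths["annotation"], bundle$chrom_sizes)
  writeLines(sprintf("%s\t%d", names(bundle$chrom_sizes),
                     as.integer(bundle$chrom_sizes)), paths["chrom_sizes"])
  write_peaks(bundle$atac, paths["atac"])
  write_peaks(bundle$meth, paths["meth"])
  eff <- bundle$efficiency
  eff$functional <- ifelse(eff$functional, "TRUE", "FALSE")
  write_tsv_formatted(eff, paths["efficiency"])
  write_tsv_formatted(bundle$latent, paths["latent"])
  if (!is.null(bundle$expression)) {
    paths <- c(paths, expression = file.path(dir, "expression.tsv"))
    write_tsv_formatted(bundle$expression, paths["expression"])
  }
  if (!is.null(bundle$probes)) {
    paths <- c(paths, probes = file.path(dir, "probes.tsv"))
    write_tsv_formatted(bundle$probes, paths["probes"])
  }
  paths
}
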