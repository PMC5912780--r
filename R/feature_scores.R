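# Per-gene chromatin features: the ATAC accessibility coefficient over TSS
# regions, the exon-methylation coefficient, the promoter probe score, and
# guide GC content.

#' ATAC coefficient of a single transcriptional-unit region
#'
#' Sum over overlapping peaks of `signal_value * overlap_bp`, divided by the
#' region's nominal length (2 * flank, 2,000 nt at defaults). No overlapping
#' peak gives 0.
#'
#' @param unit one-row unit table ([build_units()]).
#' @param peaks peak table sorted by `(chrom, start)` ([read_peaks()]).
#' @return non-negative scalar.
#' @export
atac_coefficient <- function(unit, peaks) {
  atac_coefficients(unit[1, , drop = FALSE], peaks)
}

#' ATAC coefficients for many unit regions at once
#'
#' @param units unit table.
#' @param peaks peak table.
#' @return numeric vector, one coefficient per unit row.
#' @export
atac_coefficients <- function(units, peaks) {
  acc <- numeric(nrow(units))
  if (nrow(units) == 0 || nrow(peaks) == 0) return(acc)
  hits <- interval_overlaps(units[, c("chrom", "start", "end")],
                            peaks[, c("chrom", "start", "end")])
  if (nrow(hits)) {
    contrib <- peaks$signal_value[hits$b_idx] * hits$overlap
    sums <- tapply(contrib, hits$a_idx, sum)
    acc[as.integer(names(sums))] <- as.numeric(sums)
  }
  acc / units$nominal_length
}

#' Gene-level ATAC coefficient: mean over the gene's units
#'
#' A gene whose TSSs resolve to several transcriptional units gets the
#' arithmetic mean of its per-unit coefficients, so every gene carries a
#' single accessibility value.
#'
#' @param units unit table (possibly many genes).
#' @param peaks peak table.
#' @return data.frame with columns `gene_id`, `atac_coefficient`.
#' @export
gene_atac_coefficients <- function(units, peaks) {
  if (nrow(units) == 0)
    return(data.frame(gene_id = character(), atac_coefficient = numeric(),
                      stringsAsFactors = FALSE))
  co <- atac_coefficients(units, peaks)
  m <- tapply(co, units$gene_id, mean)
  data.frame(gene_id = names(m), atac_coefficient = as.numeric(m),
             stringsAsFactors = FALSE)
}

#' Merge a gene's exons across transcripts into disjoint intervals
#'
#' The union of all isoforms' exons, so the exonic footprint (the methylation
#' denominator) counts no base twice.
#'
#' @param models exon-level gene-model table (one or more genes).
#' @return data.frame `gene_id`, `chrom`, `start`, `end` of disjoint merged
#'   exons, plus attribute-free total via [interval_width()].
#' @export
merged_exons <- function(models) {
  if (nrow(models) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  chrom_of <- tapply(models$chrom, models$gene_id, function(x) x[1])
  # merge per gene: a gene lives on one chromosome, so the gene id can stand
  # in for the sequence name during the union
  red <- merge_intervals(data.frame(chrom = models$gene_id,
                                    start = models$start, end = models$end,
                                    stringsAsFactors = FALSE))
  data.frame(gene_id = red$chrom,
             chrom = unname(chrom_of[red$chrom]),
             start = red$start,
             end = red$end,
             stringsAsFactors = FALSE)
}

#' Exon-methylation coefficient of one gene
#'
#' Overlap between the gene's merged exons and the (merged) methylation peak
#' footprint, divided by the total merged-exon length. The default coverage
#' reading is dimensionless in `[0, 1]`; `weight = "signal"` instead sums
#' `signal_value * overlap_bp` over raw peaks (unbounded).
#'
#' @param exons merged-exon table of one gene ([merged_exons()]).
#' @param peaks methylation peak table.
#' @param weight `"coverage"` (default) or `"signal"`.
#' @return scalar coefficient, or `NA` when the gene has no exonic bases.
#' @export
methylation_coefficient <- function(exons, peaks,
                                    weight = c("coverage", "signal")) {
  weight <- match.arg(weight)
  total <- sum(interval_width(exons))
  if (total == 0) return(NA_real_)
  if (nrow(peaks) == 0) return(0)
  if (weight == "coverage") {
    fp <- merge_intervals(peaks[, c("chrom", "start", "end")])
    hits <- interval_overlaps(exons[, c("chrom", "start", "end")], fp)
    sum(hits$overlap) / total
  } else {
    hits <- interval_overlaps(exons[, c("chrom", "start", "end")],
                              peaks[, c("chrom", "start", "end")])
    sum(peaks$signal_value[hits$b_idx] * hits$overlap) / total
  }
}

#' Methylation coefficients for all genes
#'
#' @param models exon-level gene-model table.
#' @param peaks methylation peak table.
#' @param weight `"coverage"` or `"signal"` (see
#'   [methylation_coefficient()]).
#' @return data.frame `gene_id`, `methylation_coefficient`.
#' @export
gene_methylation_coefficients <- function(models, peaks,
                                          weight = c("coverage", "signal")) {
  weight <- match.arg(weight)
  ex <- merged_exons(models)
  genes <- unique(ex$gene_id)
  total <- tapply(interval_width(ex), ex$gene_id, sum)[genes]
  acc <- stats::setNames(numeric(length(genes)), genes)
  if (nrow(peaks) > 0 && nrow(ex) > 0) {
    b <- if (weight == "coverage")
      merge_intervals(peaks[, c("chrom", "start", "end")]) else peaks
    hits <- interval_overlaps(ex[, c("chrom", "start", "end")],
                              b[, c("chrom", "start", "end")])
    if (nrow(hits)) {
      contrib <- if (weight == "coverage") hits$overlap
                 else b$signal_value[hits$b_idx] * hits$overlap
      sums <- tapply(contrib, ex$gene_id[hits$a_idx], sum)
      acc[names(sums)] <- as.numeric(sums)
    }
  }
  data.frame(gene_id = genes,
             methylation_coefficient = as.numeric(acc / total),
             stringsAsFactors = FALSE)
}

#' Promoter probe score of one gene
#'
#' Per array, the sum of `log2(median_intensity)` over the gene's probes;
#' the score is the arithmetic mean of these per-array sums.
#'
#' @param probes probe records of one gene (columns `probe_id`, `array_id`,
#'   `median_intensity`).
#' @return scalar score, `NA` for zero probes.
#' @export
promoter_score <- function(probes) {
  if (nrow(probes) == 0) return(NA_real_)
  if (any(probes$median_intensity <= 0))
    stop("median_intensity must be > 0 (log-domain)")
  per_array <- tapply(log2(probes$median_intensity), probes$array_id, sum)
  mean(per_array)
}

#' Promoter probe scores for all genes
#'
#' @param probes probe records (with `gene_id`).
#' @return data.frame `gene_id`, `promoter_score`.
#' @export
gene_promoter_scores <- function(probes) {
  if (nrow(probes) == 0)
    return(data.frame(gene_id = character(), promoter_score = numeric(),
                      stringsAsFactors = FALSE))
  if (any(probes$median_intensity <= 0))
    stop("median_intensity must be > 0 (log-domain)")
  sums <- tapply(log2(probes$median_intensity),
                 list(probes$gene_id, probes$array_id), sum)
  data.frame(gene_id = rownames(sums),
             promoter_score = rowMeans(sums, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

#' GC content of guide protospacers
#'
#' @param guide_sequence character vector of 20-mers over `{A,C,G,T}` (PAM
#'   excluded).
#' @return percent GC in `[0, 100]`, vectorized.
#' @export
gc_content <- function(guide_sequence) {
  g <- toupper(guide_sequence)
  if (any(nchar(g) != 20L))
    stop("guide sequences must be exactly 20 nt (PAM excluded)")
  if (any(grepl("[^ACGT]", g)))
    stop("guide sequences must contain only A, C, G, T")
  100 * nchar(gsub("[AT]", "", g)) / 20
}

#' Assemble the per-gene feature table
#'
#' Joins the gene-level chromatin features, stage-wise RPKM (wide), and
#' aggregated efficiency into one row per gene. Genes lacking a data source
#' carry `NA` for that feature, never 0.
#'
#' @param models exon-level gene-model table (or `NULL`).
#' @param atac_peaks,meth_peaks peak tables (or `NULL`).
#' @param probes probe records (or `NULL`).
#' @param expression long expression records (or `NULL`).
#' @param efficiency efficiency records (or `NULL`).
#' @param cluster_gap,flank unit-building parameters.
#' @param chrom_sizes optional named chromosome lengths.
#' @param aggregation per-gene guide aggregation, `"mean"` or `"median"`.
#' @param meth_weight `"coverage"` or `"signal"`.
#' @param alias optional identifier alias map applied to the efficiency,
#'   expression and probe tables before joining.
#' @return feature table data.frame, one row per gene.
#' @export
build_feature_table <- function(models = NULL, atac_peaks = NULL,
                                meth_peaks = NULL, probes = NULL,
                                expression = NULL, efficiency = NULL,
                                cluster_gap = 500, flank = 1000,
                                chrom_sizes = NULL,
                                aggregation = c("mean", "median"),
                                meth_weight = c("coverage", "signal"),
                                alias = NULL) {
  aggregation <- match.arg(aggregation)
  meth_weight <- match.arg(meth_weight)
  pieces <- list()
  if (!is.null(models)) {
    units <- build_units(models, cluster_gap = cluster_gap, flank = flank,
                         chrom_sizes = chrom_sizes)
    if (!is.null(atac_peaks))
      pieces$atac <- gene_atac_coefficients(units, atac_peaks)
    if (!is.null(meth_peaks))
      pieces$meth <- gene_methylation_coefficients(models, meth_peaks,
                                                   weight = meth_weight)
  }
  if (!is.null(probes)) {
    probes$gene_id <- apply_alias(probes$gene_id, alias)
    pieces$promoter <- gene_promoter_scores(probes)
  }
  if (!is.null(expression)) {
    expression$gene_id <- apply_alias(expression$gene_id, alias)
    wide <- stats::reshape(
      expression[, c("gene_id", "stage", "rpkm")], idvar = "gene_id",
      timevar = "stage", direction = "wide")
    names(wide) <- sub("^rpkm\\.", "", names(wide))
    keep <- intersect(DEV_STAGES, names(wide))
    names(wide)[match(keep, names(wide))] <-
      vapply(keep, stage_column, character(1))
    pieces$expression <- wide
  }
  if (!is.null(efficiency)) {
    efficiency$gene_id <- apply_alias(efficiency$gene_id, alias)
    pieces$efficiency <- aggregate_efficiency(efficiency, method = aggregation)
  }
  if (length(pieces) == 0)
    stop("no inputs supplied to build_feature_table()")
  all_genes <- sort(unique(unlist(lapply(pieces, `[[`, "gene_id"))))
  out <- data.frame(gene_id = all_genes, stringsAsFactors = FALSE)
  for (p in pieces)
    out <- merge(out, p, by = "gene_id", all.x = TRUE, sort = TRUE)
  out
}
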