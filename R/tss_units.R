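# Transcriptional units: per-gene TSS pooling, single-linkage clustering of
# TSSs within a fixed gap (default 500 nt), and the symmetric flanking region
# (default +/- 1,000 nt) used for accessibility scoring.

#' Extract pooled transcription start sites for each gene
#'
#' One TSS per transcript: the first transcribed base, i.e. the minimum exon
#' start on the plus strand and the maximum exon end minus one on the minus
#' strand (0-based). Duplicate positions within a gene are collapsed.
#'
#' @param models exon-level gene-model table ([read_gene_annotation()]).
#' @return data.frame with columns `gene_id`, `chrom`, `tss`, sorted by
#'   `(gene_id, tss)` and deduplicated.
#' @export
extract_tss <- function(models) {
  if (any(models$strand == "."))
    stop("strand required to orient TSS; transcript(s) with strand '.': ",
         paste(utils::head(unique(
           models$transcript_id[models$strand == "."]), 5), collapse = ", "))
  key <- paste(models$gene_id, models$transcript_id, sep = "\r")
  first <- !duplicated(key)
  lo <- tapply(models$start, key, min)
  hi <- tapply(models$end, key, max)
  k <- key[first]
  tss_tx <- ifelse(models$strand[first] == "+", lo[k], hi[k] - 1L)
  out <- data.frame(gene_id = models$gene_id[first],
                    chrom = models$chrom[first],
                    tss = as.integer(tss_tx),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$gene_id, out$tss), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster sorted TSS positions into transcriptional units
#'
#' Single-linkage chaining: consecutive positions at most `cluster_gap` apart
#' join the same cluster. The representative TSS is the midpoint of the
#' cluster span, `floor((min + max) / 2)`; a singleton's representative is the
#' position itself.
#'
#' @param positions sorted, deduplicated TSS positions (0-based bp).
#' @param cluster_gap maximum chaining distance in bp (default 500).
#' @return list of clusters, each a list with `members` (positions) and
#'   `representative` (bp); empty input gives an empty list.
#' @export
cluster_tss <- function(positions, cluster_gap = 500) {
  if (length(positions) == 0) return(list())
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be sorted ascending and deduplicated")
  grp <- cumsum(c(0L, as.integer(diff(positions) > cluster_gap)))
  unname(lapply(split(positions, grp), function(p)
    list(members = p,
         representative = as.integer((min(p) + max(p)) %/% 2))))
}

#' Build transcriptional units with flanking scoring regions
#'
#' Pools TSSs per gene ([extract_tss()]), clusters them ([cluster_tss()]),
#' and attaches the symmetric `+/- flank` region around each representative
#' TSS. Regions are clipped at position 0 (and at the chromosome end when
#' `chrom_sizes` is given) but the nominal length stays `2 * flank` — it is
#' the fixed denominator of the accessibility coefficient.
#'
#' @param models exon-level gene-model table.
#' @param cluster_gap TSS chaining distance in bp (default 500).
#' @param flank half-width of the scoring region in bp (default 1000).
#' @param chrom_sizes optional named vector of chromosome lengths (bp).
#' @return data.frame with one row per unit: `gene_id`, `unit_id`, `chrom`,
#'   `representative_tss`, `n_members`, `tss_min`, `tss_max`, `start`, `end`,
#'   `nominal_length`.
#' @export
build_units <- function(models, cluster_gap = 500, flank = 1000,
                        chrom_sizes = NULL) {
  tss <- extract_tss(models)
  n <- nrow(tss)
  if (n == 0)
    return(data.frame(gene_id = character(), unit_id = character(),
                      chrom = character(), representative_tss = integer(),
                      n_members = integer(), tss_min = integer(),
                      tss_max = integer(), start = integer(), end = integer(),
                      nominal_length = integer(), stringsAsFactors = FALSE))
  new_cluster <- c(TRUE, tss$gene_id[-1] != tss$gene_id[-n] |
                     diff(tss$tss) > cluster_gap)
  grp <- cumsum(new_cluster)
  lo <- as.integer(tapply(tss$tss, grp, min))
  hi <- as.integer(tapply(tss$tss, grp, max))
  cnt <- as.integer(tapply(tss$tss, grp, length))
  gene <- tss$gene_id[new_cluster]
  chrom <- tss$chrom[new_cluster]
  rep_tss <- (lo + hi) %/% 2L
  idx <- stats::ave(seq_along(gene), gene, FUN = seq_along)
  start <- pmax(0L, rep_tss - as.integer(flank))
  end <- rep_tss + as.integer(flank)
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[chrom])
    end <- ifelse(!is.na(lim), pmin(end, as.integer(lim)), end)
  }
  data.frame(gene_id = gene,
             unit_id = sprintf("%s_u%d", gene, idx),
             chrom = chrom,
             representative_tss = rep_tss,
             n_members = cnt,
             tss_min = lo,
             tss_max = hi,
             start = start,
             end = end,
             nominal_length = 2L * as.integer(flank),
             stringsAsFactors = FALSE)
}

#' Render units as BED6 (name = gene, score = member count)
#'
#' @param units unit table from [build_units()].
#' @param path output BED file.
#' @export
write_units_bed <- function(units, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.", units$chrom, units$start,
                     units$end, units$gene_id, units$n_members), path)
  invisible(path)
}
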