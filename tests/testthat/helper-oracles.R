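# Independent oracles used by the tests: per-base brute-force accumulation
# for the overlap coefficients, a gap-scan for TSS clustering, closed-form /
# enumeration routes for the rank statistics. Deliberately naive code paths,
# sharing nothing with the package implementation.

# Per-base ATAC accumulator: for each base of the region add the signal of
# every peak covering it, then divide by the nominal length.
brute_atac <- function(unit, peaks) {
  if (unit$end <= unit$start) return(0)
  bases <- seq(unit$start, unit$end - 1)
  acc <- 0
  for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[i] != unit$chrom) next
    covered <- bases >= peaks$start[i] & bases < peaks$end[i]
    acc <- acc + sum(covered) * peaks$signal_value[i]
  }
  acc / unit$nominal_length
}

# Per-base methylation accumulator: mark exonic bases and peak-covered bases
# in genome-position bitmaps, count exonic bases covered by >= 1 peak, divide
# by the number of exonic bases (exons may arrive unmerged).
brute_meth <- function(exons, peaks) {
  covered_exonic <- 0
  total <- 0
  for (ch in unique(exons$chrom)) {
    exch <- exons[exons$chrom == ch, , drop = FALSE]
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    glen <- max(exch$end, pk$end, 1)
    exonic <- logical(glen)
    for (i in seq_len(nrow(exch)))
      exonic[(exch$start[i] + 1):exch$end[i]] <- TRUE
    inpeak <- logical(glen)
    for (i in seq_len(nrow(pk)))
      inpeak[(pk$start[i] + 1):pk$end[i]] <- TRUE
    total <- total + sum(exonic)
    covered_exonic <- covered_exonic + sum(exonic & inpeak)
  }
  if (total == 0) return(NA_real_)
  covered_exonic / total
}

# Merged total exon length by per-base bitmap.
brute_exon_footprint <- function(exons) {
  sum(vapply(unique(exons$chrom), function(ch) {
    exch <- exons[exons$chrom == ch, , drop = FALSE]
    bit <- logical(max(exch$end))
    for (i in seq_len(nrow(exch)))
      bit[(exch$start[i] + 1):exch$end[i]] <- TRUE
    sum(bit)
  }, numeric(1)))
}

# Gap-scan clustering oracle: cluster count is 1 + number of adjacent gaps
# exceeding the threshold.
oracle_cluster_count <- function(positions, gap) {
  if (length(positions) == 0) return(0L)
  1L + sum(diff(sort(positions)) > gap)
}

# Classical no-ties Spearman formula.
oracle_spearman_noties <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Rank-Pearson oracle (valid with ties), written from the covariance
# definition rather than stats::cor.
oracle_spearman_ties <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Mann-Whitney exact two-sided p by enumeration over all C(na+nb, na)
# labelings of the pooled values (no ties assumed).
oracle_mw_exact <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    av <- pool[idx]; bv <- pool[-idx]
    sum(outer(av, bv, ">"))
  }
  u_obs <- u_of(seq_len(na))
  us <- utils::combn(length(pool), na, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Fisher two-sided p by direct enumeration over all tables with the observed
# margins, probabilities from log-binomial coefficients (not dhyper).
oracle_fisher <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- sum(m)
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(N, c1)
  probs <- exp(logp)
  p_obs <- exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(N, c1))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Random small scoring instance: a handful of units and peaks on one or two
# chromosomes with coordinates < 1e5.
random_overlap_instance <- function() {
  n_units <- sample(1:5, 1)
  n_peaks <- sample(0:20, 1)
  chroms <- c("chr1", "chr2")
  flank <- sample(c(200, 500, 1000), 1)
  rep_tss <- sample(2000:95000, n_units)
  units <- data.frame(
    gene_id = sprintf("g%02d", seq_len(n_units)),
    unit_id = sprintf("u%02d", seq_len(n_units)),
    chrom = sample(chroms, n_units, replace = TRUE),
    representative_tss = rep_tss,
    start = pmax(0L, rep_tss - flank), end = rep_tss + flank,
    nominal_length = 2L * flank,
    stringsAsFactors = FALSE)
  pk_start <- sample(0:99000, max(n_peaks, 1), replace = TRUE)
  peaks <- data.frame(
    chrom = sample(chroms, max(n_peaks, 1), replace = TRUE),
    start = pk_start,
    end = pk_start + sample(50:3000, max(n_peaks, 1), replace = TRUE),
    name = "p", score = 0L, strand = ".",
    signal_value = round(stats::runif(max(n_peaks, 1), 0, 50), 3),
    p_value = -1, q_value = -1,
    stringsAsFactors = FALSE)[seq_len(n_peaks), , drop = FALSE]
  list(units = units, peaks = peaks)
}

# Tiny exon set (possibly overlapping across transcripts) for methylation
# oracle checks.
random_exon_instance <- function() {
  n_ex <- sample(1:8, 1)
  start <- sample(0:5000, n_ex, replace = TRUE)
  exons <- data.frame(chrom = "chr1", start = start,
                      end = start + sample(50:800, n_ex, replace = TRUE),
                      stringsAsFactors = FALSE)
  n_pk <- sample(0:10, 1)
  ps <- sample(0:5500, max(n_pk, 1), replace = TRUE)
  peaks <- data.frame(chrom = "chr1", start = ps,
                      end = ps + sample(20:1500, max(n_pk, 1), replace = TRUE),
                      name = "p", score = 0L, strand = ".",
                      signal_value = 1, p_value = -1, q_value = -1,
                      stringsAsFactors = FALSE)[seq_len(n_pk), , drop = FALSE]
  list(exons = exons, peaks = peaks)
}

# Minimal hand-built gene-model table.
make_models <- function(...) {
  tx <- list(...)
  do.call(rbind, lapply(tx, function(t)
    data.frame(gene_id = t$gene, transcript_id = t$tx,
               chrom = t$chrom %||% "chr1", strand = t$strand,
               start = vapply(t$exons, `[[`, numeric(1), 1),
               end = vapply(t$exons, `[[`, numeric(1), 2),
               stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
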