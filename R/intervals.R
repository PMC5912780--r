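# Interval primitives. All coordinates in this package are 0-based half-open
# [start, end); GFF3/GTF (1-based inclusive) are converted at the I/O boundary,
# BED/broadPeak need no conversion. The overlap engine is a vectorized sweep
# over start-sorted intervals (candidate windows pruned with findInterval on
# starts and on the running maximum of ends), sized for the tens of thousands
# of intervals a study of this kind carries.

#' Construct a validated interval table
#'
#' @param chrom character vector of chromosome names.
#' @param start 0-based inclusive start positions (bp).
#' @param end exclusive end positions (bp).
#' @param strand strand of each interval, one of `"+"`, `"-"`, `"."`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  start <- as.integer(start)
  end <- as.integer(end)
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop(what, ": missing coordinates", call. = FALSE)
  if (any(df$start < 0))
    stop(what, ": negative start position", call. = FALSE)
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(what, ": start must be < end (zero-length intervals rejected); ",
         "first offending row ", bad[1], call. = FALSE)
  if (!is.null(df$strand) && !all(df$strand %in% c("+", "-", ".")))
    stop(what, ": strand must be one of '+', '-', '.'", call. = FALSE)
  invisible(df)
}

interval_width <- function(df) df$end - df$start

#' Merge intervals into maximal disjoint intervals
#'
#' Abutting and overlapping intervals are unioned (per chromosome); output is
#' sorted by `(chrom, start)`.
#'
#' @param df interval data.frame (`chrom`, `start`, `end`).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
merge_intervals <- function(df) {
  n <- nrow(df)
  if (n == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  o <- order(df$chrom, df$start, df$end)
  ch <- df$chrom[o]; s <- df$start[o]; e <- df$end[o]
  run_max_end <- stats::ave(e, ch, FUN = cummax)
  new_grp <- c(TRUE, ch[-1] != ch[-n] | s[-1] > run_max_end[-n])
  grp <- cumsum(new_grp)
  data.frame(chrom = ch[new_grp],
             start = as.integer(s[new_grp]),
             end = as.integer(tapply(e, grp, max)),
             stringsAsFactors = FALSE)
}

# All pairwise overlaps between two interval tables; returns index pairs and
# the overlap width in bp. Strand is ignored. For each chromosome, b is
# sorted by start; candidates for a query are the contiguous window between
# the first b whose running-max end exceeds the query start and the last b
# whose start precedes the query end, then exact widths filter the window.
interval_overlaps <- function(a, b) {
  empty <- data.frame(a_idx = integer(), b_idx = integer(),
                      overlap = integer())
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  out_a <- list(); out_b <- list(); out_ov <- list(); piece <- 0L
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    ob <- bi[order(b$start[bi], b$end[bi])]
    bs <- as.numeric(b$start[ob])
    cme <- cummax(as.numeric(b$end[ob]))
    hi <- findInterval(a$end[ai] - 0.5, bs)       # b starts before query end
    lo <- findInterval(a$start[ai] + 0.5, cme) + 1L  # running end past start
    len <- pmax(0L, hi - lo + 1L)
    if (sum(len) == 0) next
    a_rep <- rep(ai, len)
    b_rep <- ob[sequence(len) + rep(lo - 1L, len)]
    ov <- pmin(a$end[a_rep], b$end[b_rep]) - pmax(a$start[a_rep],
                                                  b$start[b_rep])
    keep <- ov > 0
    piece <- piece + 1L
    out_a[[piece]] <- a_rep[keep]
    out_b[[piece]] <- b_rep[keep]
    out_ov[[piece]] <- as.integer(ov[keep])
  }
  if (piece == 0L) return(empty)
  data.frame(a_idx = unlist(out_a), b_idx = unlist(out_b),
             overlap = unlist(out_ov))
}
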