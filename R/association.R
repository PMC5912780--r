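# Rank-based association statistics and the feature-vs-efficiency analyses:
# Spearman correlations per stage/feature, Mann-Whitney GC comparison,
# Fisher's exact tests on expression-category contingency tables.

association_result <- function(feature_name = NA_character_,
                               stage_or_timepoint = NA_character_,
                               statistic_name, statistic, n, p_value) {
  data.frame(feature = feature_name, stage = stage_or_timepoint,
             statistic_name = statistic_name, statistic = statistic,
             n = as.integer(n), p_value = p_value,
             stringsAsFactors = FALSE)
}

#' Aggregate guide efficiencies to one value per gene
#'
#' @param records efficiency records (`gene_id`, `efficiency`).
#' @param method `"mean"` (default) or `"median"` over a gene's guides.
#' @return data.frame `gene_id`, `efficiency`; genes with only missing
#'   efficiencies are excluded with a message.
#' @export
aggregate_efficiency <- function(records, method = c("mean", "median")) {
  method <- match.arg(method)
  ok <- !is.na(records$efficiency)
  dropped <- setdiff(unique(records$gene_id), unique(records$gene_id[ok]))
  if (length(dropped))
    message(length(dropped),
            " gene(s) with no recorded efficiency excluded from aggregation")
  f <- if (method == "mean") mean else stats::median
  agg <- tapply(records$efficiency[ok], records$gene_id[ok], f)
  data.frame(gene_id = names(agg), efficiency = as.numeric(agg),
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rho is the Pearson correlation of average ranks (ties get average rank);
#' the two-sided p comes from `t = rho * sqrt((n-2) / (1-rho^2))` on `n - 2`
#' degrees of freedom, with `p = 0` at `rho = +/-1`. Pairs with missing
#' values are dropped first and the complete-case `n` is recorded. For
#' `exact = TRUE` and `n <= 8` the p-value is instead computed by full
#' permutation enumeration.
#'
#' @param x,y paired numeric vectors.
#' @param feature_name,stage labels carried into the result.
#' @param exact use the exact permutation p at small n.
#' @return one-row data.frame: `feature`, `stage`, `statistic_name`,
#'   `statistic` (rho), `n`, `p_value`.
#' @export
spearman_test <- function(x, y, feature_name = NA_character_,
                          stage = NA_character_, exact = FALSE) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("spearman: need >= 3 complete pairs, have ", n)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("spearman: zero variance in input; correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  # identical (or exactly reversed) rankings are rho = +/-1; snap float dust
  if (1 - abs(rho) < 1e-12) rho <- sign(rho)
  if (n < 10 && !exact)
    message("spearman: t-approximation used at n = ", n,
            " (small-sample caution)")
  if (exact && n <= 8) {
    obs <- abs(rho)
    perms <- permutations_of(n)
    rperm <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rperm) >= obs - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  association_result(feature_name, stage, "spearman_rho", rho, n, p)
}

# all permutations of 1..n as a matrix (n! rows); used for exact spearman p
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Mann-Whitney U test
#'
#' `U` counts pairs where a value of `a` exceeds a value of `b` (ties count
#' one half), so complete separation of `a` below `b` gives `U = 0`. For
#' `min(n_a, n_b) <= 8` without ties the two-sided p is exact (distribution
#' of U by enumeration); otherwise the tie-corrected normal approximation is
#' used, without continuity correction.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param feature_name,stage labels carried into the result.
#' @return one-row data.frame with `statistic` = U and a two-sided `p_value`.
#' @export
mann_whitney <- function(a, b, feature_name = NA_character_,
                         stage = NA_character_) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("mann_whitney: both groups must be non-empty")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && min(na, nb) <= 8) {
    p <- min(1, 2 * min(stats::pwilcox(U, na, nb),
                        stats::pwilcox(U - 1, na, nb, lower.tail = FALSE)))
  } else {
    mu <- na * nb / 2
    ntot <- na + nb
    tab <- table(r)
    sigma2 <- na * nb / 12 *
      ((ntot + 1) - sum(tab^3 - tab) / (ntot * (ntot - 1)))
    if (sigma2 <= 0) stop("mann_whitney: all values tied; test undefined")
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  association_result(feature_name, stage, "mann_whitney_U", U,
                     na + nb, p)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p as the sum of hypergeometric probabilities of all tables with
#' the observed margins whose probability does not exceed that of the
#' observed table (standard 1e-7 relative slack for float comparison). The
#' statistic is the sample odds ratio `(a*d)/(b*c)`; zero cells give `Inf`
#' or `0`, and a doubly degenerate ratio gives `NA`.
#'
#' @param counts 2x2 matrix (or length-4 vector, filled by row) of
#'   non-negative counts, rows = group (e.g. resistant/permissive),
#'   columns = category.
#' @param feature_name,stage labels carried into the result.
#' @return one-row data.frame with `statistic` = odds ratio and two-sided
#'   `p_value`.
#' @export
fisher_exact <- function(counts, feature_name = NA_character_,
                         stage = NA_character_) {
  m <- matrix(as.numeric(counts), nrow = 2, byrow = !is.matrix(counts))
  if (any(is.na(m)) || any(m < 0))
    stop("fisher_exact: counts must be non-negative")
  if (sum(m) == 0) stop("fisher_exact: empty table")
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- (a * d) / (b * c)
  association_result(feature_name, stage, "odds_ratio", or, sum(m), p)
}

#' Classify genes as low-expressed over the early-stage window
#'
#' A gene is `"low"` iff its RPKM is strictly below `low_threshold` at every
#' stage of the window (oblong-sphere through 15-somite by default, the
#' window bracketing the maternal-to-zygotic transition); a value exactly at
#' the threshold counts as expressed. Genes missing any window stage are
#' excluded with a message.
#'
#' @param features wide feature table with `rpkm_*` columns.
#' @param low_threshold RPKM limit for low expression (default 0.5).
#' @param window stages that must all be below threshold.
#' @return data.frame `gene_id`, `expression_class` (`"low"`/`"expressed"`).
#' @export
classify_expression <- function(features, low_threshold = 0.5,
                                window = c("oblong-sphere", "50%-epiboly",
                                           "15-somite")) {
  cols <- vapply(window, stage_column, character(1))
  miss_col <- setdiff(cols, names(features))
  if (length(miss_col))
    stop("feature table lacks stage column(s): ",
         paste(miss_col, collapse = ", "))
  vals <- as.matrix(features[, cols, drop = FALSE])
  complete <- stats::complete.cases(vals)
  if (any(!complete))
    message(sum(!complete), " gene(s) missing a window stage excluded ",
            "from expression classification")
  low <- rowSums(vals < low_threshold) == length(cols)
  data.frame(gene_id = features$gene_id[complete],
             expression_class = ifelse(low[complete], "low", "expressed"),
             stringsAsFactors = FALSE)
}

#' Classify the transcript change across the maternal-to-zygotic transition
#'
#' `"increased"` iff RPKM at 50%-epiboly strictly exceeds RPKM at
#' oblong-sphere; genes missing either value are excluded with a message.
#'
#' @param features wide feature table with the two stage columns.
#' @return data.frame `gene_id`, `mzt_class`
#'   (`"increased"`/`"not_increased"`).
#' @export
mzt_change <- function(features) {
  co <- stage_column("oblong-sphere")
  ce <- stage_column("50%-epiboly")
  if (!all(c(co, ce) %in% names(features)))
    stop("feature table lacks oblong-sphere / 50%-epiboly columns")
  ok <- !(is.na(features[[co]]) | is.na(features[[ce]]))
  if (any(!ok))
    message(sum(!ok), " gene(s) missing an MZT stage excluded")
  inc <- features[[ce]][ok] - features[[co]][ok] > 0
  data.frame(gene_id = features$gene_id[ok],
             mzt_class = ifelse(inc, "increased", "not_increased"),
             stringsAsFactors = FALSE)
}

#' Spearman correlations of every requested feature with efficiency
#'
#' One result row per (feature, stage) pair: each of the eight stage RPKMs
#' plus the chromatin features against the per-gene efficiency, each with its
#' own complete-case n and a significance flag at `alpha`.
#'
#' @param features feature table (with an `efficiency` column).
#' @param stages developmental stages whose RPKM columns to test.
#' @param chromatin named character vector mapping feature column ->
#'   timepoint label for the chromatin features to include (set `NULL` to
#'   test stages only).
#' @param alpha significance level for the flag (default 0.05).
#' @param exact passed to [spearman_test()].
#' @return data.frame of association rows with a logical `significant`
#'   column.
#' @export
correlate_all <- function(features, stages = DEV_STAGES,
                          chromatin = c(atac_coefficient = "4hpf",
                                        methylation_coefficient = "1-cell",
                                        promoter_score = "75-80%-epiboly"),
                          alpha = 0.05, exact = FALSE) {
  if (!"efficiency" %in% names(features))
    stop("feature table lacks an 'efficiency' column")
  rows <- list()
  for (s in stages) {
    col <- stage_column(s)
    if (!col %in% names(features)) next
    rows[[length(rows) + 1]] <-
      spearman_test(features[[col]], features$efficiency,
                    feature_name = "expression", stage = s, exact = exact)
  }
  for (f in names(chromatin)) {
    if (!f %in% names(features)) next
    rows[[length(rows) + 1]] <-
      spearman_test(features[[f]], features$efficiency,
                    feature_name = f, stage = unname(chromatin[f]),
                    exact = exact)
  }
  if (length(rows) == 0) stop("no testable feature columns found")
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Cross-tabulate two gene classifications into a 2x2 table
#'
#' @param class_a,class_b data.frames with `gene_id` and a class column
#'   (second column used); joined on `gene_id`.
#' @return 2x2 integer matrix (rows = levels of `class_a`'s column).
#' @export
contingency_table <- function(class_a, class_b) {
  j <- merge(class_a, class_b, by = "gene_id")
  tab <- table(j[[2]], j[[3]])
  if (!all(dim(tab) == c(2, 2))) {
    lv_a <- sort(unique(class_a[[2]])); lv_b <- sort(unique(class_b[[2]]))
    full <- matrix(0L, 2, 2, dimnames = list(lv_a[1:2], lv_b[1:2]))
    full[rownames(tab), colnames(tab)] <- tab
    tab <- full
  }
  as.matrix(tab)
}

#' GC-content comparison between functional and non-functional guides
#'
#' Mann-Whitney U test of protospacer GC percent for guides with detectable
#' in-vivo activity against those without.
#'
#' @param records efficiency records with `guide_sequence` and `functional`.
#' @return one-row association data.frame.
#' @export
gc_comparison <- function(records) {
  gc <- gc_content(records$guide_sequence)
  if (!any(records$functional) || all(records$functional))
    stop("gc_comparison: need both functional and non-functional guides")
  mann_whitney(gc[records$functional], gc[!records$functional],
               feature_name = "gc_content", stage = "guides")
}
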