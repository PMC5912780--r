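# Rank statistics and the association analyses.

test_that("spearman recovers perfect and reversed rankings", {
  x <- c(1, 3, 4, 8, 20)
  r1 <- spearman_test(x, x^3)        # monotone transform of x
  expect_equal(r1$statistic, 1)
  expect_equal(r1$p_value, 0)
  r2 <- spearman_test(x, -x)
  expect_equal(r2$statistic, -1)
  expect_equal(r2$p_value, 0)
})

test_that("spearman matches the classical formula and the rank-Pearson oracle", {
  set.seed(303)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
    r <- suppressMessages(spearman_test(x, y))
    expect_equal(r$statistic, oracle_spearman_noties(x, y), tolerance = 1e-12)
    # with ties the rank-Pearson definition applies
    xt <- round(stats::rnorm(n), 1)
    yt <- round(stats::rnorm(n), 1)
    if (stats::var(xt) > 0 && stats::var(yt) > 0) {
      rt <- suppressMessages(spearman_test(xt, yt))
      expect_equal(rt$statistic, oracle_spearman_ties(xt, yt),
                   tolerance = 1e-12)
      ct <- suppressWarnings(stats::cor.test(xt, yt, method = "spearman"))
      expect_equal(rt$statistic, unname(ct$estimate), tolerance = 1e-12)
    }
  }
})

test_that("spearman p agrees with cor.test's t-approximation", {
  set.seed(7)
  x <- stats::rnorm(30); y <- x + stats::rnorm(30)
  r <- spearman_test(x, y)
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-10)
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(11)
  x <- stats::rexp(25); y <- stats::rnorm(25)
  base <- spearman_test(x, y)
  expect_equal(spearman_test(log(x), y)$statistic, base$statistic)
  expect_equal(spearman_test(x, exp(y))$statistic, base$statistic)
})

test_that("spearman guards its preconditions and records complete-case n", {
  expect_error(spearman_test(1:2, 2:1), ">= 3")
  expect_error(spearman_test(rep(1, 5), 1:5), "zero variance")
  x <- c(1, 2, 3, NA, 5); y <- c(2, 1, 5, 4, NA)
  r <- suppressMessages(spearman_test(x, y))
  expect_equal(r$n, 3)
})

test_that("exact permutation p equals the t path's target at small n", {
  set.seed(12)
  x <- stats::rnorm(6); y <- stats::rnorm(6)
  r <- spearman_test(x, y, exact = TRUE)
  ct <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-9)
})

test_that("mann_whitney U has the documented orientation and symmetry", {
  a <- c(1, 2, 3); b <- c(10, 20, 30, 40)
  expect_equal(mann_whitney(a, b)$statistic, 0)       # a entirely below b
  expect_equal(mann_whitney(b, a)$statistic, 12)      # n_a * n_b
  same <- c(1.5, 2.5, 9)
  expect_equal(mann_whitney(same, same)$statistic, length(same)^2 / 2)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("mann_whitney exact p matches labeling enumeration and wilcox.test", {
  set.seed(505)
  for (i in 1:20) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- stats::rnorm(na); b <- stats::rnorm(nb)
    r <- mann_whitney(a, b)
    expect_equal(r$p_value, oracle_mw_exact(a, b), tolerance = 1e-12)
    w <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(r$statistic, unname(w$statistic))
    expect_equal(r$p_value, w$p.value, tolerance = 1e-12)
  }
})

test_that("mann_whitney normal approximation handles ties", {
  a <- c(rep(1, 6), rep(2, 6), 3:8)
  b <- c(rep(1, 4), rep(2, 8), 2:7)
  r <- mann_whitney(a, b)
  w <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(r$statistic, unname(w$statistic))
  expect_equal(r$p_value, w$p.value, tolerance = 1e-10)
})

test_that("fisher_exact handles balanced and degenerate tables", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))$p_value, 1)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(fisher_exact(matrix(0, 2, 2)), "empty")
})

test_that("fisher_exact matches enumeration and stats::fisher.test", {
  set.seed(606)
  for (i in 1:40) {
    m <- matrix(sample(0:9, 4, replace = TRUE), 2)
    if (sum(m) == 0) next
    r <- fisher_exact(m)
    expect_equal(r$p_value, oracle_fisher(m), tolerance = 1e-12)
    expect_equal(r$p_value, stats::fisher.test(m)$p.value, tolerance = 1e-9)
    # invariance under transpose and under swapping both rows and columns
    expect_equal(fisher_exact(t(m))$p_value, r$p_value, tolerance = 1e-12)
    expect_equal(fisher_exact(m[2:1, 2:1])$p_value, r$p_value,
                 tolerance = 1e-12)
  }
})

test_that("aggregate_efficiency averages guides per gene", {
  rec <- data.frame(gene_id = c("a", "b", "b", "c"),
                    efficiency = c(40, 20, 60, NA),
                    stringsAsFactors = FALSE)
  expect_message(agg <- aggregate_efficiency(rec), "excluded")
  expect_equal(agg$efficiency[agg$gene_id == "a"], 40)
  expect_equal(agg$efficiency[agg$gene_id == "b"], 40)
  expect_false("c" %in% agg$gene_id)
  med <- suppressMessages(
    aggregate_efficiency(data.frame(gene_id = "b",
                                    efficiency = c(10, 20, 90)),
                         method = "median"))
  expect_equal(med$efficiency, 20)
})

test_that("low-expression classification uses strict < at every window stage", {
  ft <- data.frame(gene_id = c("g1", "g2", "g3"),
                   rpkm_oblong_sphere = c(0, 0.6, 0.5),
                   rpkm_50_epiboly = c(0, 0.1, 0.5),
                   rpkm_15_somite = c(0, 0.1, 0.5),
                   stringsAsFactors = FALSE)
  cl <- classify_expression(ft)
  expect_equal(cl$expression_class, c("low", "expressed", "expressed"))
})

test_that("MZT change requires a strictly positive increase", {
  ft <- data.frame(gene_id = c("g1", "g2", "g3"),
                   rpkm_oblong_sphere = c(1, 2, 1),
                   rpkm_50_epiboly = c(2, 1, 1),
                   stringsAsFactors = FALSE)
  mz <- mzt_change(ft)
  expect_equal(mz$mzt_class, c("increased", "not_increased", "not_increased"))
})

test_that("correlate_all reports per-pair complete-case n and flags alpha", {
  set.seed(21)
  n <- 60
  eff <- stats::runif(n, 0, 100)
  ft <- data.frame(gene_id = sprintf("g%02d", 1:n),
                   rpkm_36hpf = eff,                   # identical ranking
                   atac_coefficient = stats::rnorm(n),
                   efficiency = eff, stringsAsFactors = FALSE)
  ft$rpkm_36hpf[1:10] <- NA
  res <- suppressMessages(
    correlate_all(ft, stages = "36hpf",
                  chromatin = c(atac_coefficient = "4hpf")))
  expr_row <- res[res$feature == "expression", ]
  expect_equal(expr_row$statistic, 1)
  expect_true(expr_row$significant)
  expect_equal(expr_row$n, 50)                         # NA pairs dropped
  expect_equal(res$n[res$feature == "atac_coefficient"], 60)
})

test_that("contingency_table cross-tabulates joined gene classes", {
  a <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                  status = c("permissive", "permissive", "resistant",
                             "resistant"), stringsAsFactors = FALSE)
  b <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                  expression_class = c("expressed", "low", "expressed",
                                       "expressed"), stringsAsFactors = FALSE)
  tab <- contingency_table(a, b)
  expect_equal(as.vector(tab), c(1, 2, 1, 0))
})

test_that("gc_comparison tests functional vs non-functional guide GC", {
  set.seed(31)
  seqs <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
    character(1))
  rec <- data.frame(gene_id = sprintf("g%02d", 1:30), guide_sequence = seqs,
                    efficiency = stats::runif(30, 0, 100),
                    functional = rep(c(TRUE, FALSE), 15),
                    stringsAsFactors = FALSE)
  r <- gc_comparison(rec)
  expect_equal(r$statistic_name, "mann_whitney_U")
  expect_gte(r$p_value, 0)
  expect_error(gc_comparison(transform(rec, functional = TRUE)), "both")
})
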