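# End-to-end orchestration: read inputs, build units and the per-gene
# feature table, run every association analysis, and write the result bundle
# (feature table, association table, contingency report, manifest).

#' Assemble and validate a pipeline run configuration
#'
#' @param annotation path to the gene annotation (GFF3/GTF).
#' @param atac,meth paths to ATAC / methylation broadPeak files (optional).
#' @param expression,probes,efficiency paths to the TSV tables
#'   (`efficiency` required).
#' @param alias optional two-column identifier alias TSV.
#' @param chrom_sizes optional two-column chromosome-size TSV.
#' @param format annotation dialect, `"gff3"` or `"gtf"`.
#' @param cluster_gap,flank,low_rpkm,alpha,aggregation,meth_weight analysis
#'   parameters (defaults 500 nt, 1,000 nt, 0.5 RPKM, 0.05, mean, coverage).
#' @param stages stages whose expression is correlated with efficiency.
#' @param seed integer recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(annotation, efficiency, atac = NULL, meth = NULL,
                       expression = NULL, probes = NULL, alias = NULL,
                       chrom_sizes = NULL, format = "gff3",
                       cluster_gap = 500, flank = 1000, low_rpkm = 0.5,
                       alpha = 0.05, aggregation = "mean",
                       meth_weight = "coverage", stages = DEV_STAGES,
                       seed = 1L) {
  paths <- list(annotation = annotation, efficiency = efficiency,
                atac = atac, meth = meth, expression = expression,
                probes = probes, alias = alias, chrom_sizes = chrom_sizes)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p))
      stop("input '", nm, "' does not exist: ", p)
  }
  stopifnot(cluster_gap >= 0, flank > 0, low_rpkm >= 0,
            alpha > 0, alpha < 1,
            aggregation %in% c("mean", "median"),
            meth_weight %in% c("coverage", "signal"),
            format %in% c("gff3", "gtf"))
  structure(c(paths, list(format = format, cluster_gap = cluster_gap,
                          flank = flank, low_rpkm = low_rpkm, alpha = alpha,
                          aggregation = aggregation,
                          meth_weight = meth_weight, stages = stages,
                          seed = as.integer(seed))),
            class = "run_config")
}

count_warnings <- function(expr) {
  n <- 0L
  val <- withCallingHandlers(expr, warning = function(w) {
    n <<- n + 1L
    invokeRestart("muffleWarning")
  }, message = function(m) {
    n <<- n + 1L
    invokeRestart("muffleMessage")
  })
  list(value = val, n = n)
}

#' Run the full analysis pipeline
#'
#' Reads every configured input, builds the per-gene feature table, runs the
#' Spearman correlations per feature/stage, the expression-category Fisher
#' tests (low-expression window and MZT increase, split by
#' resistant/permissive genes), and the guide GC-content comparison, then
#' writes `feature_table.tsv`, `associations.tsv`, `contingency.tsv` and
#' `manifest.json` under `out_dir`. Deterministic given identical inputs.
#'
#' @param config `run_config`.
#' @param out_dir output directory (created).
#' @return invisibly, a list with `features`, `associations`, `contingency`,
#'   `gc_test`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nwarn <- 0L
  rd <- count_warnings(read_gene_annotation(config$annotation,
                                            format = config$format))
  nwarn <- nwarn + rd$n
  models <- rd$value
  alias <- if (!is.null(config$alias)) read_alias_map(config$alias)
  chrom_sizes <- if (!is.null(config$chrom_sizes)) {
    cs <- utils::read.delim(config$chrom_sizes, header = FALSE)
    stats::setNames(as.integer(cs[[2]]), as.character(cs[[1]]))
  }
  atac <- if (!is.null(config$atac)) read_peaks(config$atac)
  meth <- if (!is.null(config$meth)) read_peaks(config$meth)
  expression <- if (!is.null(config$expression))
    read_table(config$expression, "expression")
  probes <- if (!is.null(config$probes)) read_table(config$probes, "probes")
  efficiency <- read_table(config$efficiency, "efficiency")
  if (!is.null(atac) && !is.null(chrom_sizes)) {
    unknown <- setdiff(unique(atac$chrom), names(chrom_sizes))
    if (length(unknown))
      message(length(unknown), " peak chromosome(s) absent from the ",
              "annotation retained (they overlap nothing)")
  }

  ft <- count_warnings(build_feature_table(
    models = models, atac_peaks = atac, meth_peaks = meth, probes = probes,
    expression = expression, efficiency = efficiency,
    cluster_gap = config$cluster_gap, flank = config$flank,
    chrom_sizes = chrom_sizes, aggregation = config$aggregation,
    meth_weight = config$meth_weight, alias = alias))
  nwarn <- nwarn + ft$n
  features <- ft$value

  feature_cols <- intersect(
    c("atac_coefficient", "methylation_coefficient", "promoter_score"),
    names(features))
  joined <- !is.na(features$efficiency)
  any_feature <- Reduce(`|`, lapply(
    c(feature_cols, intersect(vapply(config$stages, stage_column,
                                     character(1)), names(features))),
    function(cl) !is.na(features[[cl]])), rep(FALSE, nrow(features)))
  if (!any(joined & any_feature))
    stop("empty join: no gene_id shared between the feature table ",
         "('gene_id') and the efficiency table ('gene_id'); ",
         "consider an alias map")

  chromatin <- c(atac_coefficient = "4hpf",
                 methylation_coefficient = "1-cell",
                 promoter_score = "75-80%-epiboly")[feature_cols]
  associations <- suppressMessages(
    correlate_all(features, stages = config$stages, chromatin = chromatin,
                  alpha = config$alpha))

  contingency <- NULL
  gc_test <- NULL
  if (!is.null(expression)) {
    permissive <- tapply(efficiency$functional,
                         apply_alias(efficiency$gene_id, alias), any)
    status <- data.frame(gene_id = names(permissive),
                         status = ifelse(permissive, "permissive",
                                         "resistant"),
                         stringsAsFactors = FALSE)
    rows <- list()
    cls <- suppressMessages(
      classify_expression(features, low_threshold = config$low_rpkm))
    tab1 <- contingency_table(status, cls)
    f1 <- fisher_exact(tab1, feature_name = "low_expression_window",
                       stage = "oblong-sphere..15-somite")
    rows[[1]] <- cbind(f1, a = tab1[1, 1], b = tab1[1, 2], c = tab1[2, 1],
                       d = tab1[2, 2])
    mzt <- suppressMessages(mzt_change(features))
    tab2 <- contingency_table(status, mzt)
    f2 <- fisher_exact(tab2, feature_name = "mzt_increase",
                       stage = "oblong-sphere->50%-epiboly")
    rows[[2]] <- cbind(f2, a = tab2[1, 1], b = tab2[1, 2], c = tab2[2, 1],
                       d = tab2[2, 2])
    contingency <- do.call(rbind, rows)
  }
  if (any(efficiency$functional) && !all(efficiency$functional))
    gc_test <- gc_comparison(efficiency)

  write_feature_table(features, file.path(out_dir, "feature_table.tsv"))
  write_association(associations, file.path(out_dir, "associations.tsv"))
  if (!is.null(contingency))
    write_association(contingency, file.path(out_dir, "contingency.tsv"))
  if (!is.null(gc_test))
    write_association(gc_test, file.path(out_dir, "gc_comparison.tsv"))

  inputs <- Filter(Negate(is.null),
                   config[c("annotation", "efficiency", "atac", "meth",
                            "expression", "probes", "alias", "chrom_sizes")])
  manifest <- list(
    tool = "crisprchrom",
    version = as.character(utils::packageVersion("crisprchrom")),
    seed = config$seed,
    parameters = config[c("cluster_gap", "flank", "low_rpkm", "alpha",
                          "aggregation", "meth_weight", "format")],
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    n_genes_annotation = length(unique(models$gene_id)),
    n_genes_feature_table = nrow(features),
    n_warnings = nwarn,
    analyses = stats::setNames(
      lapply(seq_len(nrow(associations)), function(i)
        list(feature = associations$feature[i],
             stage = associations$stage[i], n = associations$n[i])),
      paste(associations$feature, associations$stage, sep = ":")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(features = features, associations = associations,
                 contingency = contingency, gc_test = gc_test,
                 manifest = manifest))
}

#' Score a simulated bundle in memory and estimate the planted correlation
#'
#' Fast path used by replicate studies: builds units, computes gene-level
#' ATAC coefficients, aggregates guide efficiencies, and returns the
#' Spearman test of coefficient vs efficiency.
#'
#' @param bundle `sim_bundle` from [simulate_study()].
#' @return one-row association data.frame for the ATAC feature.
#' @export
estimate_atac_association <- function(bundle) {
  stopifnot(inherits(bundle, "sim_bundle"))
  units <- build_units(bundle$models,
                       cluster_gap = bundle$config$cluster_gap,
                       flank = bundle$config$flank,
                       chrom_sizes = bundle$chrom_sizes)
  atac <- gene_atac_coefficients(units, bundle$atac)
  eff <- suppressMessages(aggregate_efficiency(bundle$efficiency))
  j <- merge(atac, eff, by = "gene_id")
  spearman_test(j$atac_coefficient, j$efficiency,
                feature_name = "atac_coefficient", stage = "4hpf")
}
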