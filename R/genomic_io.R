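# Readers and writers for the standard input formats: GFF3/GTF annotation,
# broadPeak (BED6+3) peak calls, and the TSV tables (efficiency, expression,
# probes). Everything downstream operates on plain data.frames in 0-based
# half-open coordinates.

#' Developmental stages of the stage-wise expression table
#'
#' The eight early developmental stages carried by the expression input, from
#' 64-cell (pre-MBT) to 72 hours post fertilization.
#' @export
DEV_STAGES <- c("64-cell", "oblong-sphere", "50%-epiboly", "15-somite",
                "36hpf", "48hpf", "60hpf", "72hpf")

# Column name used for a stage's RPKM in the wide per-gene feature table.
stage_column <- function(stage) {
  paste0("rpkm_", gsub("_$", "", gsub("[^A-Za-z0-9]+", "_", stage)))
}

# Cheap structural pre-scan so malformed annotation lines are reported with
# their line number (rtracklayer's own errors are less specific).
check_gff_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9)) {
    lineno <- which(body)[which(nfield != 9)[1]]
    stop("malformed annotation record at line ", lineno,
         ": expected 9 tab-separated fields, found ", nfield[nfield != 9][1],
         call. = FALSE)
  }
  invisible(TRUE)
}

first_parent <- function(parent_list) {
  vapply(parent_list, function(p) if (length(p)) p[[1]] else NA_character_,
         character(1))
}

# Strip a GFF3 "gene:"/"transcript:" style prefix if present (Ensembl dumps).
strip_id_prefix <- function(x) sub("^(gene|transcript|mRNA):", "", x)

#' Read a gene annotation into an exon-level gene-model table
#'
#' Parses a GFF3 or GTF file via rtracklayer, resolves the
#' gene/transcript/exon hierarchy, and returns one row per exon with
#' coordinates converted from the format's 1-based inclusive convention to
#' the internal 0-based half-open convention. Genes with no exons are dropped
#' with a warning; exons whose parent transcript cannot be resolved are
#' skipped with a warning.
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"gtf"`.
#' @return A `data.frame` with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`, one row per exon, ordered by
#'   `(gene_id, transcript_id, start)`.
#' @export
read_gene_annotation <- function(path, format = c("gff3", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  check_gff_lines(path)
  gr <- rtracklayer::import(path, format = format)
  type <- as.character(gr$type)
  ex <- gr[type == "exon"]
  if (format == "gff3") {
    tx <- gr[type %in% c("mRNA", "transcript")]
    tx_id <- strip_id_prefix(as.character(tx$ID))
    tx_gene <- strip_id_prefix(first_parent(tx$Parent))
    ex_tx <- strip_id_prefix(first_parent(ex$Parent))
    orphan <- is.na(ex_tx) | !(ex_tx %in% tx_id)
    if (any(orphan)) {
      warning(sum(orphan), " exon(s) with no resolvable parent transcript ",
              "skipped", call. = FALSE)
      ex <- ex[!orphan]
      ex_tx <- ex_tx[!orphan]
    }
    gene_of_tx <- stats::setNames(tx_gene, tx_id)
    gene_id <- unname(gene_of_tx[ex_tx])
    transcript_id <- ex_tx
  } else {
    gene_id <- as.character(ex$gene_id)
    transcript_id <- as.character(ex$transcript_id)
    orphan <- is.na(gene_id) | is.na(transcript_id)
    if (any(orphan)) {
      warning(sum(orphan), " exon(s) lacking gene_id/transcript_id skipped",
              call. = FALSE)
      ex <- ex[!orphan]
      gene_id <- gene_id[!orphan]
      transcript_id <- transcript_id[!orphan]
    }
  }
  models <- data.frame(
    gene_id = gene_id,
    transcript_id = transcript_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L,   # 1-based incl -> 0-based half-open
    end = GenomicRanges::end(ex),
    stringsAsFactors = FALSE)
  models$strand[models$strand == "*"] <- "."
  # report annotated genes that carry no exons at all
  if (format == "gff3") {
    all_genes <- strip_id_prefix(as.character(gr$ID[type == "gene"]))
    lost <- setdiff(all_genes[!is.na(all_genes)], models$gene_id)
    if (length(lost))
      warning(length(lost), " gene(s) without exons dropped: ",
              paste(utils::head(lost, 5), collapse = ", "), call. = FALSE)
  }
  validate_gene_models(models)
}

#' Validate an exon-level gene-model table
#'
#' Checks the gene-model invariants: valid exon intervals, a single chromosome
#' per gene, and non-overlapping exons within each transcript.
#'
#' @param models exon-level data.frame as returned by [read_gene_annotation()].
#' @return The table, ordered by `(gene_id, transcript_id, start)`, invisibly
#'   usable downstream.
#' @export
validate_gene_models <- function(models) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(models))
  if (length(miss)) stop("gene models missing column(s): ",
                         paste(miss, collapse = ", "))
  validate_intervals(models, what = "exon")
  nchrom <- tapply(models$chrom, models$gene_id,
                   function(x) length(unique(x)))
  if (any(nchrom > 1))
    stop("gene(s) spanning multiple chromosomes: ",
         paste(utils::head(names(nchrom)[nchrom > 1], 5), collapse = ", "))
  models <- models[order(models$gene_id, models$transcript_id, models$start), ,
                   drop = FALSE]
  rownames(models) <- NULL
  by_tx <- paste(models$gene_id, models$transcript_id, sep = "\r")
  n <- nrow(models)
  if (n > 1) {
    same_tx <- by_tx[-1] == by_tx[-n]
    overlap <- models$start[-1] < models$end[-n]
    if (any(same_tx & overlap))
      stop("overlapping exons within transcript ",
           models$transcript_id[which(same_tx & overlap)[1] + 1])
  }
  models
}

#' Read peak calls from a broadPeak (BED6+3) file
#'
#' Whitespace-delimited with at least 7 columns; column 7 is the signal value.
#' Intervals are 0-based half-open as in BED. Output is sorted by
#' `(chrom, start, end)`.
#'
#' @param path broadPeak file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal_value`, `p_value`, `q_value`.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = integer(),
                      strand = character(), signal_value = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#", colClasses = "character")
  if (nrow(raw) == 0) return(empty)
  if (ncol(raw) < 7)
    stop("broadPeak format error: need >= 7 columns, found ", ncol(raw))
  for (k in seq(ncol(raw) + 1, 9)) if (k <= 9 && k > ncol(raw)) raw[[k]] <- NA
  peaks <- data.frame(
    chrom = raw[[1]],
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    name = raw[[4]],
    score = as.integer(raw[[5]]),
    strand = raw[[6]],
    signal_value = as.numeric(raw[[7]]),
    p_value = suppressWarnings(as.numeric(raw[[8]])),
    q_value = suppressWarnings(as.numeric(raw[[9]])),
    stringsAsFactors = FALSE)
  if (any(is.na(peaks$start) | is.na(peaks$end)))
    stop("broadPeak format error: non-numeric coordinates")
  if (any(peaks$start < 0))
    stop("broadPeak format error: negative start position")
  validate_intervals(peaks[, c("chrom", "start", "end")], what = "peak")
  if (any(is.na(peaks$signal_value) | peaks$signal_value < 0))
    stop("broadPeak format error: signalValue (column 7) must be >= 0")
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Write peaks as broadPeak
#'
#' @param peaks peak data.frame as from [read_peaks()].
#' @param path output file.
#' @export
write_peaks <- function(peaks, path) {
  fmt <- function(x, digits6 = TRUE)
    ifelse(is.na(x), "-1", sprintf("%.6g", x))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%s",
                   peaks$chrom, peaks$start, peaks$end, peaks$name,
                   peaks$score, peaks$strand, fmt(peaks$signal_value),
                   fmt(peaks$p_value), fmt(peaks$q_value))
  writeLines(lines, path)
  invisible(path)
}

table_schemas <- list(
  efficiency = c("gene_id", "guide_sequence", "efficiency", "functional"),
  expression = c("gene_id", "stage", "rpkm"),
  probes = c("gene_id", "probe_id", "array_id", "median_intensity")
)

#' Read a typed TSV table (efficiency, expression, or probes)
#'
#' Validates every row against the schema's invariants and fails with
#' row-numbered messages when a row violates them.
#'
#' @param path TSV file with a header.
#' @param schema one of `"efficiency"`, `"expression"`, `"probes"`.
#' @return data.frame of validated records.
#' @export
read_table <- function(path, schema = c("efficiency", "expression", "probes")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- table_schemas[[schema]]
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "))
  df <- df[, need, drop = FALSE]
  bad <- switch(schema,
    efficiency = {
      df$efficiency <- suppressWarnings(as.numeric(df$efficiency))
      df$functional <- as.logical(df$functional)
      df$guide_sequence <- toupper(df$guide_sequence)
      (!is.na(df$efficiency) & (df$efficiency < 0 | df$efficiency > 100)) |
        nchar(df$guide_sequence) != 20L |
        grepl("[^ACGT]", df$guide_sequence) |
        is.na(df$functional)
    },
    expression = {
      df$rpkm <- suppressWarnings(as.numeric(df$rpkm))
      !(df$stage %in% DEV_STAGES) | is.na(df$rpkm) | df$rpkm < 0
    },
    probes = {
      df$median_intensity <- suppressWarnings(as.numeric(df$median_intensity))
      is.na(df$median_intensity) | df$median_intensity <= 0
    })
  if (any(bad))
    stop("validation error in ", basename(path), " (schema '", schema,
         "'): invalid row(s) ",
         paste(utils::head(which(bad), 10), collapse = ", "))
  df
}

#' Read a two-column gene-identifier alias map
#'
#' Translates identifiers used by efficiency/expression tables into the
#' annotation's `gene_id` vocabulary before joining.
#'
#' @param path TSV with columns `from`, `to`.
#' @return named character vector mapping `from` to `to`.
#' @export
read_alias_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(df)))
    stop("alias map needs columns 'from' and 'to'")
  stats::setNames(df$to, df$from)
}

#' Apply an alias map to gene identifiers
#'
#' @param ids character vector of identifiers.
#' @param alias named vector from [read_alias_map()], or `NULL` (identity).
#' @return translated identifiers; ids absent from the map pass through.
#' @export
apply_alias <- function(ids, alias = NULL) {
  if (is.null(alias)) return(ids)
  hit <- ids %in% names(alias)
  ids[hit] <- unname(alias[ids[hit]])
  ids
}

fmt6 <- function(x) {
  out <- rep("NA", length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.6g", x[ok])
  out
}

write_tsv_formatted <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) fmt6(col) else as.character(col)
  })
  body <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(paste(names(df), collapse = "\t"), body), path)
  invisible(path)
}

#' Write the per-gene feature table as TSV
#'
#' Deterministic column order, gene-sorted rows, floats rendered with 6
#' significant digits; two writes of the same table are byte-identical.
#'
#' @param features feature table (see [build_feature_table()]).
#' @param path output TSV.
#' @export
write_feature_table <- function(features, path) {
  features <- features[order(features$gene_id), , drop = FALSE]
  lead <- intersect(c("gene_id", "atac_coefficient", "methylation_coefficient",
                      "promoter_score",
                      vapply(DEV_STAGES, stage_column, character(1)),
                      "efficiency"), names(features))
  features <- features[, c(lead, setdiff(names(features), lead)), drop = FALSE]
  write_tsv_formatted(features, path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path TSV path.
#' @return data.frame with numeric feature columns.
#' @export
read_feature_table <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write association results as TSV
#'
#' @param results data.frame of association results (one row per test).
#' @param path output TSV.
#' @export
write_association <- function(results, path) {
  write_tsv_formatted(results, path)
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_annotation()]: internal 0-based half-open exons are
#' rendered as 1-based inclusive GFF3 gene/mRNA/exon records.
#'
#' @param models exon-level gene-model table.
#' @param path output file.
#' @param chrom_sizes optional named vector of chromosome lengths for
#'   `##sequence-region` headers.
#' @export
write_gff3 <- function(models, path, chrom_sizes = NULL) {
  models <- validate_gene_models(models)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(chrom_sizes))
    writeLines(sprintf("##sequence-region %s 1 %d", names(chrom_sizes),
                       as.integer(chrom_sizes)), con)
  out <- character(0)
  for (g in unique(models$gene_id)) {
    rows <- models[models$gene_id == g, , drop = FALSE]
    out <- c(out, sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                          rows$chrom[1], min(rows$start) + 1L, max(rows$end),
                          rows$strand[1], g))
    for (t in unique(rows$transcript_id)) {
      ex <- rows[rows$transcript_id == t, , drop = FALSE]
      out <- c(out,
               sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       ex$chrom[1], min(ex$start) + 1L, max(ex$end),
                       ex$strand[1], t, g),
               sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                       ex$chrom, ex$start + 1L, ex$end, ex$strand, t,
                       seq_len(nrow(ex)), t))
    }
  }
  writeLines(out, con)
  invisible(path)
}
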