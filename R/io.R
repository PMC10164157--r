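# Plain-text I/O (guide libraries, count tables, sample sheets, FASTQ
# emission) and the end-to-end pipeline.

#' Read a guide library table from delimited text
#'
#' Expects a header with columns `guide_id`, `nuclease`, `spacer`, `gene`,
#' `gene_class`, `position` (optional: `rank`, `pam_context`). Row-level
#' problems (bad nuclease token, non-DNA spacer, wrong spacer length,
#' NHT/class inconsistency) are collected and reported together with their
#' row numbers.
#'
#' @param path file path.
#' @param sep field separator (default tab; use "," for CSV).
#' @return validated guide data.frame ready for [build_library()].
#' @export
read_guide_library <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = TRUE)
  required <- c("guide_id", "nuclease", "spacer", "gene", "gene_class",
                "position")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("guide library is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"rank" %in% names(df)) df$rank <- NA_integer_
  if (!"pam_context" %in% names(df)) df$pam_context <- NA_character_
  df$spacer <- toupper(trimws(as.character(df$spacer)))
  df$nuclease <- trimws(as.character(df$nuclease))
  df$gene_class <- trimws(as.character(df$gene_class))
  errs <- character(0)
  row_err <- function(rows, what) {
    if (any(rows))
      errs <<- c(errs, paste0(what, " at row(s) ",
                              paste(which(rows), collapse = ", ")))
  }
  row_err(!(df$nuclease %in% names(SPACER_LEN)), "bad nuclease token")
  bad_dna <- !grepl("^[ACGT]+$", df$spacer)
  row_err(bad_dna, "non-DNA spacer")
  ok_nuc <- df$nuclease %in% names(SPACER_LEN)
  bad_len <- ok_nuc & !bad_dna &
    nchar(df$spacer) != unname(SPACER_LEN[df$nuclease])
  row_err(bad_len, "spacer length inconsistent with nuclease")
  row_err(!(df$gene_class %in% GENE_CLASSES), "unknown gene_class")
  row_err(xor(df$gene == "NHT", df$gene_class == "NHT"),
          "gene/NHT class inconsistency")
  row_err(!(df$position %in% c(1L, 2L)), "position must be 1 or 2")
  if (length(errs))
    stop("invalid guide library: ", paste(errs, collapse = "; "))
  df$position <- as.integer(df$position)
  df
}

#' Write / read a combination count table as delimited text
#'
#' The table has leading columns `combo_id`, `guide_a`, `guide_b`, then one
#' column of integer counts per sample. Sample roles live in a separate
#' sample sheet ([write_sample_sheet()]); the count table read back can be
#' re-annotated with genes and pair classes via [annotate_combinations()].
#'
#' @param counts a `count_table`.
#' @param path output file path (tab-separated).
#' @export
write_count_table <- function(counts, path) {
  stopifnot(inherits(counts, "count_table"))
  df <- cbind(counts$combinations[, c("combo_id", "guide_a", "guide_b")],
              as.data.frame(counts$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @param sample_sheet data.frame with `sample_id`, `role`, `replicate` (or
#'   a path readable by [read_sample_sheet()]). Covers externally supplied
#'   tables in the same schema after column mapping.
#' @return `read_count_table()` returns a `count_table` (combinations
#'   unannotated until [annotate_combinations()] is applied).
#' @export
read_count_table <- function(path, sample_sheet) {
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  stopifnot(all(c("sample_id", "role", "replicate") %in% names(sample_sheet)))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE)
  lead <- c("combo_id", "guide_a", "guide_b")
  if (!all(lead %in% names(df)))
    stop("count table must have columns combo_id, guide_a, guide_b")
  sample_cols <- setdiff(names(df), lead)
  missing <- setdiff(sample_sheet$sample_id, sample_cols)
  if (length(missing))
    stop("sample sheet names absent from count table: ",
         paste(missing, collapse = ", "))
  combos <- df[, lead]
  m <- as.matrix(df[, sample_sheet$sample_id, drop = FALSE])
  count_table(m, combos, as.data.frame(sample_sheet))
}

#' Write / read a sample sheet
#'
#' @param samples data.frame with `sample_id`, `role`
#'   (`library_reference`/`screen_end`), `replicate`.
#' @param path file path (tab-separated).
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "role", "replicate") %in% names(df)),
            all(df$role %in% c("library_reference", "screen_end")))
  df$replicate <- as.integer(df$replicate)
  df
}

#' Annotate a count table's combinations from a library
#'
#' Attaches genes, gene classes and the pair class to each combination of an
#' externally read count table, matching on the `(guide_a, guide_b)` ids.
#'
#' @param counts a `count_table`.
#' @param library a `combi_library`.
#' @return the `count_table` with fully annotated combinations.
#' @export
annotate_combinations <- function(counts, library) {
  stopifnot(inherits(counts, "count_table"), inherits(library, "combi_library"))
  idx <- match(paste(counts$combinations$guide_a, counts$combinations$guide_b,
                     sep = "|"),
               library$combinations$combo_id)
  if (anyNA(idx))
    stop(sum(is.na(idx)), " combination(s) not present in the library")
  counts$combinations <- library$combinations[idx, , drop = FALSE]
  rownames(counts$combinations) <- NULL
  rownames(counts$counts) <- counts$combinations$combo_id
  counts
}

#' Write paired reads as FASTQ
#'
#' @param reads character vector of read sequences.
#' @param path output path (`.fastq`; plain text).
#' @param prefix read-name prefix.
#' @export
write_fastq <- function(reads, path, prefix = "read") {
  qual <- strrep("I", nchar(reads))
  lines <- as.vector(rbind(sprintf("@%s_%d", prefix, seq_along(reads)),
                           reads, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full screen-analysis pipeline
#'
#' Executes QC, normalization, guide and gene-pair LFC computation, screen
#' metrics (effect-size ranges, class separations, replicate correlations)
#' and, when a gold standard is supplied, the ROC evaluation. Inputs can be
#' in-memory objects or file paths; when `output_dir` is given, every table
#' plus a structured metrics report and the effective configuration are
#' written as plain text. The pipeline is deterministic: identical inputs
#' and options give identical outputs.
#'
#' @param library a `combi_library`, or a guide-library file path (then
#'   `design` must name the construct).
#' @param counts a `count_table`, or a count-table path (then
#'   `sample_sheet` is required).
#' @param design design name, used when `library` is a path.
#' @param sample_sheet sample sheet (data.frame or path) for count paths.
#' @param reference sample_id of the library reference; default the sample
#'   with role `library_reference`.
#' @param gold optional `gold_standard`; defaults to the declared sets with
#'   negatives derived from the library when its genes cover them.
#' @param pseudocount,aggregate passed to [guide_lfc()].
#' @param roc_unit passed to [evaluate_screen()].
#' @param ts_genes TS subset for class separations.
#' @param output_dir optional directory for the written report bundle.
#' @return list with `qc`, `normalized`, `lfc`, `gene_pairs`, `metrics`
#'   (ranges, class summary, replicate correlations) and `evaluation`.
#' @export
run_pipeline <- function(library, counts, design = "SpCas9",
                         sample_sheet = NULL, reference = NULL,
                         gold = NULL, pseudocount = 0.5,
                         aggregate = c("mean", "median", "pooled"),
                         roc_unit = c("guide_pairs", "all_pairs", "nht_single"),
                         ts_genes = c("TP53", "NF2"),
                         output_dir = NULL) {
  aggregate <- match.arg(aggregate)
  roc_unit <- match.arg(roc_unit)
  if (is.character(library))
    library <- build_library(read_guide_library(library), design)
  if (is.character(counts)) {
    if (is.null(sample_sheet))
      stop("a sample sheet is required when counts are read from a file")
    counts <- read_count_table(counts, sample_sheet)
  }
  if (!"pair_class" %in% names(counts$combinations))
    counts <- annotate_combinations(counts, library)
  if (is.null(reference)) {
    refs <- counts$samples$sample_id[counts$samples$role == "library_reference"]
    if (length(refs) != 1L)
      stop("specify 'reference': found ", length(refs),
           " library_reference sample(s)")
    reference <- refs
  } else if (!reference %in% counts$samples$sample_id) {
    stop("reference sample '", reference, "' not present")
  }
  qc <- qc_report(counts)
  normalized <- normalize_counts(counts)
  lfc <- guide_lfc(normalized, reference, pseudocount = pseudocount,
                   aggregate = aggregate)
  gene_pairs <- gene_pair_lfc(lfc)
  n_end <- sum(counts$samples$role == "screen_end")
  metrics <- list(
    range_guide = effect_size_range(lfc),
    range_gene = effect_size_range(gene_pairs),
    class_summary_guide = class_summary(lfc, "target", ts_genes),
    class_summary_gene = class_summary(gene_pairs, "target", ts_genes),
    replicate_correlations = if (n_end >= 2L)
      replicate_correlations(normalized, reference, pseudocount) else NULL
  )
  if (is.null(gold)) {
    genes <- setdiff(unique(library$guides$gene), "NHT")
    if (all(c(GOLD_CE_DEFAULT, GOLD_TS_DEFAULT) %in% genes))
      gold <- gold_standard(library = library)
  }
  evaluation <- if (!is.null(gold)) evaluate_screen(lfc, gold, roc_unit)
  result <- list(qc = qc, normalized = normalized, lfc = lfc,
                 gene_pairs = gene_pairs, metrics = metrics,
                 evaluation = evaluation)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) utils::write.table(
      df, file.path(output_dir, name), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(qc, "qc_report.tsv")
    wt(as.data.frame(lfc), "guide_lfc.tsv")
    wt(as.data.frame(gene_pairs), "gene_pair_lfc.tsv")
    report <- c(
      sprintf("range_guide\t%.10g", metrics$range_guide),
      sprintf("range_gene\t%.10g", metrics$range_gene),
      sprintf("pseudocount\t%g", pseudocount),
      sprintf("replicate_aggregation\t%s", aggregate),
      sprintf("reference_sample\t%s", reference),
      sprintf("roc_unit\t%s", roc_unit),
      if (!is.null(evaluation)) sprintf("auc_ce\t%.10g", evaluation$auc_ce),
      if (!is.null(evaluation)) sprintf("auc_ts\t%.10g", evaluation$auc_ts)
    )
    writeLines(report, file.path(output_dir, "metrics_report.tsv"))
  }
  result
}
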