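# Normalization, LFC computation, gene-pair aggregation, effect-size-range
# and class-separation statistics, single-guide decomposition, correlations.

#' Normalize counts to total depth and the NHT-NHT median
#'
#' Per sample, each count is divided by the sample total and then by the
#' median of the total-normalized values of all NHT-NHT combinations (the
#' neutral baseline), and finally multiplied by `scale`. After normalization
#' the median NHT-NHT value of every sample equals `scale` exactly, so the
#' operation is idempotent on its own output.
#'
#' @param counts a `count_table` (or `normalized_table`) whose combinations
#'   carry a `pair_class` column.
#' @param scale positive multiplier applied after normalization (default 1).
#' @return a `normalized_table`: same shape, real-valued `values`, plus a
#'   `normalization` record (per-sample total, NHT-NHT median, scale).
#' @export
normalize_counts <- function(counts, scale = 1) {
  stopifnot(inherits(counts, c("count_table", "normalized_table")), scale > 0)
  m <- if (inherits(counts, "normalized_table")) counts$values else counts$counts
  combos <- counts$combinations
  if (!"pair_class" %in% names(combos))
    stop("combinations lack pair_class annotation; see annotate_combinations()")
  nht <- combos$pair_class == "NHT-NHT"
  if (!any(nht)) stop("no NHT-NHT combinations present; cannot normalize")
  values <- m
  rec <- data.frame(sample_id = counts$samples$sample_id,
                    total = NA_real_, nht_median = NA_real_, scale = scale,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) {
    tot <- sum(m[, j])
    if (tot == 0) stop("sample '", counts$samples$sample_id[j], "' has zero total count")
    v <- m[, j] / tot
    med <- median(v[nht])
    if (med == 0)
      stop("NHT-NHT median is zero in sample '", counts$samples$sample_id[j], "'")
    values[, j] <- v / med * scale
    rec$total[j] <- tot
    rec$nht_median[j] <- med
  }
  structure(list(values = values, combinations = combos,
                 samples = counts$samples, normalization = rec),
            class = "normalized_table")
}

#' @export
print.normalized_table <- function(x, ...) {
  cat("Normalized table: ", nrow(x$values), " combinations x ",
      ncol(x$values), " sample(s); NHT-NHT median scaled to ",
      x$normalization$scale[1], "\n", sep = "")
  invisible(x)
}

#' Guide-pair log2 fold changes (end vs. library reference)
#'
#' LFC = log2((end + pc) / (reference + pc)) on normalized values, where the
#' pseudocount `pc` is applied to a pair only when one of its two values is
#' zero (nonzero data stay untouched). With several end replicates the
#' per-replicate LFCs are combined by the configured aggregator: `"mean"`
#' (default, arithmetic mean of log-ratios), `"median"`, or `"pooled"`
#' (average the replicate normalized values first, then one log-ratio).
#'
#' @param normalized a `normalized_table`.
#' @param reference sample_id of the library reference.
#' @param end sample_id(s) of the end-timepoint replicates; default all
#'   samples with role `"screen_end"`.
#' @param pseudocount nonnegative; must be positive if any compared value is
#'   zero.
#' @param aggregate replicate aggregation mode.
#' @return an `lfc_table`: data.frame with combination annotation and `lfc`,
#'   carrying provenance attributes (`reference`, `end`, `pseudocount`,
#'   `aggregate`).
#' @export
guide_lfc <- function(normalized, reference, end = NULL, pseudocount = 0.5,
                      aggregate = c("mean", "median", "pooled")) {
  stopifnot(inherits(normalized, "normalized_table"), pseudocount >= 0)
  aggregate <- match.arg(aggregate)
  ids <- normalized$samples$sample_id
  if (is.null(end))
    end <- ids[normalized$samples$role == "screen_end"]
  missing <- setdiff(c(reference, end), ids)
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  if (length(end) == 0L) stop("no end-timepoint samples")
  ref <- normalized$values[, reference]
  E <- normalized$values[, end, drop = FALSE]
  if (pseudocount == 0 && (any(ref == 0) || any(E == 0)))
    stop("zero values present: a positive pseudocount is required")
  lfc_one <- function(e) {
    pc <- ifelse(e == 0 | ref == 0, pseudocount, 0)
    log2((e + pc) / (ref + pc))
  }
  if (aggregate == "pooled") {
    lfc <- lfc_one(rowMeans(E))
  } else {
    per_rep <- vapply(seq_len(ncol(E)), function(j) lfc_one(E[, j]),
                      numeric(nrow(E)))
    per_rep <- matrix(per_rep, nrow = nrow(E))
    lfc <- if (aggregate == "mean") rowMeans(per_rep)
           else apply(per_rep, 1, median)
  }
  out <- cbind(normalized$combinations, lfc = lfc)
  rownames(out) <- NULL
  structure(out, class = c("lfc_table", "data.frame"),
            reference = reference, end = end,
            pseudocount = pseudocount, aggregate = aggregate)
}

# Collapse NHT guides to one pseudo-gene so that NHT-gene pairs aggregate
# across all NHT partners.
.gene_label <- function(gene, class) ifelse(class == "NHT", "NHT", gene)

#' Median-aggregated gene-pair log2 fold changes
#'
#' Aggregates guide-level LFCs to ordered gene pairs by the median over all
#' contributing guide pairs (16 for a complete 4 x 4 library). All NHT guides
#' collapse to the single pseudo-gene `"NHT"`.
#'
#' @param lfc an `lfc_table`.
#' @return a `gene_pair_table`: data.frame with `gene_a`, `gene_b`,
#'   `class_a`, `class_b`, `pair_class`, median `lfc`, and the number of
#'   contributing guide pairs `n`.
#' @export
gene_pair_lfc <- function(lfc) {
  stopifnot(inherits(lfc, "lfc_table"))
  ga <- .gene_label(lfc$gene_a, lfc$class_a)
  gb <- .gene_label(lfc$gene_b, lfc$class_b)
  key <- paste(ga, gb, sep = "|")
  idx <- !duplicated(key)
  out <- data.frame(gene_a = ga[idx], gene_b = gb[idx],
                    class_a = lfc$class_a[idx], class_b = lfc$class_b[idx],
                    pair_class = lfc$pair_class[idx],
                    stringsAsFactors = FALSE)
  med <- tapply(lfc$lfc, key, median)
  n <- tapply(lfc$lfc, key, length)
  out$lfc <- as.numeric(med[paste(out$gene_a, out$gene_b, sep = "|")])
  out$n <- as.integer(n[paste(out$gene_a, out$gene_b, sep = "|")])
  rownames(out) <- NULL
  structure(out, class = c("gene_pair_table", "data.frame"))
}

#' Effect size range of a screen
#'
#' Difference between the highest and the lowest LFC value — a one-number
#' summary of how far apart fitness-increasing and fitness-decreasing guide
#' (or gene) pairs are driven.
#'
#' @param values numeric vector, or an `lfc_table`/`gene_pair_table` (its
#'   `lfc` column is used).
#' @return nonnegative scalar `max - min`.
#' @export
#' @examples
#' effect_size_range(c(-4, 0, 3))
effect_size_range <- function(values) {
  if (is.data.frame(values)) values <- values$lfc
  if (length(values) == 0L) stop("empty value vector")
  if (!all(is.finite(values))) stop("non-finite LFC value(s)")
  max(values) - min(values)
}

#' Per-class LFC summaries
#'
#' Two grouping schemes: `"target"` reproduces the density-plot populations
#' (records involving at least one CE gene; records involving a restricted
#' TS gene set — default TP53 and NF2, the strong proliferation phenotypes —
#' and no CE gene; pure NHT-NHT records), and `"pair_class"` summarizes each
#' of the six pair-class labels.
#'
#' @param lfc an `lfc_table` or `gene_pair_table`.
#' @param scheme grouping scheme.
#' @param ts_genes TS gene subset used by the `"target"` scheme.
#' @return data.frame with `class`, `n`, `mean`, `median` (classes with no
#'   records are absent).
#' @export
class_summary <- function(lfc, scheme = c("target", "pair_class"),
                          ts_genes = c("TP53", "NF2")) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(lfc), "lfc" %in% names(lfc))
  if (scheme == "pair_class") {
    grp <- lfc$pair_class
  } else {
    has_ce <- lfc$class_a == "CE" | lfc$class_b == "CE"
    has_ts <- (lfc$gene_a %in% ts_genes) | (lfc$gene_b %in% ts_genes)
    grp <- rep(NA_character_, nrow(lfc))
    grp[lfc$pair_class == "NHT-NHT"] <- "NHT"
    grp[has_ts & !has_ce] <- "TS"
    grp[has_ce] <- "CE"
  }
  keep <- !is.na(grp)
  g <- grp[keep]
  v <- lfc$lfc[keep]
  out <- data.frame(
    class = sort(unique(g)),
    stringsAsFactors = FALSE
  )
  out$n <- as.integer(tapply(v, g, length)[out$class])
  out$mean <- as.numeric(tapply(v, g, mean)[out$class])
  out$median <- as.numeric(tapply(v, g, median)[out$class])
  out
}

#' Single-guide LFCs via NHT partners
#'
#' Decomposes the combinatorial screen into per-guide phenotypes: for each
#' non-NHT guide at the chosen position, the median LFC over all combinations
#' pairing it with an NHT partner in the other cassette (e.g. gRNA-NHT for
#' position 1, NHT-gRNA for position 2). The gene-level version aggregates
#' the per-guide medians by median per gene.
#'
#' @param lfc an `lfc_table`.
#' @param position cassette of the focal guide (1 or 2).
#' @param level `"guide"` or `"gene"`.
#' @return data.frame with `guide_id` (guide level), `gene`, `gene_class`,
#'   `lfc`, `n` (contributing NHT-partner pairs).
#' @export
single_guide_lfc <- function(lfc, position = 1L, level = c("guide", "gene")) {
  stopifnot(inherits(lfc, "lfc_table"), position %in% c(1L, 2L))
  level <- match.arg(level)
  if (position == 1L) {
    keep <- lfc$class_a != "NHT" & lfc$class_b == "NHT"
    guide <- lfc$guide_a[keep]; gene <- lfc$gene_a[keep]
    cls <- lfc$class_a[keep]
  } else {
    keep <- lfc$class_b != "NHT" & lfc$class_a == "NHT"
    guide <- lfc$guide_b[keep]; gene <- lfc$gene_b[keep]
    cls <- lfc$class_b[keep]
  }
  if (!any(keep)) stop("no NHT partners found for position ", position)
  v <- lfc$lfc[keep]
  idx <- !duplicated(guide)
  out <- data.frame(guide_id = guide[idx], gene = gene[idx],
                    gene_class = cls[idx], stringsAsFactors = FALSE)
  out$lfc <- as.numeric(tapply(v, guide, median)[out$guide_id])
  out$n <- as.integer(tapply(v, guide, length)[out$guide_id])
  if (level == "gene") {
    gidx <- !duplicated(out$gene)
    gout <- data.frame(gene = out$gene[gidx], gene_class = out$gene_class[gidx],
                       stringsAsFactors = FALSE)
    gout$lfc <- as.numeric(tapply(out$lfc, out$gene, median)[gout$gene])
    gout$n <- as.integer(tapply(out$n, out$gene, sum)[gout$gene])
    rownames(gout) <- NULL
    return(gout)
  }
  rownames(out) <- NULL
  out
}

#' Correlation between two paired metric vectors
#'
#' Pairs with a non-finite member are dropped (and counted); a zero-variance
#' vector yields a flagged `NA` rather than an error. For Pearson
#' correlations the least-squares slope and intercept of `y ~ x` are also
#' reported (the regression line drawn in cross-screen comparisons).
#'
#' @param x,y equal-length numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `method`, `n` (pairs used), `n_dropped`, and (for
#'   Pearson) `slope`, `intercept`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("fewer than 3 finite pairs")
  out <- list(r = NA_real_, method = method, n = length(x),
              n_dropped = n_dropped)
  if (var(x) == 0 || var(y) == 0) {
    attr(out, "undefined") <- TRUE
    return(out)
  }
  out$r <- cor(x, y, method = method)
  if (method == "pearson") {
    fit <- coef(lm(y ~ x))
    out$intercept <- unname(fit[1])
    out$slope <- unname(fit[2])
  }
  out
}

#' Replicate-concordance QC of a screen
#'
#' Pearson correlations between the two (or more) end-timepoint replicates on
#' guide counts and on per-replicate guide LFCs — the standard technical
#' reproducibility readouts of a dropout screen.
#'
#' @param normalized a `normalized_table` containing a library reference and
#'   at least two end replicates.
#' @param reference reference sample_id.
#' @param pseudocount passed to the per-replicate LFCs.
#' @return data.frame with `metric` (`guide_counts`, `guide_lfc`) and `r`
#'   (mean pairwise Pearson r over replicate pairs).
#' @export
replicate_correlations <- function(normalized, reference, pseudocount = 0.5) {
  ends <- normalized$samples$sample_id[normalized$samples$role == "screen_end"]
  if (length(ends) < 2L) stop("need at least two end replicates")
  pairs <- utils::combn(ends, 2, simplify = FALSE)
  mean_r <- function(get) {
    mean(vapply(pairs, function(p) correlate(get(p[1]), get(p[2]))$r, numeric(1)))
  }
  cnt <- function(s) normalized$values[, s]
  lfc1 <- function(s) guide_lfc(normalized, reference, end = s,
                                pseudocount = pseudocount)$lfc
  data.frame(metric = c("guide_counts", "guide_lfc"),
             r = c(mean_r(cnt), mean_r(lfc1)),
             stringsAsFactors = FALSE)
}
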