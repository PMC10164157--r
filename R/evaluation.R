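# Gold-standard construction and ROC/AUC benchmarking of essential-gene and
# tumor-suppressor recovery; cross-screen comparison.

GOLD_CE_DEFAULT <- c("CCT4", "EIF3B", "XPO1", "IARS", "EFTUD2", "NARS")
GOLD_TS_DEFAULT <- c("ARNT", "AHR", "KIRREL", "TP53", "NF2")

#' Declare a gold standard of positive and negative genes
#'
#' The defaults are the dependency-score-derived sets used for benchmarking
#' in RPE1 cells: six core-essential positives with strong negative Chronos
#' dependency scores, five tumor-suppressor positives with strong positive
#' scores, and the remaining nine library genes as negatives. NHT is never a
#' gold-standard member.
#'
#' @param ce_positive,ts_positive,negatives gene character vectors; the three
#'   sets must be pairwise disjoint.
#' @param library optional `combi_library`; when given and `negatives` is
#'   `NULL`, the negatives default to the library genes not in either
#'   positive set.
#' @param source free-text provenance of the sets.
#' @return an object of class `gold_standard`.
#' @export
gold_standard <- function(ce_positive = GOLD_CE_DEFAULT,
                          ts_positive = GOLD_TS_DEFAULT,
                          negatives = NULL, library = NULL,
                          source = "median Chronos dependency score, RPE1 (declared sets)") {
  if (is.null(negatives)) {
    if (is.null(library))
      stop("supply 'negatives' explicitly or a 'library' to derive them from")
    genes <- setdiff(unique(library$guides$gene), "NHT")
    negatives <- setdiff(genes, c(ce_positive, ts_positive))
  }
  sets <- list(ce_positive = unique(ce_positive),
               ts_positive = unique(ts_positive),
               negatives = unique(negatives))
  if (any(vapply(sets, function(s) "NHT" %in% s, logical(1))))
    stop("NHT cannot be a gold-standard class member")
  all_g <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_g))
    stop("gold-standard sets overlap: ",
         paste(unique(all_g[duplicated(all_g)]), collapse = ", "))
  structure(c(sets, list(source = source)), class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("Gold standard (", x$source, ")\n", sep = "")
  cat("  CE positives (n=", length(x$ce_positive), "): ",
      paste(x$ce_positive, collapse = ", "), "\n", sep = "")
  cat("  TS positives (n=", length(x$ts_positive), "): ",
      paste(x$ts_positive, collapse = ", "), "\n", sep = "")
  cat("  negatives   (n=", length(x$negatives), "): ",
      paste(x$negatives, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Derive a gold standard from dependency scores
#'
#' Genes at or below `ce_cut` (strong negative dependency, i.e. essential)
#' become CE positives; genes at or above `ts_cut` become TS positives; the
#' rest are negatives. `"NHT"` entries are never classified.
#'
#' @param dep_scores named numeric vector, gene -> dependency score (e.g.
#'   median Chronos score across RPE1 lines).
#' @param ce_cut,ts_cut thresholds with `ce_cut < ts_cut`.
#' @param source provenance string.
#' @return a `gold_standard`; an empty negative set is kept but flagged with
#'   a warning.
#' @export
#' @examples
#' gold_standard_from_scores(c(g1 = -1.2, g2 = 0.6, g3 = 0), -0.5, 0.4)
gold_standard_from_scores <- function(dep_scores, ce_cut, ts_cut,
                                      source = "dependency scores") {
  stopifnot(is.numeric(dep_scores), !is.null(names(dep_scores)))
  if (ce_cut >= ts_cut)
    stop("overlapping cuts: ce_cut (", ce_cut, ") must be below ts_cut (",
         ts_cut, ")")
  s <- dep_scores[names(dep_scores) != "NHT"]
  ce <- names(s)[s <= ce_cut]
  ts <- names(s)[s >= ts_cut]
  neg <- setdiff(names(s), c(ce, ts))
  if (length(neg) == 0L)
    warning("empty negative set: every gene lies beyond a cut")
  gold_standard(ce_positive = ce, ts_positive = ts, negatives = neg,
                source = source)
}

#' ROC curve and AUC by the midrank Mann-Whitney construction
#'
#' The AUC equals the Mann-Whitney probability that a positive record ranks
#' above a negative one under the stated orientation, with tied scores
#' counted 1/2. For depletion phenotypes (CE genes) the orientation is
#' `low_is_positive`; for enrichment (TS genes), `high_is_positive`. The
#' curve is evaluated at every distinct score threshold.
#'
#' @param scores numeric vector of record scores (e.g. guide-pair LFCs).
#' @param labels logical (`TRUE` = positive) or character `"pos"`/`"neg"`.
#' @param orientation which tail of the score scale marks positives.
#' @return an object of class `roc_result`: `auc`, `curve` (FPR/TPR points
#'   from (0,0) to (1,1)), `n_pos`, `n_neg`, `orientation`, and a
#'   `degenerate` flag when all scores tie (AUC 0.5).
#' @export
#' @examples
#' roc_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE), "high_is_positive")$auc
roc_auc <- function(scores, labels,
                    orientation = c("high_is_positive", "low_is_positive")) {
  orientation <- match.arg(orientation)
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    stopifnot(all(labels %in% c("pos", "neg")))
    labels <- labels == "pos"
  }
  stopifnot(is.logical(labels), length(labels) == length(scores),
            all(is.finite(scores)))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("need at least one positive and one negative record")
  s <- if (orientation == "low_is_positive") -scores else scores
  rk <- rank(s, ties.method = "average")
  auc <- (sum(rk[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  o <- order(s, decreasing = TRUE)
  sv <- s[o]
  lab <- labels[o]
  last_of_tie <- c(sv[-1] != sv[-length(sv)], TRUE)
  curve <- data.frame(
    fpr = c(0, cumsum(!lab)[last_of_tie] / n_neg),
    tpr = c(0, cumsum(lab)[last_of_tie] / n_pos)
  )
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg,
                 orientation = orientation,
                 degenerate = length(unique(scores)) == 1L),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d positives vs %d negatives, %s)%s\n",
              x$auc, x$n_pos, x$n_neg, x$orientation,
              if (x$degenerate) " [degenerate: all scores tied]" else ""))
  invisible(x)
}

# Build (score, label) records for one positive gene set.
.roc_records <- function(lfc, pos_genes, neg_genes, unit) {
  lab_of <- function(g, cls) {
    out <- rep("other", length(g))
    out[cls == "NHT"] <- "nht"
    out[g %in% neg_genes] <- "neg"
    out[g %in% pos_genes] <- "pos"
    out
  }
  if (unit == "nht_single") {
    recs <- rbind(single_guide_lfc(lfc, 1L), single_guide_lfc(lfc, 2L))
    lab <- lab_of(recs$gene, recs$gene_class)
    keep <- lab %in% c("pos", "neg")
    return(data.frame(score = recs$lfc[keep], label = lab[keep] == "pos"))
  }
  la <- lab_of(lfc$gene_a, lfc$class_a)
  lb <- lab_of(lfc$gene_b, lfc$class_b)
  if (unit == "all_pairs") {
    pos <- la == "pos" | lb == "pos"
    neg <- !pos & (la == "neg" | lb == "neg")
  } else { # guide_pairs: focal gold gene with NHT or negative-set partner
    pos <- (la == "pos" & lb %in% c("nht", "neg")) |
           (lb == "pos" & la %in% c("nht", "neg"))
    neg <- !pos & la %in% c("nht", "neg") & lb %in% c("nht", "neg") &
           (la == "neg" | lb == "neg")
  }
  keep <- pos | neg
  data.frame(score = lfc$lfc[keep], label = pos[keep])
}

#' Benchmark a screen against a gold standard
#'
#' Builds scored records from the guide-level LFC table (by default every
#' guide pair in which a gold-labeled gene is targeted alongside an NHT or
#' negative-set partner; alternatives: `"all_pairs"`, or the NHT-partner
#' single-guide decomposition `"nht_single"`) and runs [roc_auc()] for CE
#' positives vs. negatives (orientation `low_is_positive`: essential genes
#' deplete) and TS positives vs. negatives (`high_is_positive`: suppressors
#' enrich).
#'
#' @param lfc an `lfc_table`.
#' @param gold a `gold_standard`.
#' @param unit record construction mode.
#' @return list with `auc_ce`, `auc_ts`, `roc_ce`, `roc_ts`, `unit`. When a
#'   class has no records its AUC is `NA` with a warning.
#' @export
evaluate_screen <- function(lfc, gold,
                            unit = c("guide_pairs", "all_pairs", "nht_single")) {
  stopifnot(inherits(lfc, "lfc_table"), inherits(gold, "gold_standard"))
  unit <- match.arg(unit)
  run <- function(pos_genes, orientation, what) {
    recs <- .roc_records(lfc, pos_genes, gold$negatives, unit)
    if (!any(recs$label) || !any(!recs$label)) {
      warning("no ", what, " records for ROC; AUC absent")
      return(NULL)
    }
    roc_auc(recs$score, recs$label, orientation)
  }
  roc_ce <- run(gold$ce_positive, "low_is_positive", "CE")
  roc_ts <- run(gold$ts_positive, "high_is_positive", "TS")
  list(auc_ce = if (is.null(roc_ce)) NA_real_ else roc_ce$auc,
       auc_ts = if (is.null(roc_ts)) NA_real_ else roc_ts$auc,
       roc_ce = roc_ce, roc_ts = roc_ts, unit = unit)
}

#' Compare two screens over their shared combinations or gene pairs
#'
#' Matches records by `combo_id` (guide level) or by the ordered gene pair
#' (gene level) and reports Pearson and Spearman correlations plus the
#' least-squares regression line over the intersection.
#'
#' @param a,b two `lfc_table`s or two `gene_pair_table`s.
#' @return list with `r_pearson`, `r_spearman`, `slope`, `intercept`, `n`,
#'   and `only_a`/`only_b` (sizes of the key sets' symmetric difference).
#' @export
compare_screens <- function(a, b) {
  key_of <- function(x) {
    if ("combo_id" %in% names(x)) x$combo_id
    else paste(x$gene_a, x$gene_b, sep = "|")
  }
  ka <- key_of(a); kb <- key_of(b)
  shared <- intersect(ka, kb)
  if (length(shared) < 3L)
    stop("fewer than 3 shared records between the two screens")
  va <- a$lfc[match(shared, ka)]
  vb <- b$lfc[match(shared, kb)]
  cp <- correlate(va, vb, "pearson")
  cs <- correlate(va, vb, "spearman")
  list(r_pearson = cp$r, r_spearman = cs$r,
       slope = cp$slope, intercept = cp$intercept, n = cp$n,
       only_a = length(setdiff(ka, kb)), only_b = length(setdiff(kb, ka)))
}
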