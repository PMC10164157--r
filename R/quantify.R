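# Paired-read quantification: anchored spacer extraction, bounded-Hamming
# matching against the designed library, and library-uniformity QC.

#' Extract spacers downstream of a constant anchor sequence
#'
#' Locates the constant region upstream of the gRNA in each read, allowing an
#' edit distance (substitutions and indels) of up to
#' `floor(error_tolerance * nchar(anchor))`, and returns the `spacer_len`
#' bases immediately following it. Reads without a qualifying anchor
#' occurrence, or with fewer than `spacer_len` bases after it, yield `NA`
#' (they are discarded as untrimmed). When several occurrences qualify the
#' leftmost is used. `N` bases count as mismatches inside the anchor;
#' extraction of the spacer itself is verbatim.
#'
#' @param reads character vector of reads (A/C/G/T/N).
#' @param anchor constant region immediately 5' of the spacer.
#' @param spacer_len number of bases to extract after the anchor.
#' @param error_tolerance fraction in \[0, 0.5) of the anchor length allowed
#'   as edit distance (default 0.1).
#' @return character vector of spacers, `NA` where the read is discarded.
#' @export
#' @examples
#' locate_spacer("GGCTTTATATATCTTGTGGAAAGGACGAAACACCGAAAACCCCGGGGTTTT",
#'               "TATCTTGTGGAAAGGACGAAACACCG", 16)
locate_spacer <- function(reads, anchor, spacer_len, error_tolerance = 0.1) {
  stopifnot(is.character(reads), nchar(anchor) > 0L,
            error_tolerance >= 0, error_tolerance < 0.5,
            spacer_len >= 1L)
  anchor <- toupper(anchor)
  if (!grepl("^[ACGT]+$", anchor)) stop("anchor must be plain DNA (A/C/G/T)")
  if (length(reads) == 0L) return(character(0))
  reads <- toupper(reads)
  bad <- !grepl("^[ACGTN]*$", reads)
  if (any(bad))
    stop("read(s) contain non-DNA characters (first offender at index ",
         which(bad)[1], ")")
  max_ed <- floor(error_tolerance * nchar(anchor))
  subj <- Biostrings::DNAStringSet(reads)
  # Vectorized substitution-only pass first; per-read indel-aware fallback
  # for the rare reads it misses, so the full edit-distance semantics hold.
  m <- Biostrings::vmatchPattern(anchor, subj, max.mismatch = max_ed)
  ends <- vapply(Biostrings::endIndex(m),
                 function(e) if (length(e)) min(e) else NA_integer_,
                 integer(1))
  if (max_ed > 0L) {
    for (i in which(is.na(ends))) {
      mm <- Biostrings::matchPattern(anchor, subj[[i]],
                                     max.mismatch = max_ed,
                                     with.indels = TRUE)
      if (length(mm)) ends[i] <- min(BiocGenerics::end(mm))
    }
  }
  out <- substr(reads, ends + 1L, ends + spacer_len)
  out[is.na(ends) | nchar(out) < spacer_len] <- NA_character_
  out
}

#' Match extracted spacers against a position's guide index
#'
#' An exact match wins immediately; otherwise the unique guide within Hamming
#' distance `max_mismatches` is reported. Queries tying two or more guides at
#' the minimal qualifying distance are `ambiguous`; length-mismatched or
#' unmatched queries are `no_match`. `NA` queries (no anchor found upstream)
#' stay `no_anchor`.
#'
#' @param spacers character vector of extracted spacers (may contain `NA`).
#' @param index guide index for one position: a data.frame with `guide_id`
#'   and `spacer` columns, or a named character vector
#'   (names = guide ids, values = spacers).
#' @param max_mismatches maximum Hamming distance (default 1, mirroring a
#'   one-mismatch seed).
#' @return data.frame with columns `guide_id` (`NA` unless matched) and
#'   `status` in `{"matched","no_match","ambiguous","no_anchor"}`.
#' @export
match_spacer <- function(spacers, index, max_mismatches = 1L) {
  if (is.data.frame(index)) {
    ids <- as.character(index$guide_id)
    seqs <- toupper(as.character(index$spacer))
  } else {
    ids <- names(index)
    seqs <- toupper(as.character(index))
  }
  stopifnot(length(ids) > 0L, !anyDuplicated(seqs))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("index spacers must share one length")
  status <- rep("no_match", length(spacers))
  guide <- rep(NA_character_, length(spacers))
  is_na <- is.na(spacers)
  status[is_na] <- "no_anchor"
  q <- toupper(spacers)
  hit <- match(q, seqs)
  exact <- !is_na & !is.na(hit)
  status[exact] <- "matched"
  guide[exact] <- ids[hit[exact]]
  todo <- which(!is_na & !exact & nchar(q) == L)
  if (length(todo) && max_mismatches > 0L) {
    idx_mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                      nrow = L)
    uq <- unique(q[todo])
    res_id <- character(length(uq))
    res_st <- character(length(uq))
    for (k in seq_along(uq)) {
      qc <- strsplit(uq[k], "")[[1]]
      d <- colSums(idx_mat != qc)
      dmin <- min(d)
      if (dmin > max_mismatches) {
        res_st[k] <- "no_match"
        res_id[k] <- NA_character_
      } else if (sum(d == dmin) > 1L) {
        res_st[k] <- "ambiguous"
        res_id[k] <- NA_character_
      } else {
        res_st[k] <- "matched"
        res_id[k] <- ids[which.min(d)]
      }
    }
    pos <- match(q[todo], uq)
    status[todo] <- res_st[pos]
    guide[todo] <- res_id[pos]
  }
  data.frame(guide_id = guide, status = status, stringsAsFactors = FALSE)
}

UNASSIGNED_CATEGORIES <- c("no_anchor", "no_match", "ambiguous", "not_in_library")

# Internal constructor for the count-table container (modelled on list-based
# expression containers such as DGEList).
count_table <- function(counts, combinations, samples, unassigned = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(combinations),
            ncol(counts) == nrow(samples),
            all(counts >= 0))
  rownames(counts) <- combinations$combo_id
  colnames(counts) <- samples$sample_id
  if (is.null(unassigned)) {
    unassigned <- matrix(0L, nrow = length(UNASSIGNED_CATEGORIES),
                         ncol = nrow(samples),
                         dimnames = list(UNASSIGNED_CATEGORIES, samples$sample_id))
  }
  structure(list(counts = counts, combinations = combinations,
                 samples = samples, unassigned = unassigned),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("Count table: ", nrow(x$counts), " combinations x ",
      ncol(x$counts), " sample(s)\n", sep = "")
  print(x$samples, row.names = FALSE)
  invisible(x)
}

#' Count paired guide combinations from synchronized read streams
#'
#' Processes the two mates of each read pair independently (anchored spacer
#' extraction, then bounded-Hamming matching against the corresponding
#' cassette's guide index) and assigns the pair to a library combination when
#' both mates match unambiguously and the (position-1, position-2) guide pair
#' exists in the library. Failed pairs are tallied once, under the first
#' failing category in the precedence
#' `no_anchor < no_match < ambiguous < not_in_library` (mate 1 checked before
#' mate 2 within a category).
#'
#' @param reads1,reads2 character vectors of mate-1/mate-2 reads, or paths to
#'   (optionally gzipped) FASTQ files. Must be synchronized and equally long.
#' @param library a `combi_library`.
#' @param anchor1,anchor2 constant regions upstream of the position-1 and
#'   position-2 spacers.
#' @param error_tolerance anchor edit-distance tolerance (see
#'   [locate_spacer()]).
#' @param max_mismatches spacer Hamming tolerance (see [match_spacer()]).
#' @param sample_id,role,replicate sample descriptors for the resulting
#'   single-sample count table (`role` is `"library_reference"` or
#'   `"screen_end"`).
#' @return a `count_table` with one sample and per-category unassigned
#'   tallies; assigned + unassigned always equals the number of input pairs.
#' @export
count_pairs <- function(reads1, reads2, library, anchor1, anchor2,
                        error_tolerance = 0.1, max_mismatches = 1L,
                        sample_id = "sample1", role = "screen_end",
                        replicate = 1L) {
  stopifnot(inherits(library, "combi_library"))
  role <- match.arg(role, c("library_reference", "screen_end"))
  reads1 <- read_seqs(reads1)
  reads2 <- read_seqs(reads2)
  if (length(reads1) != length(reads2))
    stop("read streams are unsynchronized: ", length(reads1), " vs ",
         length(reads2), " reads")
  g1 <- position_guides(library, 1L)
  g2 <- position_guides(library, 2L)
  n <- length(reads1)
  combos <- library$combinations
  samples <- data.frame(sample_id = sample_id, role = role,
                        replicate = as.integer(replicate),
                        stringsAsFactors = FALSE)
  if (n == 0L) {
    return(count_table(matrix(0L, nrow(combos), 1L), combos, samples))
  }
  sp1 <- locate_spacer(reads1, anchor1, unique(nchar(g1$spacer)), error_tolerance)
  sp2 <- locate_spacer(reads2, anchor2, unique(nchar(g2$spacer)), error_tolerance)
  m1 <- match_spacer(sp1, g1, max_mismatches)
  m2 <- match_spacer(sp2, g2, max_mismatches)
  category <- rep(NA_character_, n)
  anchor_fail <- m1$status == "no_anchor" | m2$status == "no_anchor"
  match_fail <- !anchor_fail & (m1$status == "no_match" | m2$status == "no_match")
  ambig <- !anchor_fail & !match_fail &
    (m1$status == "ambiguous" | m2$status == "ambiguous")
  category[anchor_fail] <- "no_anchor"
  category[match_fail] <- "no_match"
  category[ambig] <- "ambiguous"
  ok <- is.na(category)
  key <- paste(m1$guide_id, m2$guide_id, sep = "|")
  idx <- match(key, combos$combo_id)
  category[ok & is.na(idx)] <- "not_in_library"
  assigned <- ok & !is.na(idx)
  counts <- tabulate(idx[assigned], nbins = nrow(combos))
  unassigned <- matrix(
    vapply(UNASSIGNED_CATEGORIES, function(ct) sum(category == ct, na.rm = TRUE),
           integer(1)),
    ncol = 1L, dimnames = list(UNASSIGNED_CATEGORIES, sample_id))
  count_table(matrix(as.integer(counts), ncol = 1L), combos, samples, unassigned)
}

# Read sequences from a character vector or a FASTQ file path.
read_seqs <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", x)) {
    return(as.character(Biostrings::readDNAStringSet(x, format = "fastq")))
  }
  as.character(x)
}

#' Combine single-sample count tables over the same combination universe
#'
#' @param ... `count_table` objects sharing identical combinations.
#' @return one multi-sample `count_table`.
#' @export
combine_samples <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1L, all(vapply(tabs, inherits, logical(1), "count_table")))
  combos <- tabs[[1]]$combinations
  for (t in tabs[-1]) {
    if (!identical(t$combinations$combo_id, combos$combo_id))
      stop("count tables cover different combination universes")
  }
  count_table(do.call(cbind, lapply(tabs, `[[`, "counts")),
              combos,
              do.call(rbind, lapply(tabs, `[[`, "samples")),
              do.call(cbind, lapply(tabs, `[[`, "unassigned")))
}

#' Read-count distribution skew (P90/P10)
#'
#' Ratio of the 90th to the 10th percentile of a count distribution using the
#' nearest-rank convention (the `ceiling(p * n)`-th order statistic). A skew
#' below 2.5 denotes a uniform library. When the 10th percentile is zero the
#' ratio is undefined and `NA` is returned with attribute
#' `undefined = TRUE` rather than an error.
#'
#' @param counts non-empty nonnegative numeric vector.
#' @return the ratio (scale-invariant, >= 1), or flagged `NA`.
#' @export
#' @examples
#' skew_ratio(c(rep(10, 8), 100, 100))
skew_ratio <- function(counts) {
  if (length(counts) == 0L) stop("empty count vector")
  stopifnot(all(is.finite(counts)), all(counts >= 0))
  s <- sort(counts)
  n <- length(s)
  p10 <- s[ceiling(0.1 * n)]
  p90 <- s[ceiling(0.9 * n)]
  if (p10 == 0) {
    return(structure(NA_real_, undefined = TRUE,
                     reason = "10th percentile is zero"))
  }
  structure(p90 / p10, convention = "nearest-rank")
}

#' Lorenz curve of a count distribution
#'
#' Sorts counts ascending and returns the cumulative fraction of reads as a
#' function of the cumulative fraction of combinations, from (0,0) to (1,1),
#' with the area under the curve (trapezoidal) as a summary; 0.5 is perfect
#' uniformity.
#'
#' @param counts non-empty, nonnegative, not all zero.
#' @return data.frame with `frac_combinations`, `frac_reads`; attribute
#'   `area`.
#' @export
#' @examples
#' lorenz_curve(c(1, 1, 2))
lorenz_curve <- function(counts) {
  if (length(counts) == 0L) stop("empty count vector")
  stopifnot(all(is.finite(counts)), all(counts >= 0))
  if (all(counts == 0)) stop("all-zero count vector has no Lorenz curve")
  s <- sort(counts)
  n <- length(s)
  x <- (0:n) / n
  y <- c(0, cumsum(s)) / sum(s)
  area <- sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  structure(data.frame(frac_combinations = x, frac_reads = y),
            area = area)
}

#' Per-sample library-uniformity QC
#'
#' For every sample of a count table: the P90/P10 skew ratio (nearest-rank),
#' the Lorenz area, and the number of zero-count combinations.
#'
#' @param counts a `count_table` or `normalized_table`.
#' @return data.frame with one row per sample (`sample_id`, `skew`,
#'   `lorenz_area`, `n_zero`); attribute `lorenz` holds the per-sample
#'   curves and attribute `percentile_convention` records the convention.
#' @export
qc_report <- function(counts) {
  m <- if (inherits(counts, "normalized_table")) counts$values else counts$counts
  curves <- lapply(seq_len(ncol(m)), function(j) lorenz_curve(m[, j]))
  out <- data.frame(
    sample_id = counts$samples$sample_id,
    skew = vapply(seq_len(ncol(m)), function(j) as.numeric(skew_ratio(m[, j])),
                  numeric(1)),
    lorenz_area = vapply(curves, function(cu) attr(cu, "area"), numeric(1)),
    n_zero = vapply(seq_len(ncol(m)), function(j) sum(m[, j] == 0), numeric(1)),
    stringsAsFactors = FALSE
  )
  names(curves) <- counts$samples$sample_id
  attr(out, "lorenz") <- curves
  attr(out, "percentile_convention") <- "nearest-rank"
  out
}
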