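# Guide records, cassette designs, combination libraries, pair classes,
# and PAM subsetting.

# Spacer length is fixed by the nuclease: 20 nt for SpCas9, 23 nt for
# (en/op)AsCas12a.
SPACER_LEN <- c(SpCas9 = 20L, AsCas12a = 23L)

GENE_CLASSES <- c("CE", "TS", "NHT")

# Canonical ordering used to build symmetric pair-class labels:
# NHT-NHT, NHT-CE, NHT-TS, CE-CE, CE-TS, TS-TS.
.CLASS_RANK <- c(NHT = 0L, CE = 1L, TS = 2L)

#' Classify a guide pair by the gene classes of its two members
#'
#' The label is symmetric in the unordered class pair: `(CE, NHT)` and
#' `(NHT, CE)` both yield `"NHT-CE"`. Possible labels are `CE-CE`, `TS-TS`,
#' `CE-TS`, `NHT-CE`, `NHT-TS` and `NHT-NHT`. Pairs with one NHT member
#' target a single gene; NHT-NHT pairs define the neutral baseline.
#'
#' @param class_a,class_b character vectors over `{"CE","TS","NHT"}`
#'   (recycled to a common length).
#' @return character vector of pair-class labels.
#' @export
#' @examples
#' classify_pair("CE", "CE")
#' classify_pair(c("TS", "NHT"), c("NHT", "NHT"))
classify_pair <- function(class_a, class_b) {
  a <- as.character(class_a)
  b <- as.character(class_b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  bad <- !(a %in% GENE_CLASSES) | !(b %in% GENE_CLASSES)
  if (any(bad)) {
    stop("unknown gene class token(s): ",
         paste(setdiff(unique(c(a, b)), GENE_CLASSES), collapse = ", "))
  }
  swap <- .CLASS_RANK[a] > .CLASS_RANK[b]
  paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "-")
}

#' Describe a dual-cassette library design
#'
#' Returns the cassette composition of one of the six screening constructs:
#' the nuclease served by each cassette (position 1 = h7SK cassette or first
#' hybrid-transcript guide, position 2 = hU6 cassette or second guide),
#' whether a cassette carries an arrayed dual-gRNA targeting one gene
#' (`dual_gene_arrays`), whether the construct expresses a single hybrid
#' transcript that must be processed by Cas12a (`hybrid_transcript`), and the
#' simulation defaults for per-position RNA-processing penalties
#' (`processing_penalty`, multipliers in \[0,1\] applied to that position's
#' fitness contribution) and within-cassette array weights (`array_weights`).
#'
#' The penalty defaults are phenomenological: hybrid-transcript designs have
#' a strongly penalized SpCas9 position (the SpCas9 half of the hybrid guide
#' is largely inactive) and a mildly penalized Cas12a position, while dual
#' Cas12a arrays in a processing-free cassette are down-weighted.
#'
#' @param name one of `"SpCas9"`, `"enAsCas12a"`, `"CHyMErA"`,
#'   `"enAsCas12a_dual"`, `"CHyMErA_v2"`, `"multiSPAS"`.
#' @param processing_penalty optional length-2 numeric in \[0,1\] overriding
#'   the per-position defaults.
#' @param array_weights optional length-2 numeric overriding the per-slot
#'   weights of dual-gRNA arrays.
#' @return an object of class `library_design`.
#' @export
#' @examples
#' library_design("multiSPAS")
library_design <- function(name = c("SpCas9", "enAsCas12a", "CHyMErA",
                                    "enAsCas12a_dual", "CHyMErA_v2",
                                    "multiSPAS"),
                           processing_penalty = NULL,
                           array_weights = NULL) {
  name <- match.arg(name)
  defs <- list(
    SpCas9 = list(nuc = c("SpCas9", "SpCas9"), dual = c(FALSE, FALSE),
                  hybrid = FALSE, pi = c(1, 1), w = c(1, 1)),
    enAsCas12a = list(nuc = c("AsCas12a", "AsCas12a"), dual = c(FALSE, FALSE),
                      hybrid = FALSE, pi = c(0.85, 0.85), w = c(1, 1)),
    CHyMErA = list(nuc = c("SpCas9", "AsCas12a"), dual = c(FALSE, FALSE),
                   hybrid = TRUE, pi = c(0.20, 0.90), w = c(1, 1)),
    enAsCas12a_dual = list(nuc = c("AsCas12a", "AsCas12a"),
                           dual = c(TRUE, TRUE), hybrid = FALSE,
                           pi = c(0.85, 0.85), w = c(0.4, 0.4)),
    CHyMErA_v2 = list(nuc = c("SpCas9", "AsCas12a"), dual = c(FALSE, TRUE),
                      hybrid = TRUE, pi = c(0.20, 0.90), w = c(1, 1)),
    multiSPAS = list(nuc = c("SpCas9", "AsCas12a"), dual = c(FALSE, FALSE),
                     hybrid = FALSE, pi = c(1, 0.85), w = c(1, 1))
  )
  d <- defs[[name]]
  pi <- processing_penalty %||% d$pi
  w <- array_weights %||% d$w
  stopifnot(length(pi) == 2L, all(pi >= 0 & pi <= 1),
            length(w) == 2L, all(w >= 0))
  structure(list(name = name,
                 cassette_nucleases = d$nuc,
                 dual_gene_arrays = d$dual,
                 hybrid_transcript = d$hybrid,
                 processing_penalty = as.numeric(pi),
                 array_weights = as.numeric(w)),
            class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat("Library design:", x$name, "\n")
  cat("  position 1:", x$cassette_nucleases[1],
      if (x$dual_gene_arrays[1]) "(dual-gRNA array)" else "",
      " penalty", x$processing_penalty[1], "\n")
  cat("  position 2:", x$cassette_nucleases[2],
      if (x$dual_gene_arrays[2]) "(dual-gRNA array)" else "",
      " penalty", x$processing_penalty[2], "\n")
  if (x$hybrid_transcript) cat("  hybrid single-transcript gRNA (requires processing)\n")
  invisible(x)
}

.GUIDE_COLS <- c("guide_id", "nuclease", "spacer", "gene", "gene_class")

# Validate a per-position guide table; returns the normalized data.frame.
validate_guides <- function(guides, nuclease = NULL, position = NA,
                            check_length = TRUE) {
  if (!is.data.frame(guides) || nrow(guides) == 0L)
    stop("guide table for position ", position, " must be a non-empty data.frame")
  missing_cols <- setdiff(.GUIDE_COLS, names(guides))
  if (length(missing_cols))
    stop("guide table is missing column(s): ", paste(missing_cols, collapse = ", "))
  g <- guides
  for (col in c("guide_id", "nuclease", "spacer", "gene", "gene_class"))
    g[[col]] <- as.character(g[[col]])
  if (!"rank" %in% names(g)) g$rank <- NA_integer_
  if (!"pam_context" %in% names(g)) g$pam_context <- NA_character_
  g$spacer <- toupper(g$spacer)
  if (anyDuplicated(g$guide_id))
    stop("duplicate guide_id within position ", position, ": ",
         paste(unique(g$guide_id[duplicated(g$guide_id)]), collapse = ", "))
  bad_nuc <- !(g$nuclease %in% names(SPACER_LEN))
  if (any(bad_nuc))
    stop("unknown nuclease token(s): ", paste(unique(g$nuclease[bad_nuc]), collapse = ", "))
  bad_dna <- !grepl("^[ACGT]+$", g$spacer)
  if (any(bad_dna))
    stop("non-DNA spacer(s) for guide(s): ",
         paste(g$guide_id[bad_dna], collapse = ", "))
  if (check_length) {
    exp_len <- SPACER_LEN[g$nuclease]
    bad_len <- nchar(g$spacer) != exp_len
    if (any(bad_len))
      stop("spacer length inconsistent with nuclease for guide(s): ",
           paste(sprintf("%s (%d nt, expected %d)", g$guide_id[bad_len],
                         nchar(g$spacer)[bad_len], exp_len[bad_len]),
                 collapse = ", "))
  }
  dup <- duplicated(g$spacer)
  if (any(dup))
    stop("duplicate spacer(s) within position ", position, ": ",
         paste(unique(g$spacer[dup]), collapse = ", "))
  bad_class <- !(g$gene_class %in% GENE_CLASSES)
  if (any(bad_class))
    stop("unknown gene_class token(s): ",
         paste(unique(g$gene_class[bad_class]), collapse = ", "))
  inconsistent <- xor(g$gene == "NHT", g$gene_class == "NHT")
  if (any(inconsistent))
    stop("gene must be 'NHT' exactly when gene_class is 'NHT'; offending guide(s): ",
         paste(g$guide_id[inconsistent], collapse = ", "))
  rownames(g) <- NULL
  g
}

#' Build a full-cross combination library
#'
#' Forms the complete cross product of the position-1 and position-2 guide
#' lists of a dual-cassette design and assigns every combination its pair
#' class. Position order is meaningful and never swapped: position 1 is the
#' h7SK cassette (or first hybrid guide), position 2 the hU6 cassette (or
#' second guide).
#'
#' @param guides either a single data.frame with a `position` column (values
#'   1/2) or a list of two data.frames `(position 1, position 2)`. Required
#'   columns: `guide_id`, `nuclease`, `spacer`, `gene`, `gene_class`;
#'   optional: `rank`, `pam_context`.
#' @param design a [library_design()] object (or a design name).
#' @param check_spacer_length validate spacer length against the cassette
#'   nuclease (disable for pre-trimmed or array libraries).
#' @return an object of class `combi_library` with elements `design`,
#'   `guides` (both positions, with a `position` column) and `combinations`
#'   (one row per guide pair: `combo_id`, guide ids, genes, classes,
#'   `pair_class`).
#' @export
#' @examples
#' g <- data.frame(guide_id = c("a", "b"), nuclease = "SpCas9",
#'                 spacer = c(strrep("A", 20), strrep("C", 20)),
#'                 gene = c("TP53", "NHT"), gene_class = c("TS", "NHT"))
#' lib <- build_library(list(g, g), library_design("SpCas9"))
#' nrow(lib$combinations)
build_library <- function(guides, design = library_design("SpCas9"),
                          check_spacer_length = TRUE) {
  if (is.character(design)) design <- library_design(design)
  stopifnot(inherits(design, "library_design"))
  if (is.data.frame(guides)) {
    if (!"position" %in% names(guides))
      stop("a single guide table must carry a 'position' column (1/2)")
    guides <- split(guides, guides$position)
    if (!identical(names(guides), c("1", "2")))
      stop("'position' must take exactly the values 1 and 2")
  }
  stopifnot(is.list(guides), length(guides) == 2L)
  g1 <- validate_guides(guides[[1]], position = 1, check_length = check_spacer_length)
  g2 <- validate_guides(guides[[2]], position = 2, check_length = check_spacer_length)
  exp1 <- design$cassette_nucleases[1]
  exp2 <- design$cassette_nucleases[2]
  if (check_spacer_length) {
    if (!all(g1$nuclease == exp1))
      stop("position-1 guides must use nuclease ", exp1, " for design ", design$name)
    if (!all(g2$nuclease == exp2))
      stop("position-2 guides must use nuclease ", exp2, " for design ", design$name)
  }
  g1$position <- 1L
  g2$position <- 2L
  idx <- expand.grid(i = seq_len(nrow(g1)), j = seq_len(nrow(g2)),
                     KEEP.OUT.ATTRS = FALSE)
  combos <- data.frame(
    combo_id = paste(g1$guide_id[idx$i], g2$guide_id[idx$j], sep = "|"),
    guide_a = g1$guide_id[idx$i],
    guide_b = g2$guide_id[idx$j],
    gene_a = g1$gene[idx$i],
    gene_b = g2$gene[idx$j],
    class_a = g1$gene_class[idx$i],
    class_b = g2$gene_class[idx$j],
    stringsAsFactors = FALSE
  )
  combos$pair_class <- classify_pair(combos$class_a, combos$class_b)
  stopifnot(!anyDuplicated(combos$combo_id))
  structure(list(design = design,
                 guides = rbind(g1, g2),
                 combinations = combos),
            class = "combi_library")
}

#' @export
print.combi_library <- function(x, ...) {
  n1 <- sum(x$guides$position == 1L)
  n2 <- sum(x$guides$position == 2L)
  cat("Combination library (", x$design$name, "): ",
      n1, " x ", n2, " guides = ", nrow(x$combinations),
      " combinations\n", sep = "")
  tab <- table(x$combinations$pair_class)
  cat("  pair classes:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Guides of one library position
#'
#' @param library a `combi_library`.
#' @param position 1 or 2.
#' @return the guide data.frame of that cassette.
#' @export
position_guides <- function(library, position) {
  stopifnot(inherits(library, "combi_library"), position %in% c(1L, 2L))
  out <- library$guides[library$guides$position == position, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subset guides by PAM context with an IUPAC pattern
#'
#' Retains guides whose `pam_context` matches the IUPAC pattern (e.g.
#' `"TTTV"`, the canonical AsCas12a motif, with V = A/C/G). Guides lacking a
#' `pam_context` are excluded and counted in the `excluded_no_pam` attribute.
#'
#' @param guides guide data.frame with a `pam_context` column.
#' @param pattern IUPAC string, same length as the PAM contexts.
#' @return the retained rows, with attribute `excluded_no_pam`.
#' @export
#' @examples
#' g <- data.frame(guide_id = 1:2, pam_context = c("TTTA", "TTTT"))
#' pam_filter(g, "TTTV")$guide_id
pam_filter <- function(guides, pattern) {
  stopifnot(is.data.frame(guides), "pam_context" %in% names(guides))
  pattern <- toupper(pattern)
  codes <- strsplit(pattern, "")[[1]]
  bad <- !(codes %in% names(Biostrings::IUPAC_CODE_MAP))
  if (any(bad))
    stop("invalid IUPAC code(s) in pattern: ", paste(unique(codes[bad]), collapse = ", "))
  pam <- toupper(as.character(guides$pam_context))
  has_pam <- !is.na(pam) & nzchar(pam)
  keep <- logical(nrow(guides))
  if (any(has_pam)) {
    wrong_len <- nchar(pam[has_pam]) != nchar(pattern)
    if (any(wrong_len))
      stop("pam_context length differs from pattern length for ",
           sum(wrong_len), " guide(s)")
    hits <- Biostrings::vcountPattern(pattern,
                                      Biostrings::DNAStringSet(pam[has_pam]),
                                      fixed = FALSE) > 0L
    keep[has_pam] <- hits
  }
  out <- guides[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_no_pam") <- sum(!has_pam)
  out
}
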