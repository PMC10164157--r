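# Small deterministic fixtures built in code.

# Deterministic distinct spacers: integer i encoded in base 4, each digit
# written as a block of 4 identical bases (so distinct spacers are at least
# Hamming distance 3 apart, keeping 1-mismatch matching unambiguous).
fixed_spacers <- function(n, len, offset = 0L) {
  ndig <- ceiling(len / 4)
  vapply(seq_len(n) + offset, function(i) {
    d <- integer(ndig)
    x <- i
    for (k in seq_len(ndig)) {
      d[k] <- x %% 4L
      x <- x %/% 4L
    }
    substr(paste(rep(c("A", "C", "G", "T")[d + 1L], each = 4), collapse = ""),
           1, len)
  }, character(1))
}

# One cassette's guide table with the given genes/classes plus NHT controls.
tiny_position <- function(genes, classes, n_nht = 2L, nuclease = "SpCas9",
                          position = 1L, guides_per_gene = 1L, offset = 0L) {
  gene_v <- rep(genes, each = guides_per_gene)
  class_v <- rep(classes, each = guides_per_gene)
  if (n_nht > 0L) {
    gene_v <- c(gene_v, rep("NHT", n_nht))
    class_v <- c(class_v, rep("NHT", n_nht))
  }
  n <- length(gene_v)
  sub <- stats::ave(seq_len(n), gene_v, FUN = seq_along)
  data.frame(
    guide_id = sprintf("%s_g%d_p%d", gene_v, sub, position),
    nuclease = nuclease,
    spacer = fixed_spacers(n, combscreen:::SPACER_LEN[[nuclease]], offset),
    gene = gene_v,
    gene_class = class_v,
    stringsAsFactors = FALSE
  )
}

tiny_library <- function(genes = c("CCT4", "TP53"), classes = c("CE", "TS"),
                         n_nht = 2L, guides_per_gene = 1L,
                         design = library_design("SpCas9")) {
  g1 <- tiny_position(genes, classes, n_nht, design$cassette_nucleases[1], 1L,
                      guides_per_gene, offset = 0L)
  g2 <- tiny_position(genes, classes, n_nht, design$cassette_nucleases[2], 2L,
                      guides_per_gene, offset = 1000L)
  build_library(list(g1, g2), design)
}

# A count table over a library, with counts supplied per combination.
tiny_count_table <- function(library, counts, sample_id = "s1",
                             role = "screen_end", replicate = 1L) {
  combos <- library$combinations
  stopifnot(length(counts) == nrow(combos))
  combscreen:::count_table(
    matrix(counts, ncol = 1L),
    combos,
    data.frame(sample_id = sample_id, role = role,
               replicate = as.integer(replicate), stringsAsFactors = FALSE))
}

# A normalized table with prescribed values (for LFC arithmetic tests).
fake_normalized <- function(values, pair_class = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  combos <- data.frame(
    combo_id = sprintf("c%03d", seq_len(n)),
    guide_a = sprintf("a%03d", seq_len(n)),
    guide_b = sprintf("b%03d", seq_len(n)),
    gene_a = sprintf("GA%03d", seq_len(n)),
    gene_b = sprintf("GB%03d", seq_len(n)),
    class_a = "CE", class_b = "CE",
    stringsAsFactors = FALSE)
  combos$pair_class <- pair_class %||% "CE-CE"
  samples <- data.frame(
    sample_id = colnames(values) %||% sprintf("s%d", seq_len(ncol(values))),
    role = c("library_reference", rep("screen_end", ncol(values) - 1L)),
    replicate = c(1L, seq_len(ncol(values) - 1L)),
    stringsAsFactors = FALSE)
  colnames(values) <- samples$sample_id
  structure(list(values = values, combinations = combos, samples = samples,
                 normalization = data.frame(sample_id = samples$sample_id,
                                            total = 1, nht_median = 1,
                                            scale = 1)),
            class = "normalized_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive pairwise Mann-Whitney oracle for AUC (ties count 1/2).
auc_oracle <- function(scores, labels, orientation = "high_is_positive") {
  s <- if (orientation == "low_is_positive") -scores else scores
  pos <- s[labels]
  neg <- s[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
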