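# Synthetic combinatorial screens with known ground truth: library layout,
# per-gene fitness, per-guide activity, per-design processing penalties,
# dropout dynamics over cell doublings, sampling noise, and raw reads.

#' Configure a synthetic combinatorial screen
#'
#' Defaults emulate the reference screening setup: a 160 x 160 combination
#' library (10 core-essential + 10 tumor-suppressor genes x 4 guides plus 80
#' NHT controls per cassette), 10 cell doublings, 100-fold library coverage,
#' two technical end-timepoint replicates, and lentiviral-representation
#' skew. Gene fitness is expressed in log2 abundance change per doubling per
#' unit guide activity; with the defaults a fully active single CE guide
#' paired with NHT drifts to LFC near -4 over the screen. Six of the ten CE
#' genes (named after the gold-standard essentials) and five of the ten TS
#' genes carry strong fitness effects; the rest are near-neutral, mirroring
#' the gold-standard partition of the library into 6 + 5 positives and 9
#' negatives.
#'
#' @param design a [library_design()] (or name); its processing penalties
#'   and dual-array weights shape the simulated guide activities.
#' @param n_ce,n_ts,guides_per_gene,n_nht library layout per cassette.
#' @param doublings cell doublings between transduction and harvest.
#' @param coverage reads (and cells) per library element; the default
#'   sequencing depth is `coverage * n_combinations`.
#' @param replicates number of end-timepoint technical replicates.
#' @param fitness_ce,fitness_ce_sd,strong_ce_fraction strong-CE fitness
#'   distribution (log2/doubling) and the fraction of CE genes carrying it.
#' @param fitness_ts,fitness_ts_sd,strong_ts_fraction ditto for TS genes.
#' @param weak_sd fitness spread of the near-neutral remaining genes.
#' @param activity_shape1,activity_shape2,activity_min per-guide activity
#'   `a = activity_min + (1 - activity_min) * Beta(shape1, shape2)`.
#' @param rep_sigma lognormal sigma of the initial library representation
#'   (0.3 keeps the simulated plasmid library below the 2.5 uniformity skew).
#' @param depth reads per sample (default `coverage * n_combinations`).
#' @param combination_rule `"additive"` (no epistasis, the default) or
#'   `"max"` (the position contribution of larger magnitude wins).
#' @param interaction additive interaction term hook (default 0; no
#'   epistasis is modeled).
#' @param overdispersion Dirichlet-multinomial concentration; `Inf` (default)
#'   is plain multinomial sampling.
#' @param noiseless if `TRUE`, [simulate_counts()] returns expected
#'   real-valued counts instead of random draws.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(design = "SpCas9",
                              n_ce = 10L, n_ts = 10L, guides_per_gene = 4L,
                              n_nht = 80L,
                              doublings = 10, coverage = 100, replicates = 2L,
                              fitness_ce = -0.4, fitness_ce_sd = 0.05,
                              strong_ce_fraction = 0.6,
                              fitness_ts = 0.2, fitness_ts_sd = 0.05,
                              strong_ts_fraction = 0.5,
                              weak_sd = 0.02,
                              activity_shape1 = 3, activity_shape2 = 1.5,
                              activity_min = 0.25,
                              rep_sigma = 0.3, depth = NULL,
                              combination_rule = c("additive", "max"),
                              interaction = 0,
                              overdispersion = Inf, noiseless = FALSE) {
  if (is.character(design)) design <- library_design(design)
  stopifnot(inherits(design, "library_design"),
            n_ce >= 0, n_ts >= 0, guides_per_gene >= 1, n_nht >= 0,
            doublings > 0, coverage > 0, replicates >= 1,
            strong_ce_fraction >= 0, strong_ce_fraction <= 1,
            strong_ts_fraction >= 0, strong_ts_fraction <= 1,
            activity_min >= 0, activity_min <= 1,
            rep_sigma >= 0, overdispersion > 0)
  if (any(design$dual_gene_arrays) && n_nht %% 2L != 0L)
    stop("n_nht must be even for dual-gRNA array designs")
  structure(list(design = design, n_ce = as.integer(n_ce),
                 n_ts = as.integer(n_ts),
                 guides_per_gene = as.integer(guides_per_gene),
                 n_nht = as.integer(n_nht),
                 doublings = doublings, coverage = coverage,
                 replicates = as.integer(replicates),
                 fitness_ce = fitness_ce, fitness_ce_sd = fitness_ce_sd,
                 strong_ce_fraction = strong_ce_fraction,
                 fitness_ts = fitness_ts, fitness_ts_sd = fitness_ts_sd,
                 strong_ts_fraction = strong_ts_fraction,
                 weak_sd = weak_sd,
                 activity_shape1 = activity_shape1,
                 activity_shape2 = activity_shape2,
                 activity_min = activity_min,
                 rep_sigma = rep_sigma, depth = depth,
                 combination_rule = match.arg(combination_rule),
                 interaction = interaction,
                 overdispersion = overdispersion, noiseless = noiseless),
            class = "simulation_config")
}

# Gene names: the gold-standard essentials and suppressors come first so the
# default strong fractions (6/10 CE, 5/10 TS) coincide with the declared
# gold sets; extra genes get synthetic placeholder names.
.default_gene_names <- function(n, class) {
  canonical <- if (class == "CE") GOLD_CE_DEFAULT
               else c("TP53", "NF2", "ARNT", "AHR", "KIRREL")
  c(canonical, sprintf("%s%02d", class, seq_len(max(0, n)) ))[seq_len(n)]
}

.random_spacers <- function(n, len, existing = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- vapply(seq_len(need), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1))
    out <- unique(c(out, setdiff(cand, existing)))
  }
  out[seq_len(n)]
}

# One cassette's guide table. Dual-array positions carry one row per
# same-gene guide pair (ranks 1+4 or 2+3); the row's spacer is the first
# member's (read emission), and its activity is drawn for both members.
.position_guides_table <- function(config, position) {
  design <- config$design
  nuc <- design$cassette_nucleases[position]
  len <- SPACER_LEN[nuc]
  dual <- design$dual_gene_arrays[position]
  genes <- c(.default_gene_names(config$n_ce, "CE"),
             .default_gene_names(config$n_ts, "TS"))
  classes <- rep(c("CE", "TS"), c(config$n_ce, config$n_ts))
  if (dual) {
    rank_pairs <- list(c(1L, 4L), c(2L, 3L))
    gene_rows <- do.call(rbind, lapply(seq_along(genes), function(i) {
      data.frame(gene = genes[i], gene_class = classes[i],
                 rank = c(1L, 2L),
                 label = vapply(rank_pairs, function(rp)
                   sprintf("arr%d%d", rp[1], rp[2]), character(1)),
                 stringsAsFactors = FALSE)
    }))
    n_nht_rows <- config$n_nht %/% 2L
  } else {
    gene_rows <- do.call(rbind, lapply(seq_along(genes), function(i) {
      data.frame(gene = genes[i], gene_class = classes[i],
                 rank = seq_len(config$guides_per_gene),
                 label = sprintf("sg%d", seq_len(config$guides_per_gene)),
                 stringsAsFactors = FALSE)
    }))
    n_nht_rows <- config$n_nht
  }
  nht_rows <- if (n_nht_rows > 0) {
    data.frame(gene = "NHT", gene_class = "NHT",
               rank = NA_integer_,
               label = sprintf("nht%03d", seq_len(n_nht_rows)),
               stringsAsFactors = FALSE)
  }
  g <- rbind(gene_rows, nht_rows)
  g$guide_id <- sprintf("%s_%s_p%d", g$gene, g$label, position)
  g$nuclease <- nuc
  g$spacer <- .random_spacers(nrow(g), len)
  g$pam_context <- if (nuc == "AsCas12a")
    paste0("TTT", sample(c("A", "C", "G", "T"), nrow(g), replace = TRUE))
  else NA_character_
  g$label <- NULL
  g[, c("guide_id", "nuclease", "spacer", "gene", "gene_class", "rank",
        "pam_context")]
}

#' Draw the ground truth of a synthetic screen
#'
#' Builds the combination library of the configured design, draws per-gene
#' fitness and per-guide activity, applies the design's per-position
#' processing penalties, and computes each combination's expected log2 fold
#' change `mu = d * (f_A * a_i * pi1 + f_B * a_j * pi2)` under the additive
#' rule (NHT guides contribute zero fitness by construction). Dual-array
#' positions combine two same-gene member activities with the design's array
#' weights. Reproducible: identical config + seed give identical output.
#'
#' @param config a [simulation_config()].
#' @param seed integer RNG seed.
#' @return an object of class `true_effects`: `library`, `genes`
#'   (gene/class/fitness), `guides` (with drawn `activity`), `combos`
#'   (`combo_id`, raw per-position contributions `contrib1`/`contrib2`, and
#'   `mu`), and the `config`.
#' @export
draw_true_effects <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(seed, {
    design <- config$design
    g1 <- .position_guides_table(config, 1L)
    g2 <- .position_guides_table(config, 2L)
    lib <- build_library(list(g1, g2), design)
    gene_names <- c(.default_gene_names(config$n_ce, "CE"),
                    .default_gene_names(config$n_ts, "TS"))
    classes <- rep(c("CE", "TS"), c(config$n_ce, config$n_ts))
    n_strong_ce <- round(config$strong_ce_fraction * config$n_ce)
    n_strong_ts <- round(config$strong_ts_fraction * config$n_ts)
    strong <- c(seq_len(config$n_ce) <= n_strong_ce,
                seq_len(config$n_ts) <= n_strong_ts)
    f <- numeric(length(gene_names))
    is_ce <- classes == "CE"
    f[is_ce & strong] <- rnorm(sum(is_ce & strong), config$fitness_ce,
                               config$fitness_ce_sd)
    f[!is_ce & strong] <- rnorm(sum(!is_ce & strong), config$fitness_ts,
                                config$fitness_ts_sd)
    f[!strong] <- rnorm(sum(!strong), 0, config$weak_sd)
    genes <- data.frame(gene = c(gene_names, "NHT"),
                        class = c(classes, "NHT"),
                        fitness = c(f, 0), stringsAsFactors = FALSE)
    guides <- lib$guides
    draw_act <- function(n) config$activity_min +
      (1 - config$activity_min) * rbeta(n, config$activity_shape1,
                                        config$activity_shape2)
    act <- numeric(nrow(guides))
    for (p in 1:2) {
      rows <- which(guides$position == p)
      if (design$dual_gene_arrays[p]) {
        w <- design$array_weights
        act[rows] <- w[1] * draw_act(length(rows)) +
          w[2] * draw_act(length(rows))
      } else {
        act[rows] <- draw_act(length(rows))
      }
    }
    guides$activity <- act
    fit_of <- setNames(genes$fitness, genes$gene)
    act_of <- setNames(guides$activity, guides$guide_id)
    cmb <- lib$combinations
    d <- config$doublings
    contrib1 <- d * unname(fit_of[cmb$gene_a]) * unname(act_of[cmb$guide_a])
    contrib2 <- d * unname(fit_of[cmb$gene_b]) * unname(act_of[cmb$guide_b])
    combos <- data.frame(combo_id = cmb$combo_id,
                         contrib1 = contrib1, contrib2 = contrib2,
                         stringsAsFactors = FALSE)
    eff <- structure(list(library = lib, genes = genes, guides = guides,
                          combos = combos, config = config),
                     class = "true_effects")
    apply_design_penalty(eff, design)
  })
}

#' Apply (or swap) a design's processing penalties on drawn effects
#'
#' Rescales the raw per-position fitness contributions by the design's
#' per-position penalties and recombines them under the configured rule,
#' recomputing every combination's expected LFC `mu`. Array weights are part
#' of the drawn activities and are not re-applied here.
#'
#' @param effects a `true_effects`.
#' @param design a [library_design()] (or name) supplying the penalties.
#' @return the `true_effects` with updated `mu` and `penalty_design`.
#' @export
apply_design_penalty <- function(effects, design) {
  stopifnot(inherits(effects, "true_effects"))
  if (is.character(design)) design <- library_design(design)
  pi <- design$processing_penalty
  m1 <- pi[1] * effects$combos$contrib1
  m2 <- pi[2] * effects$combos$contrib2
  mu <- if (effects$config$combination_rule == "max") {
    ifelse(abs(m1) >= abs(m2), m1, m2)
  } else {
    m1 + m2 + effects$config$interaction
  }
  effects$combos$mu <- mu
  effects$penalty_design <- design$name
  effects
}

#' @export
print.true_effects <- function(x, ...) {
  cat("True effects for a ", nrow(x$combos), "-combination ",
      x$library$design$name, " screen\n", sep = "")
  cat(sprintf("  mu range: [%.2f, %.2f] over %g doublings\n",
              min(x$combos$mu), max(x$combos$mu), x$config$doublings))
  invisible(x)
}

#' Simulate a screen's count table from its ground truth
#'
#' Initial relative abundances are lognormal (representation skew) and
#' normalized; the library-reference sample is a multinomial draw at the
#' configured depth, and each end-timepoint replicate is a multinomial draw
#' with probabilities proportional to `initial * 2^mu`. With finite
#' `overdispersion` the replicate probabilities are first jittered by a
#' Dirichlet draw (Dirichlet-multinomial noise). In noiseless mode the
#' expected real-valued counts are returned instead; each sampled column
#' sums exactly to the depth either way.
#'
#' @param effects a `true_effects`.
#' @param seed RNG seed.
#' @param noiseless override the config's noiseless flag.
#' @param depth override the per-sample depth (default
#'   `coverage * n_combinations`); a depth below the number of combinations
#'   triggers a sub-coverage warning, not an error.
#' @return a `count_table` with samples `library` (role
#'   `library_reference`) and `end_rep<i>` (role `screen_end`).
#' @export
simulate_counts <- function(effects, seed = 1L, noiseless = NULL,
                            depth = NULL) {
  stopifnot(inherits(effects, "true_effects"))
  cfg <- effects$config
  noiseless <- noiseless %||% cfg$noiseless
  n <- nrow(effects$combos)
  depth <- depth %||% cfg$depth %||% (cfg$coverage * n)
  if (depth < n) warning("depth below the number of combinations (sub-coverage)")
  with_seed(seed, {
    w <- exp(rnorm(n, 0, cfg$rep_sigma))
    p0 <- w / sum(w)
    p1 <- p0 * 2^effects$combos$mu
    p1 <- p1 / sum(p1)
    samples <- data.frame(
      sample_id = c("library", sprintf("end_rep%d", seq_len(cfg$replicates))),
      role = c("library_reference", rep("screen_end", cfg$replicates)),
      replicate = c(1L, seq_len(cfg$replicates)),
      stringsAsFactors = FALSE)
    if (noiseless) {
      counts <- cbind(depth * p0,
                      matrix(rep(depth * p1, cfg$replicates), ncol = cfg$replicates))
    } else {
      draw_rep <- function() {
        p <- p1
        if (is.finite(cfg$overdispersion)) {
          gam <- rgamma(n, shape = cfg$overdispersion * p1, rate = 1)
          p <- gam / sum(gam)
        }
        rmultinom(1, depth, p)
      }
      counts <- cbind(rmultinom(1, depth, p0),
                      matrix(unlist(lapply(seq_len(cfg$replicates),
                                           function(i) draw_rep())),
                             ncol = cfg$replicates))
    }
    count_table(counts, effects$library$combinations, samples)
  })
}

#' Emit paired sequencing reads for one sample of a count table
#'
#' For each combination with count `c`, emits exactly `c` read pairs of the
#' form anchor + spacer + random tail (mate 1 carries the position-1 spacer,
#' mate 2 the position-2 spacer), in a deterministic shuffled order. An
#' optional error channel injects per-base substitutions at the stated rate.
#' Together with [count_pairs()] this gives an exact round trip at zero
#' error rate.
#'
#' @param counts a `count_table` with integer counts.
#' @param library the `combi_library` the counts refer to.
#' @param sample_id which sample to emit (default: the first).
#' @param anchor1,anchor2 constant regions placed 5' of the spacers.
#' @param read_len total read length; must fit anchor + spacer.
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed (tail bases, shuffling, errors).
#' @return list with character vectors `reads1` and `reads2`.
#' @export
emit_reads <- function(counts, library, sample_id = NULL,
                       anchor1, anchor2, read_len = 75L,
                       error_rate = 0, seed = 1L) {
  stopifnot(inherits(counts, "count_table"), inherits(library, "combi_library"),
            error_rate >= 0, error_rate < 1)
  sample_id <- sample_id %||% counts$samples$sample_id[1]
  cvec <- counts$counts[, sample_id]
  if (any(cvec != round(cvec))) stop("counts must be integers to emit reads")
  sp1 <- setNames(position_guides(library, 1L)$spacer,
                  position_guides(library, 1L)$guide_id)
  sp2 <- setNames(position_guides(library, 2L)$spacer,
                  position_guides(library, 2L)$guide_id)
  len1 <- nchar(anchor1) + unique(nchar(sp1))
  len2 <- nchar(anchor2) + unique(nchar(sp2))
  if (read_len < max(len1, len2))
    stop("read_len (", read_len, ") too short for anchor + spacer (",
         max(len1, len2), ")")
  with_seed(seed, {
    idx <- rep(seq_along(cvec), cvec)
    if (length(idx) == 0L)
      return(list(reads1 = character(0), reads2 = character(0)))
    idx <- idx[sample(length(idx))]
    cmb <- counts$combinations
    body1 <- paste0(anchor1, sp1[cmb$guide_a[idx]])
    body2 <- paste0(anchor2, sp2[cmb$guide_b[idx]])
    tail_chars <- function(nr, len) {
      if (len <= 0L) return(rep("", nr))
      m <- matrix(sample(c("A", "C", "G", "T"), nr * len, replace = TRUE),
                  nrow = nr)
      do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    }
    r1 <- paste0(body1, tail_chars(length(idx), read_len - len1))
    r2 <- paste0(body2, tail_chars(length(idx), read_len - len2))
    if (error_rate > 0) {
      mutate <- function(reads) {
        m <- matrix(unlist(strsplit(reads, ""), use.names = FALSE),
                    ncol = nchar(reads[1]), byrow = TRUE)
        sel <- which(runif(length(m)) < error_rate)
        if (length(sel)) {
          m[sel] <- vapply(m[sel], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        }
        apply(m, 1, paste, collapse = "")
      }
      r1 <- mutate(r1)
      r2 <- mutate(r2)
    }
    list(reads1 = unname(r1), reads2 = unname(r2))
  })
}

#' Simulate a complete screen (ground truth + counts)
#'
#' Convenience wrapper: draws the ground truth under `seed` and the count
#' table under `seed + 1`.
#'
#' @param config a [simulation_config()].
#' @param seed integer RNG seed.
#' @return list with `effects` (`true_effects`) and `counts`
#'   (`count_table`).
#' @export
simulate_screen <- function(config, seed = 1L) {
  effects <- draw_true_effects(config, seed)
  counts <- simulate_counts(effects, seed + 1L)
  list(effects = effects, counts = counts)
}
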