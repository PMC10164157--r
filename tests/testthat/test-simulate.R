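# Ground-truth model, dropout sampling, read emission, design penalties.

# Fixed fitness / unit activity config for closed-form mu checks.
exact_cfg <- function(design = "SpCas9", f_ce = -0.4, f_ts = 0.2, ...) {
  simulation_config(design = design, n_ce = 2, n_ts = 2, guides_per_gene = 2,
                    n_nht = 4, fitness_ce = f_ce, fitness_ce_sd = 0,
                    strong_ce_fraction = 1, fitness_ts = f_ts,
                    fitness_ts_sd = 0, strong_ts_fraction = 1, weak_sd = 0,
                    activity_min = 1, ...)
}

test_that("expected LFC follows the closed-form fitness model", {
  # all fitness zero: mu identically zero
  eff0 <- draw_true_effects(exact_cfg(f_ce = 0, f_ts = 0), seed = 1)
  expect_true(all(eff0$combos$mu == 0))

  # f_CE = -0.4, a = 1, pi = 1, d = 10: CE guide with NHT partner at -4,
  # CE x CE at -8 under the additive rule
  eff <- draw_true_effects(exact_cfg(), seed = 1)
  cmb <- eff$library$combinations
  ce_nht <- cmb$pair_class == "NHT-CE"
  expect_true(all(abs(eff$combos$mu[ce_nht] + 4) < 1e-12))
  ts_nht <- cmb$pair_class == "NHT-TS"
  expect_true(all(abs(eff$combos$mu[ts_nht] - 2) < 1e-12))
  ce_ce <- cmb$class_a == "CE" & cmb$class_b == "CE"
  expect_true(all(eff$combos$mu[ce_ce] == -8))
  expect_true(all(eff$combos$mu[cmb$pair_class == "NHT-NHT"] == 0))

  # processing penalty (0.3, 1): position-1 CE contribution scaled to -1.2
  pen <- library_design("SpCas9", processing_penalty = c(0.3, 1))
  effp <- apply_design_penalty(eff, pen)
  sel <- cmb$class_a == "CE" & cmb$class_b == "NHT"
  expect_true(all(abs(effp$combos$mu[sel] + 1.2) < 1e-12))

  # pi = (0, 1): position-1 guides contribute nothing
  p0 <- apply_design_penalty(eff, library_design("SpCas9",
                                                 processing_penalty = c(0, 1)))
  expect_true(all(p0$combos$mu[sel] == 0))

  # "max" rule keeps the dominant position contribution
  effm <- draw_true_effects(exact_cfg(combination_rule = "max"), seed = 1)
  expect_true(all(effm$combos$mu[ce_ce] == -4))
})

test_that("the simulator is seed-deterministic and conserves depth", {
  cfg <- simulation_config(n_ce = 3, n_ts = 3, guides_per_gene = 2,
                           n_nht = 4, coverage = 50)
  a <- simulate_screen(cfg, seed = 33)
  b <- simulate_screen(cfg, seed = 33)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$effects$combos, b$effects$combos)
  c2 <- simulate_screen(cfg, seed = 34)
  expect_false(identical(a$counts$counts, c2$counts$counts))

  # multinomial mode: every sampled column sums exactly to the depth
  n <- nrow(a$counts$counts)
  expect_true(all(colSums(a$counts$counts) == cfg$coverage * n))

  # sub-coverage warns but proceeds
  eff <- a$effects
  expect_warning(simulate_counts(eff, seed = 1, depth = n - 1),
                 "sub-coverage")
})

test_that("the noiseless pipeline recovers mu exactly", {
  cfg <- simulation_config(n_ce = 3, n_ts = 3, guides_per_gene = 2,
                           n_nht = 4, noiseless = TRUE, rep_sigma = 0.4)
  eff <- draw_true_effects(cfg, seed = 12)
  ct <- simulate_counts(eff, seed = 13)
  lfc <- guide_lfc(normalize_counts(ct), "library")
  expect_equal(lfc$lfc, eff$combos$mu, tolerance = 1e-10)

  # gene-pair values equal the median of the constituent mu values
  gp <- gene_pair_lfc(lfc)
  mu <- eff$combos$mu
  ga <- ifelse(lfc$class_a == "NHT", "NHT", lfc$gene_a)
  gb <- ifelse(lfc$class_b == "NHT", "NHT", lfc$gene_b)
  med <- tapply(mu, paste(ga, gb, sep = "|"), median)
  expect_equal(gp$lfc, as.numeric(med[paste(gp$gene_a, gp$gene_b, sep = "|")]),
               tolerance = 1e-10)
})

test_that("null screens center on zero LFC at scale", {
  cfg <- simulation_config(n_ce = 3, n_ts = 3, guides_per_gene = 2,
                           n_nht = 6, fitness_ce = 0, fitness_ce_sd = 0,
                           fitness_ts = 0, fitness_ts_sd = 0, weak_sd = 0,
                           coverage = 100)
  sim <- simulate_screen(cfg, seed = 55)
  lfc <- guide_lfc(normalize_counts(sim$counts), "library")
  # every LFC shares the per-sample NHT-NHT median normalization term, so
  # the null spread of the mean is dominated by that shift: for counts
  # around lambda, sd(log2 count) ~ 1/(ln2 sqrt(lambda)) and the median of
  # m such values has sd ~ 1.2533/sqrt(m) of it, for reference + end
  lambda <- cfg$coverage
  m_nht <- sum(lfc$pair_class == "NHT-NHT")
  se_shift <- sqrt(2) * 1.2533 / sqrt(m_nht) / (log(2) * sqrt(lambda))
  se_mean <- sd(lfc$lfc) / sqrt(nrow(lfc))
  expect_lt(abs(mean(lfc$lfc)), 3 * (se_shift + se_mean))
  # and the NHT-NHT baseline itself is centred
  expect_lt(abs(median(lfc$lfc[lfc$pair_class == "NHT-NHT"])), 0.1)
})

test_that("lowering a position's penalty shrinks its single-guide range", {
  cfg <- simulation_config(n_ce = 4, n_ts = 4, guides_per_gene = 2,
                           n_nht = 6, noiseless = TRUE)
  eff_full <- draw_true_effects(cfg, seed = 40)
  rng_at <- function(eff, pi1) {
    e <- apply_design_penalty(eff, library_design("SpCas9",
                                                  processing_penalty = c(pi1, 1)))
    ct <- simulate_counts(e, seed = 41)
    lfc <- guide_lfc(normalize_counts(ct), "library")
    effect_size_range(single_guide_lfc(lfc, position = 1)$lfc)
  }
  r_full <- rng_at(eff_full, 1)
  r_half <- rng_at(eff_full, 0.5)
  r_tenth <- rng_at(eff_full, 0.1)
  expect_gt(r_full, r_half)
  expect_gt(r_half, r_tenth)
})

test_that("per-design penalties reproduce the qualitative design ordering", {
  ranges <- vapply(c("SpCas9", "enAsCas12a", "CHyMErA", "CHyMErA_v2"),
                   function(d) {
    cfg <- simulation_config(design = d, n_ce = 4, n_ts = 4,
                             guides_per_gene = 2, n_nht = 8,
                             noiseless = TRUE)
    sim <- simulate_screen(cfg, seed = 60)
    lfc <- guide_lfc(normalize_counts(sim$counts), "library")
    effect_size_range(lfc)
  }, numeric(1))
  # single-promoter SpCas9 beats enAsCas12a beats the hybrid-transcript
  # CHyMErA, and dual Cas12a arrays roughly double CHyMErA's range
  expect_gt(ranges[["SpCas9"]], ranges[["enAsCas12a"]])
  expect_gt(ranges[["enAsCas12a"]], ranges[["CHyMErA"]])
  expect_gt(ranges[["CHyMErA_v2"]] / ranges[["CHyMErA"]], 1.5)
})

test_that("emit_reads respects counts and its substitution error budget", {
  lib <- tiny_library(c("CCT4", "TP53"), c("CE", "TS"), n_nht = 2)
  ct <- tiny_count_table(lib, rep(0L, nrow(lib$combinations)))
  anchor1 <- "TATCTTGTGGAAAGGACGAA"
  anchor2 <- "CACCGAGTCGGTGCTTTTTT"
  # empty table emits empty streams
  rd0 <- emit_reads(ct, lib, "s1", anchor1, anchor2, read_len = 60)
  expect_length(rd0$reads1, 0)
  expect_error(emit_reads(ct, lib, "s1", anchor1, anchor2, read_len = 30),
               "too short")

  # binomial oracle: with per-base substitution rate p, a read pair is
  # recoverable unless a spacer carries >= 2 errors or an anchor >= 3
  p <- 0.01
  n_pairs <- 4000L
  ct1 <- tiny_count_table(lib, c(n_pairs, rep(0L, nrow(lib$combinations) - 1)))
  rd <- emit_reads(ct1, lib, "s1", anchor1, anchor2, read_len = 60,
                   error_rate = p, seed = 91)
  out <- count_pairs(rd$reads1, rd$reads2, lib, anchor1, anchor2)
  p_sp <- function(len) 1 - pbinom(1, len, p)   # spacer >= 2 errors
  p_an <- function(len) 1 - pbinom(2, len, p)   # anchor >= 3 edits
  p_keep_mate <- (1 - p_sp(20)) * (1 - p_an(20))
  expected <- n_pairs * p_keep_mate^2
  sd_exp <- sqrt(n_pairs * p_keep_mate^2 * (1 - p_keep_mate^2))
  expect_lt(abs(sum(out$counts) - expected), 4 * sd_exp + 1)
})

test_that("dual-array designs build the reduced per-cassette layout", {
  cfg <- simulation_config(design = "enAsCas12a_dual", n_ce = 2, n_ts = 2,
                           guides_per_gene = 4, n_nht = 8)
  eff <- draw_true_effects(cfg, seed = 2)
  g1 <- position_guides(eff$library, 1)
  # 4 genes x 2 arrays + 8/2 NHT arrays = 12 elements per cassette
  expect_equal(nrow(g1), 12L)
  expect_equal(nrow(eff$library$combinations), 144L)
  # arrays pair ranks (1,4) and (2,3): two arrays per gene
  expect_equal(sum(g1$gene == "CCT4"), 2L)
})
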