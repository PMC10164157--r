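# Normalization, LFC arithmetic, aggregation, ranges, summaries,
# correlations.

test_that("normalize_counts divides by depth and the NHT-NHT median", {
  # hand arithmetic: counts (A:10, B:30, N1:20, N2:40), NHT-NHT set {N1,N2};
  # totals-normalized (0.1, 0.3, 0.2, 0.4), NHT-NHT median 0.3
  fake <- combscreen:::count_table(
    matrix(c(10L, 30L, 20L, 40L), ncol = 1),
    data.frame(combo_id = c("A", "B", "N1", "N2"),
               guide_a = c("a1", "a2", "n1", "n2"),
               guide_b = c("b1", "b2", "m1", "m2"),
               gene_a = c("G1", "G2", "NHT", "NHT"),
               gene_b = c("H1", "H2", "NHT", "NHT"),
               class_a = c("CE", "CE", "NHT", "NHT"),
               class_b = c("CE", "CE", "NHT", "NHT"),
               pair_class = c("CE-CE", "CE-CE", "NHT-NHT", "NHT-NHT"),
               stringsAsFactors = FALSE),
    data.frame(sample_id = "s", role = "screen_end", replicate = 1L))
  nrm <- normalize_counts(fake)
  expect_equal(unname(nrm$values[, 1]), c(1 / 3, 1, 2 / 3, 4 / 3))
  expect_equal(nrm$normalization$total, 100)

  # doubling all counts changes nothing
  fake2 <- fake
  fake2$counts <- fake$counts * 2L
  expect_equal(normalize_counts(fake2)$values, nrm$values)

  # idempotence on its own output
  again <- normalize_counts(nrm)
  expect_equal(again$values, nrm$values)
})

test_that("the NHT-NHT median equals one in every normalized sample", {
  cfg <- simulation_config(n_ce = 3, n_ts = 3, guides_per_gene = 2,
                           n_nht = 6, coverage = 30)
  sim <- simulate_screen(cfg, seed = 9)
  nrm <- normalize_counts(sim$counts)
  nht <- nrm$combinations$pair_class == "NHT-NHT"
  for (j in seq_len(ncol(nrm$values)))
    expect_equal(median(nrm$values[nht, j]), 1)
})

test_that("guide_lfc computes pseudocounted log2 ratios per replicate", {
  v <- cbind(ref = c(2, 1, 1, 4), e1 = c(8, 0, 1, 4))
  nt <- fake_normalized(v)
  lfc <- guide_lfc(nt, "ref", pseudocount = 0.5)
  expect_equal(lfc$lfc, c(2, log2(0.5 / 1.5), 0, 0))

  # self-comparison is identically zero for any pseudocount
  self <- fake_normalized(cbind(ref = c(2, 0, 7), end = c(2, 0, 7)))
  expect_true(all(guide_lfc(self, "ref", pseudocount = 0.3)$lfc == 0))
  expect_true(all(guide_lfc(self, "ref", pseudocount = 2)$lfc == 0))

  # zero values demand a positive pseudocount
  expect_error(guide_lfc(nt, "ref", pseudocount = 0), "pseudocount")

  # replicate aggregation: mean, median, pooled
  v3 <- cbind(ref = c(1, 1), e1 = c(2, 4), e2 = c(8, 4), e3 = c(4, 1))
  nt3 <- fake_normalized(v3)
  expect_equal(guide_lfc(nt3, "ref", aggregate = "mean")$lfc,
               c(mean(c(1, 3, 2)), mean(c(2, 2, 0))))
  expect_equal(guide_lfc(nt3, "ref", aggregate = "median")$lfc, c(2, 2))
  expect_equal(guide_lfc(nt3, "ref", aggregate = "pooled")$lfc,
               c(log2(14 / 3), log2(3)))
})

test_that("gene_pair_lfc aggregates guide pairs by median with NHT collapsed", {
  lib <- tiny_library(c("CCT4", "TP53"), c("CE", "TS"), n_nht = 2,
                      guides_per_gene = 2)
  nt <- fake_normalized(cbind(ref = rep(1, nrow(lib$combinations)),
                              end = rep(1, nrow(lib$combinations))))
  nt$combinations <- lib$combinations
  lfc <- guide_lfc(nt, "ref")
  # plant known values: CCT4 x CCT4 block (2x2 = 4 combos)
  sel <- lfc$gene_a == "CCT4" & lfc$gene_b == "CCT4"
  expect_equal(sum(sel), 4L)
  lfc$lfc[sel] <- c(-1, -2, -3, -10)
  gp <- gene_pair_lfc(lfc)
  row <- gp[gp$gene_a == "CCT4" & gp$gene_b == "CCT4", ]
  expect_equal(row$lfc, -2.5)
  expect_equal(row$n, 4L)
  # NHT collapses to a single pseudo-gene: 2 guides x 2 NHT per side
  nhtrow <- gp[gp$gene_a == "NHT" & gp$gene_b == "NHT", ]
  expect_equal(nhtrow$n, 4L)
  expect_equal(nrow(gp), 9L) # (CCT4, TP53, NHT)^2 ordered pairs

  # odd-n median and identity case
  expect_equal(median(c(-1, -2, -3)), -2)
  vals <- 1:16
  expect_equal(median(vals), 8.5) # midpoint of 8th/9th order statistics

  # permuting guide order never changes gene-pair values
  perm <- lfc[sample(nrow(lfc)), ]
  class(perm) <- class(lfc)
  gp2 <- gene_pair_lfc(perm)
  key <- function(g) paste(g$gene_a, g$gene_b)
  expect_equal(gp2$lfc[match(key(gp), key(gp2))], gp$lfc)
})

test_that("effect_size_range is a shift-invariant, scale-equivariant span", {
  expect_equal(effect_size_range(c(-4, 0, 3)), 7)
  expect_equal(effect_size_range(rep(2.2, 5)), 0)
  x <- rnorm(50)
  expect_equal(effect_size_range(x + 13.7), effect_size_range(x))
  expect_equal(effect_size_range(2.5 * x), 2.5 * effect_size_range(x))
  expect_error(effect_size_range(c(1, Inf)), "non-finite")
})

test_that("class_summary separates CE, restricted TS, and NHT populations", {
  lib <- tiny_library(c("CCT4", "TP53", "AHR"), c("CE", "TS", "TS"),
                      n_nht = 1)
  nt <- fake_normalized(cbind(ref = rep(1, nrow(lib$combinations)),
                              end = rep(1, nrow(lib$combinations))))
  nt$combinations <- lib$combinations
  lfc <- guide_lfc(nt, "ref")
  cs <- class_summary(lfc)
  # default TS population is restricted to TP53/NF2: AHR-only pairs excluded
  expect_equal(cs$n[cs$class == "TS"],
               sum((lfc$gene_a == "TP53" | lfc$gene_b == "TP53") &
                   lfc$class_a != "CE" & lfc$class_b != "CE"))
  expect_equal(cs$n[cs$class == "NHT"], 1L)

  # hand arithmetic on a planted class
  lfc$lfc[lfc$pair_class == "NHT-NHT"] <- 0
  sel <- which(lfc$class_a == "CE" | lfc$class_b == "CE")[1:3]
  lfc$lfc[] <- 0
  lfc$lfc[sel] <- c(1, 2, 6)
  lfc2 <- lfc[sel, ]
  class(lfc2) <- class(lfc)
  cs2 <- class_summary(lfc2)
  expect_equal(cs2$mean[cs2$class == "CE"], 3)
  expect_equal(cs2$median[cs2$class == "CE"], 2)
})

test_that("single_guide_lfc decomposes via NHT partners", {
  lib <- tiny_library(c("CCT4", "TP53"), c("CE", "TS"), n_nht = 4,
                      guides_per_gene = 1)
  nt <- fake_normalized(cbind(ref = rep(1, nrow(lib$combinations)),
                              end = rep(1, nrow(lib$combinations))))
  nt$combinations <- lib$combinations
  lfc <- guide_lfc(nt, "ref")
  g1 <- position_guides(lib, 1)
  ce_guide <- g1$guide_id[g1$gene == "CCT4"]
  sel <- lfc$guide_a == ce_guide & lfc$class_b == "NHT"
  expect_equal(sum(sel), 4L)
  lfc$lfc[sel] <- c(-1, -3, 0, -2)
  sg <- single_guide_lfc(lfc, position = 1)
  expect_equal(sg$lfc[sg$guide_id == ce_guide], -1.5) # even-n median
  expect_equal(sg$n[sg$guide_id == ce_guide], 4L)
  expect_false(any(sg$gene_class == "NHT")) # NHT guides excluded
  # gene level aggregates guide medians per gene
  sgg <- single_guide_lfc(lfc, position = 1, level = "gene")
  expect_equal(sgg$lfc[sgg$gene == "CCT4"], -1.5)
})

test_that("correlate matches closed-form Pearson and Spearman oracles", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  expect_equal(correlate(x, -x)$slope, -1)
  expect_equal(correlate(x, 2 * x + 1)$intercept, 1)
  # rank formula by hand: d = (0, -1, 1, 0), rho = 1 - 6*2/(4*15) = 0.8
  expect_equal(correlate(x, c(1, 3, 2, 4), "spearman")$r, 0.8)
  # non-finite pairs are dropped and counted
  r <- correlate(c(x, NA), c(2 * x, 5))
  expect_equal(r$n_dropped, 1L)
  expect_equal(r$r, 1)
  # zero variance flags rather than errors
  z <- correlate(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(z$r))
  expect_true(isTRUE(attr(z, "undefined")))
  expect_error(correlate(c(1, 2), c(1, 2)), "fewer than 3")
})
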