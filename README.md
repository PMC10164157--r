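# combscreen

Analysis and simulation of **combinatorial and orthogonal CRISPR dropout
screens** read out by paired-guide sequencing.

Dual-cassette CRISPR constructs express two guides per cell — from two
promoters (h7SK/hU6), as a hybrid Cas9–Cas12a transcript that must be
processed, or as arrayed dual-gRNAs — and pooled screens over such libraries
measure the fitness consequence of every guide pair. `combscreen` covers the
computational side of these experiments for analysts who have paired-end
amplicon reads (or pre-made count tables) and want defensible, reproducible
screen metrics:

* **Quantification** — anchored extraction of the spacer behind each
  cassette's constant region (edit-distance tolerance, default 0.1 of the
  anchor length), bounded-Hamming matching against the designed library
  (exact match wins; unique 1-mismatch otherwise; ties are ambiguous), and
  per-category accounting of every unassigned read pair
  (`no_anchor`, `no_match`, `ambiguous`, `not_in_library`).
* **QC** — Lorenz curves and the P90/P10 skew ratio (nearest-rank
  percentiles; a skew below 2.5 marks a uniform library).
* **Screen metrics** — per-sample normalization to total depth and the
  median of NHT-NHT (non-human-targeting control) combinations, so the
  neutral baseline sits at 1; guide-pair log2 fold changes
  `LFC = log2(end / reference)` with a zero-guarded pseudocount; median
  aggregation to gene pairs; effect-size range (max − min LFC);
  class-separation summaries; single-guide decomposition via NHT partners;
  replicate and cross-screen correlations.
* **Benchmarking** — gold standards from dependency scores (or the declared
  6 core-essential / 5 tumor-suppressor / 9 negative gene sets) and ROC/AUC
  by the midrank Mann–Whitney construction: AUC = P(positive ranks above
  negative), ties counted 1/2, orientation `low_is_positive` for essential
  (depleting) genes and `high_is_positive` for suppressors.
* **Simulation** — screens with known ground truth. Each combination's
  expected LFC is `mu = d (f_A a_i pi_1 + f_B a_j pi_2)`: `d` doublings,
  per-gene fitness `f` (log2 per doubling), per-guide activity `a` in [0,1],
  and per-position RNA-processing penalties `pi` that emulate
  hybrid-transcript (CHyMErA-like) inactivity. Counts are multinomial draws
  at the configured coverage over a lognormal initial representation, and
  reads can be emitted down to paired FASTQ.

## Worked example

Simulate the default screen — a 160 × 160 SpCas9 library (10 CE + 10 TS
genes × 4 guides + 80 NHT controls per cassette), 10 doublings, 100-fold
coverage, two replicates — and analyse it:

```r
library(combscreen)

cfg <- simulation_config()            # the default study conditions
sim <- simulate_screen(cfg, seed = 42)
sim$counts
#> Count table: 25600 combinations x 3 sample(s)
#>  sample_id              role replicate
#>    library library_reference         1
#>   end_rep1        screen_end         1
#>   end_rep2        screen_end         2

nrm <- normalize_counts(sim$counts)
lfc <- guide_lfc(nrm, reference = "library")
effect_size_range(lfc)                # 12.29  (guide-pair level)
gp  <- gene_pair_lfc(lfc)
effect_size_range(gp)                 # 10.31  (gene-pair level)

class_summary(gp)
#>   class   n        mean      median
#> 1    CE 320 -1.51370188 -2.05066256
#> 2   NHT   1 -0.01081651 -0.01081651
#> 3    TS  40  2.72044045  2.55018430

gold <- gold_standard(library = sim$effects$library)
evaluate_screen(lfc, gold)$roc_ce
#> ROC: AUC = 1.000 (5568 positives vs 7056 negatives, low_is_positive)

qc_report(sim$counts)
#>   sample_id      skew lorenz_area n_zero
#> 1   library  2.269841   0.4113069      0
#> 2  end_rep1 38.500000   0.2140892    307
#> 3  end_rep2 38.500000   0.2142811    291
```

Reading the output: CE-targeting gene pairs drop (negative mean LFC), the
TP53/NF2-driven TS population enriches, the NHT-NHT baseline sits at zero,
and depletion of the true essentials is fully recoverable (AUC 1.0 at this
noise level — real screens land near 0.8, see the vignette on what the
simulator does not model). The plasmid library passes the uniformity rule
(skew 2.27 < 2.5); the end timepoints are skewed by design, because dropout
is the signal.

Real data enter the same way: `count_pairs()` on FASTQ (with your
construct's constant-region anchors), or `read_count_table()` +
`annotate_combinations()` for externally produced tables, then the identical
downstream path — see `?run_pipeline` for the one-call version.

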