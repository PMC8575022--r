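# dismir

Read-level cancer detection from plasma cell-free DNA (cfDNA)
whole-genome bisulfite sequencing (WGBS).

At low sequencing depth there are too few reads per locus for
locus-level methylation statistics, so this package classifies every
read individually and aggregates. It is aimed at computational
biologists working on methylation-based liquid biopsy who need a
complete, inspectable implementation of the approach — including a
synthetic-data generator, because the real cohorts in this domain are
controlled-access.

## Method

1. **Switching regions.** The genome is tiled into 500-bp bins; reads
   need ≥ 3 CpG calls to qualify. With `H_min` the minimum per-read
   methylation ratio among healthy-plasma reads in a bin and `T_min`
   the minimum among tumor-tissue reads, a bin is a (hypomethylated)
   switching region when `H_min − T_min > 0.3`. Reads below `H_min`
   are *switching reads*; their fraction (FSR) is a model-free
   baseline. A hypermethylated variant compares maxima at threshold
   0.5.
2. **Per-read d-score.** Every qualifying read from a switching region
   is trimmed (5 bp at 5′, cut to L = 66) and encoded as an L × 5
   matrix (one-hot bases + methylation channel). A
   convolution → max-pool → bidirectional-LSTM → convolution → dense
   network (trained in-package on BLAS matrix ops, gradients verified
   numerically) maps each read to a d-score in [0, 1] — the
   probability it is tumor-derived. An ensemble of identically
   configured trainings is averaged.
3. **Tumor fraction.** For a test sample with d-scores `d_i`, the
   posterior `P(r) = Π_i [r·d_i + (1 − r)(1 − d_i)]` is maximized over
   the grid r = 0, 0.001, …, 1 (in log domain, d clipped at 1e-6).
   The maximizer r̂ is the cancer-risk score; cohorts are compared by
   rank AUC on r̂.
4. **Interpretation.** Kernel position frequency matrices (including a
   five-letter variant with methylated-C), MEME export,
   CpG-demethylation perturbation scores (Δ_single / Δ_all / Δ_sum),
   Mann–Whitney AUC effect sizes, Fisher's combined probability test
   and a quadrant/odds-ratio summary.
5. **Simulator.** Synthetic references with planted CpG sites,
   class-dependent per-read methylation levels, optional planted
   motifs, mixtures at known tumor fraction, and full ground truth.

## Worked example

```r
library(dismir)

# fully synthetic study: reference + 18 healthy / 9 tumor training cohort
ref <- simulate_reference(sim_config(), seed = 11)
design <- data.frame(
  sample_id   = c(sprintf("H%02d", 1:18), sprintf("T%02d", 1:9)),
  class_label = c(rep("healthy_plasma", 18), rep("tumor_tissue", 9)),
  true_r      = c(rep(0, 18), rep(1, 9)),
  n_reads     = 550)
simulate_cohort(ref, design, "cohort", seed = 5)

manifest <- read_manifest("cohort/manifest.tsv")
regions  <- dismir_detect_regions(manifest, "cohort/chrom.sizes")
nrow(regions)
#> [1] 30

ts  <- dismir_training_set(manifest, regions, seed = 3)
cfg <- dismir_model_config(conv1_filters = 24, lstm_units = 16,
                           conv2_filters = 16, dense_units = c(32, 8),
                           epochs = 30, patience = 6, batch_size = 64)
ens <- train_dismir_ensemble(ts$train, cfg, n_members = 2)

# a test-plasma sample carrying 20% tumor-derived reads
sm  <- simulate_sample(ref, "test_plasma", true_r = 0.2,
                       n_reads = 4000, sample_id = "pt1", seed = 99)
est <- dismir_estimate_sample(ens, sm$reads, regions)
est
#> Tumor fraction estimate: r_hat = 0.307 (n = 370 reads, grid step 0.001)
fsr(sm$reads, regions)
#> [1] 0.2

# a healthy sample under the same model
h <- simulate_sample(ref, "test_plasma", true_r = 0, n_reads = 4000,
                     sample_id = "h1", seed = 100)
dismir_estimate_sample(ens, h$reads, regions)
#> Tumor fraction estimate: r_hat = 0.000 (n = 332 reads, grid step 0.001)
```

30 of the 330 bins are called switching regions (the simulation
planted 30). For the sample whose true tumor-read fraction is 0.2 the
estimate is r̂ = 0.307 from 370 scored reads (miscalibration upward is
expected at this training size; ranking is what matters) and the
model-free FSR baseline gives 0.20, while the healthy sample comes out
at r̂ = 0 — so r̂ separates the cohorts.

A thin CLI over the same functions is in `inst/cli/dismir.R`
(`simulate`, `regions`, `train`, `score`, `estimate` subcommands).

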