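---
title: "Read-level cancer detection from cfDNA methylomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-level cancer detection from cfDNA methylomes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Plasma cell-free DNA (cfDNA) of a cancer patient is a mixture: most
fragments come from normal hematopoietic turnover, a small fraction
from the tumor. Whole-genome bisulfite sequencing (WGBS) reads carry a
per-CpG methylation call, and tumor-derived fragments show aberrant
methylation — in hepatocellular carcinoma, predominantly genome-wide
hypomethylation. At the low sequencing depths that keep a liquid
biopsy affordable (1–3x, or 100-fold less after subsampling), there
are too few reads per locus for locus-level statistics, so this
package works at *read resolution*: classify every individual read,
then aggregate.

The pipeline has four stages, each its own module:

1. **Switching regions** — cancer-specific DMRs defined by per-read
   extrema rather than mean shifts.
2. **Per-read deep model** — a joint sequence + methylation classifier
   that emits a d-score in [0, 1] per read, the probability the read
   is tumor-derived.
3. **Tumor-fraction estimate** — a one-parameter mixture posterior
   over a sample's d-scores, maximized on a grid; the estimate r-hat
   is the cancer-risk score.
4. **Interpretation** — kernel position frequency matrices (PFMs) and
   CpG-perturbation analysis of the trained network.

A fifth module, the simulator, generates complete synthetic cohorts
with ground truth, because the real training data of this method's
domain are controlled-access.

# Switching regions

The genome is tiled into non-overlapping 500-bp bins anchored at
position 0. Only reads with **three or more CpG calls** enter any
statistic, and each read belongs to the single bin containing its
start coordinate (the 5'-most aligned base) — a deterministic,
order-independent rule. Bins with fewer than 25 pooled qualifying
reads across all training samples are dropped; we read the pooled
interpretation deliberately, since a per-sample cutoff at 1–3x depth
would discard nearly the whole genome. Both classes must contribute at
least one read, otherwise the class extrema below do not exist.

For the hypomethylated direction let `H_min` be the *minimum* per-read
methylation ratio among healthy-plasma reads in a bin and `T_min` the
minimum among tumor-tissue reads. The bin is a **switching region**
when

    H_min - T_min > t,      t = 0.3 by default,

with strict inequality, and a read inside such a region is a
**switching read** when its ratio is strictly *below* `H_min`. The
hypermethylated direction mirrors this with maxima and a conventional
threshold of 0.5. Extrema are true min/max, not quantiles: the method
is designed around the extreme reads, which is what makes it sensitive
at low depth. An optional `extrema_quantile` softens this for noise
experiments but defaults to off.

All reads with three or more CpGs from switching regions — not only
switching reads — feed the model. The fraction of switching reads
(FSR) among them is kept as a model-free baseline statistic.

# The per-read classifier

Each read is trimmed 5 bp at the 5' end (adapter caution) and cut to
L = 66 bases; shorter reads are rejected rather than padded, since any
padding symbol would distort sequence statistics. A read becomes an
L x 5 matrix: one-hot A/C/G/T columns (all zero for N) plus a
methylation column that is 1 exactly at methylated-CpG cytosines.
Unmethylated C and non-CpG positions are both 0 — the base channels
already distinguish C from non-C.

The network is a DanQ-style hybrid: 1-D convolution (24–64 kernels of
width 8, ReLU), max-pooling (width 2), a bidirectional LSTM (16–32
units per direction), a second 1-D convolution, flatten, and three
dense layers ending in a single sigmoid unit. Training minimizes
binary cross-entropy with Adam (lr 1e-3, batch 64–128), an internal
10% validation split and early stopping (patience 3–6). Because no
deep-learning framework is a dependency, the forward and backward
passes are implemented directly on BLAS-backed matrix algebra inside
the package; the gradients are verified against central finite
differences in the test suite (relative error below 1e-4 on every
parameter tensor).

Classes are balanced *before* training by downsampling the majority
class (no class weights), and 20% of the balanced pool is reserved —
excluded from training — for kernel visualization. The ensemble
protocol trains the same data 10 times with seeds `seed + 0..9` and
averages the per-read d-scores; the scaled-down analyses in this
package's tests and acceptance script use 2 members, which already
removes most seed-to-seed variance on the strong synthetic signal.
Default layer sizes are this package's own choices at DanQ scale; they
are configurable in `dismir_model_config()`.

# Tumor-fraction estimation

Treating d-scores as independent per-read tumor probabilities, the
posterior of a sample at tumor fraction r is

    P(r) = prod_i [ r * d_i + (1 - r) * (1 - d_i) ].

The product underflows for realistic read counts, so the computation
is done in the log domain with d-scores clipped to
[1e-6, 1 - 1e-6] (configurable); clipping changes the argmax
immaterially but keeps every term finite. `P` is evaluated on the grid
r = 0, 0.001, ..., 1 and r-hat is the *smallest* maximizing grid point
— the conservative tie-break, returning the lowest cancer risk on a
flat posterior. The log-posterior is concave in r, so the grid argmax
is cross-checked against golden-section maximization in the acceptance
suite (agreement within one grid step over 1000 random d-score sets).

Cohort-level discrimination is summarized by the rank-based AUC
(Mann–Whitney U over pairs, ties at half weight) between the r-hat
values of cancer and healthy test samples.

# Interpretation

**Kernel PFMs.** Every first-convolution kernel is slid over every
reserved read at every valid offset (no padding; edge positions simply
contribute fewer windows). The top 1% of (read, offset) activations
are superposed, weighted by activation value, into a width x 4 base
PFM and a width x 5 PFM whose cytosine column is split into
unmethylated C and methylated M. The 4-letter PFMs export to MEME
minimal format (uniform background) for external motif comparison;
the package computes the alignment itself only for planted-motif
checks, as the best ungapped Pearson correlation between probability
columns. A read's scalar activation for ranking
(`kernel_activated_reads`, top 0.1%) is its maximum over offsets; the
PFM uses all per-offset values. The reduction to a maximum is a
documented choice — the alternative (mean) blurs positional signal.

**Perturbation deltas.** Across a region, every read-length window
(stride 1) with at least three CpGs in its scored portion is
synthesized with all CpGs methylated (baseline), each single CpG
demethylated (delta_single), and all CpGs demethylated (delta_all).
The sign convention is `delta = d(perturbed) - d(baseline)`.
`delta_sum`, the sum of single-site deltas, equals `delta_all` exactly
for any scorer affine in the methylation channel — a diagnostic the
tests exploit — while the trained network is *super-additive*: the
magnitude of `delta_all` stochastically dominates `delta_sum`
(effect size well above 0.5 on the synthetic scenario). That is the
desired noise-filter behavior: single CpG flips, the dominant WGBS
technical noise, move the d-score much less than a coordinated
methylation change.

**Statistics.** Effect sizes between delta distributions use the
Mann–Whitney AUC, `P(Y > X) + 0.5 P(Y = X)`. P-value-like evidence
across the 10 ensemble trainings combines with Fisher's method
(chi-square with 2k df); E-values above 1 are truncated to 1 with a
warning. The quadrant summary cross-tabulates kernels by
"ES(delta_all) > 0.5 and ES(delta_sum) < 0.5" against motif-match
flags, reporting the cross-product odds ratio (Haldane 0.5 correction
when a cell is zero) and Fisher's exact p.

# The simulator

The simulator generates what the method assumes and nothing more:

- Reference chromosomes of i.i.d. uniform background sequence with CpG
  dinucleotides planted at density 0.1 per bp and accidental CGs
  removed, so the CpG site list is exact. The density is at the
  CpG-island end of the genome — appropriate because switching regions
  in practice are CpG-dense — and gives 80-bp reads ~7 CpG calls, well
  above the 3-CpG filter.
- 30 switching bins among 330. Healthy reads draw a per-read
  methylation level from Beta(25.5, 4.5) (mean 0.85); tumor reads in
  switching bins from Beta(4.5, 25.5) (mean 0.15); tumor reads
  elsewhere behave like healthy ones. Each CpG is then methylated
  i.i.d. at the read's level, and each call flips with probability
  0.05 (bisulfite miscalls). Drawing the level once per read creates
  the read-level bimodality that the extrema definition exploits;
  purely site-level noise would not.
- Mixtures: each test-plasma read is tumor-origin with probability
  `true_r`; tissue and healthy samples force 1 and 0.
- Optional planted motifs (per-read insertion into one class, and/or
  overwritten into reference switching bins) and optional
  reverse-strand reads with proper CpG-dyad methylation transfer.

What it does **not** emulate: real genome composition and repeats,
fragment-length biology, copy-number signal, batch effects, mapping
error. Green tests therefore demonstrate internal correctness and
end-to-end recoverability of the planted signal, not clinical
performance.

The training-cohort design in tests mirrors the method's real-world
regime: 18 healthy plasma + 9 tumor tissue samples at ~45 pooled
qualifying reads per bin. Depth matters in a specific way: the class
*minimum* of per-read ratios degrades as pooled depth grows (a single
noisy healthy read caps `H_min`), so the extrema criterion is most
informative at tens of reads per bin — the regime the method was
designed for. This is a property of the statistic, not of this
implementation.

# Numerical and degenerate-input choices

- Coordinates are 0-based half-open everywhere internally and in BED;
  SAM positions are converted on ingest. Reads stay in
  aligner-reported orientation (raw and reverse-complement reads are
  distinct model inputs by design).
- Methylation alphabet is CpG-context only; other contexts map to `.`
  on SAM import.
- Duplicate read identifiers are tolerated (multi-segment data);
  joins key on (read_id, chrom, start).
- `methylation_ratio` and `fsr` raise errors on empty denominators
  rather than returning NaN.
- Ties: pooling takes the first maximum; r-hat takes the smallest
  maximizing grid point; read ranking breaks ties by stable input
  order.
- Paired-end mates are treated as independent reads; mate merging is
  out of scope and may differ from upstream pipelines that collapse
  fragments.

# Problem sizes used by the test and acceptance suites

All heavyweight analyses run on the scenario above: ~14k simulated
training reads of which ~900 balanced switching-region reads train the
network, test samples of 2000–4000 reads (~200–550 scored reads each),
a 40000-read sample for depth subsampling, and 1000 random d-score
vectors (10 to 10^4 scores) for the estimator cross-check. These sizes
were chosen so the complete suite runs in minutes on one CPU while
every stage still has enough signal to be tested against its oracle;
they are small-scale study conditions, not tuning knobs.

# Known limitations

- The original network's exact layer sizes and optimizer settings are
  not public; the defaults here are declared substitutes at the same
  architecture and scale, not reconstructions.
- r-hat is a risk score, not a calibrated tumor burden; the posterior
  model ignores read-to-read dependence within a region.
- The extrema-based region definition is sensitive to deep pooled
  coverage (see above); users with high-depth training cohorts should
  consider the quantile option.
- The simulator's uniform background makes motif recovery easier than
  on real genomes with repeats.
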