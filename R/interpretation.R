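# Model-introspection suite: kernel position frequency matrices, MEME
# export, CpG-demethylation perturbation scores, rank effect sizes and
# combined-probability machinery.

#' First-convolution-layer kernel activations
#'
#' Cross-correlation of each first-layer kernel with an encoded read at
#' every valid offset (no padding), including the kernel bias. This is
#' the quantity thresholded for PFM construction and read ranking.
#'
#' @param model A `dismir_model`.
#' @param encoded An `encoded_reads` object.
#' @return An `n x P1 x F1` array of activations (reads x offsets x
#'   kernels).
#' @export
conv1_activations <- function(model, encoded) {
  conv1d_fwd(encoded$x, model$params$W1, model$params$b1)
}

#' Kernel position frequency matrices from top activations
#'
#' For each first-layer kernel, activations are computed for every
#' reserved read at every valid offset; the top `top_fraction` of all
#' (read, offset) activations is located, and the corresponding input
#' windows are superposed with their activation values as weights. The
#' four-letter matrix `counts4` accumulates the one-hot base channels;
#' the five-letter matrix `counts5` splits the cytosine column into
#' methylated (`M`) and unmethylated (`C`) using the methylation
#' channel, so its columns are A, C (unmethylated), G, T, M.
#'
#' @param model A trained `dismir_model`.
#' @param reserved The reserved `encoded_reads` holdout
#'   (see [balance_and_split]).
#' @param top_fraction Fraction of (read, offset) activations kept.
#'   Default 0.01.
#' @return List of `kernel_pfm` objects, one per kernel: `kernel_id`,
#'   `width`, `counts4` (width x 4), `counts5` (width x 5),
#'   `n_contributing`.
#' @export
kernel_pfm <- function(model, reserved, top_fraction = 0.01) {
  acts <- conv1_activations(model, reserved)
  n <- dim(acts)[1L]; P <- dim(acts)[2L]; F1 <- dim(acts)[3L]
  w <- model$cfg$conv1_width
  if (n == 0L) stop("reserved set is empty")
  n_top <- max(1L, ceiling(top_fraction * n * P))
  X <- reserved$x
  lapply(seq_len(F1), function(f) {
    a <- matrix(acts[, , f], n, P)
    ord <- order(a, decreasing = TRUE)[seq_len(n_top)]
    reads <- ((ord - 1L) %% n) + 1L
    offs <- ((ord - 1L) %/% n) + 1L
    weights <- a[ord]
    counts4 <- matrix(0, w, 4L,
                      dimnames = list(NULL, c("A", "C", "G", "T")))
    counts5 <- matrix(0, w, 5L,
                      dimnames = list(NULL, c("A", "C", "G", "T", "M")))
    for (i in seq_along(reads)) {
      win <- matrix(X[reads[i], offs[i]:(offs[i] + w - 1L), ], w, 5L)
      base <- win[, 1:4, drop = FALSE]
      meth <- win[, 5L]
      counts4 <- counts4 + weights[i] * base
      c5 <- base
      c5[, 2L] <- c5[, 2L] - meth  # unmethylated C only
      counts5 <- counts5 + weights[i] * cbind(c5, M = meth)
    }
    structure(list(kernel_id = f, width = w, counts4 = counts4,
                   counts5 = counts5, n_contributing = n_top),
              class = "kernel_pfm")
  })
}

#' Write PFMs in MEME minimal motif format
#'
#' Normalizes each PFM's four-letter counts to position probabilities
#' and writes them under alphabet ACGT with `nsites` set to the number
#' of contributing windows, ready for external motif comparison tools.
#' The background model is uniform.
#'
#' @param pfms List of `kernel_pfm` objects (possibly empty).
#' @param path Output path.
#' @export
write_meme <- function(pfms, path) {
  lines <- c("MEME version 4", "",
             "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             "A 0.25 C 0.25 G 0.25 T 0.25", "")
  for (pfm in pfms) {
    rs <- rowSums(pfm$counts4)
    if (any(rs <= 0)) {
      stop("kernel ", pfm$kernel_id, ": PFM has an all-zero row; ",
           "cannot normalize")
    }
    prob <- pfm$counts4 / rs
    lines <- c(lines,
               sprintf("MOTIF kernel_%d", pfm$kernel_id),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       pfm$width, pfm$n_contributing),
               apply(prob, 1L, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                                   r[1], r[2], r[3], r[4])),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' CpG-demethylation perturbation scores across a region
#'
#' Slides a read-length window (stride 1) across a region's sequence,
#' keeps windows whose scored portion has three or more CpG sites, and
#' scores synthetic reads: the baseline read has every CpG methylated;
#' perturbed reads have one CpG (`delta_single`), or all CpGs
#' (`delta_all`), set to unmethylated. The sign convention is
#' `delta = d(perturbed) - d(baseline)`, so demethylation of a model
#' trained on tumor hypomethylation typically yields positive deltas.
#' `delta_sum` is the sum of the single-site deltas; comparing its
#' magnitude with `delta_all` measures whether the model responds
#' super-additively to global methylation change.
#'
#' @param scorer Function mapping a methyl_reads data.frame to a numeric
#'   d-score vector (e.g. a wrapper around trim + encode +
#'   [ensemble_dscore], or any closed-form scorer for diagnostics).
#' @param region_seq Character scalar: the region's DNA sequence.
#' @param chrom,region_start Coordinates used to label windows.
#' @param read_length Window width in bp; defaults to the encoder's
#'   `trim5 + length` so windows mimic raw input reads.
#' @param cfg An [encoder_config] describing which part of the window
#'   the scorer sees (the first `trim5` bases are outside the scored
#'   portion).
#' @param min_cpg Minimum CpGs in the scored portion. Default 3.
#' @return A data.frame with one row per qualifying window: `chrom`,
#'   `window_start`, `n_cpg`, `baseline`, `delta_all`, `delta_sum`, and
#'   a list-column `delta_single`.
#' @export
delta_scores <- function(scorer, region_seq, chrom = "chr1",
                         region_start = 0L,
                         cfg = encoder_config(),
                         read_length = cfg$trim5 + cfg$length,
                         min_cpg = 3L) {
  region_seq <- toupper(region_seq)
  len <- nchar(region_seq)
  if (len < read_length) {
    stop("region sequence shorter than the window length")
  }
  starts <- 0:(len - read_length)
  rows <- list()
  for (s in starts) {
    win <- substr(region_seq, s + 1L, s + read_length)
    cg <- gregexpr("CG", win, fixed = TRUE)[[1L]]
    cg <- cg[cg != -1L]
    # CpGs whose cytosine survives the 5' trim and 3' cut
    scored <- cg[cg > cfg$trim5 & cg <= cfg$trim5 + cfg$length]
    if (length(scored) < min_cpg) next
    base_meth <- rep(".", read_length)
    base_meth[scored] <- "M"
    variants <- c(list(base_meth),
                  lapply(seq_along(scored), function(j) {
                    m <- base_meth; m[scored[j]] <- "U"; m
                  }),
                  list(replace(base_meth, scored, "U")))
    reads <- data.frame(
      read_id = sprintf("w%d_v%d", s, seq_along(variants) - 1L),
      chrom = chrom, start = region_start + s, strand = "+",
      seq = win,
      meth = vapply(variants, paste, character(1), collapse = ""),
      stringsAsFactors = FALSE
    )
    d <- scorer(reads)
    k <- length(scored)
    baseline <- d[1L]
    dsingle <- d[1L + seq_len(k)] - baseline
    dall <- d[k + 2L] - baseline
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, window_start = region_start + s, n_cpg = k,
      baseline = baseline, delta_all = dall, delta_sum = sum(dsingle),
      stringsAsFactors = FALSE
    )
    rows[[length(rows)]]$delta_single <- I(list(dsingle))
  }
  if (length(rows) == 0L) {
    out <- data.frame(chrom = character(), window_start = integer(),
                      n_cpg = integer(), baseline = numeric(),
                      delta_all = numeric(), delta_sum = numeric(),
                      stringsAsFactors = FALSE)
    out$delta_single <- I(list())
    return(out)
  }
  do.call(rbind, rows)
}

#' Reads that most strongly activate a kernel
#'
#' Ranks reads by their maximum activation of one first-layer kernel
#' over all valid offsets and returns the top fraction. Ties at the
#' cutoff are broken by stable read order. The conventional input is
#' reads with every CpG set to methylated, so ranking reflects sequence
#' preference at a fixed methylation state.
#'
#' @param model A trained `dismir_model`.
#' @param kernel_id Kernel index (1-based).
#' @param encoded An `encoded_reads` object.
#' @param top_fraction Fraction of reads returned. Default 0.001.
#' @return Integer vector of read indices (rows of `encoded$info`),
#'   highest activation first.
#' @export
kernel_activated_reads <- function(model, kernel_id, encoded,
                                   top_fraction = 0.001) {
  acts <- conv1_activations(model, encoded)
  stopifnot(kernel_id >= 1L, kernel_id <= dim(acts)[3L])
  n <- dim(acts)[1L]
  m <- apply(matrix(acts[, , kernel_id], n, dim(acts)[2L]), 1L, max)
  n_top <- max(1L, floor(top_fraction * n))
  if (n < 1 / top_fraction) {
    warning("fewer than 1/top_fraction reads; returning the top read(s)")
  }
  if (length(unique(m)) == 1L) {
    warning("degenerate ranking: all reads activate the kernel equally")
  }
  order(-m, seq_len(n))[seq_len(n_top)]
}

#' Rank-based effect size (AUC) between two distributions
#'
#' The probability that a random value of `y` exceeds a random value of
#' `x`, with ties counted at half weight — the AUC statistic derived
#' from the Mann-Whitney U test.
#'
#' @param x,y Numeric samples.
#' @return Effect size in `[0, 1]`.
#' @export
mwu_effect_size <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty")
  }
  r <- rank(c(x, y))
  u_y <- sum(r[length(x) + seq_along(y)]) - length(y) * (length(y) + 1) / 2
  u_y / (length(x) * length(y))
}

#' Fisher's combined probability test
#'
#' Combines k independent p-values via `chi2 = -2 * sum(log(p))` against
#' a chi-square distribution with 2k degrees of freedom. Values above 1
#' (e.g. E-values from motif comparison tools) are truncated to 1 with a
#' warning.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @return Combined p-value.
#' @export
fisher_combine <- function(pvalues) {
  if (length(pvalues) == 0L) stop("no p-values to combine")
  if (any(pvalues <= 0)) stop("p-values must be > 0")
  if (any(pvalues > 1)) {
    warning("p-values > 1 truncated to 1 (E-value input?)")
    pvalues <- pmin(pvalues, 1)
  }
  chi2 <- -2 * sum(log(pvalues))
  stats::pchisq(chi2, df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Quadrant summary of kernel effect sizes versus motif matches
#'
#' Cross-tabulates kernels by whether they fall in the fourth quadrant
#' of the (effect size of `delta_all`, effect size of `delta_sum`)
#' plane — `ES_all > 0.5` and `ES_sum < 0.5`, i.e. the kernel responds
#' to global demethylation but filters single-site demethylation — and
#' whether they match a known motif. Returns the 2x2 table, the odds
#' ratio (Haldane 0.5 correction applied when any cell is zero) and a
#' two-sided Fisher's exact p-value.
#'
#' @param es_all,es_sum Numeric vectors of effect sizes per kernel.
#' @param motif_flag Logical vector: kernel matched a known motif.
#' @return List with `table`, `odds_ratio`, `p_value`, `degenerate`
#'   (TRUE when a table margin is empty).
#' @export
quadrant_summary <- function(es_all, es_sum, motif_flag) {
  stopifnot(length(es_all) == length(es_sum),
            length(es_all) == length(motif_flag))
  if (length(es_all) == 0L) stop("empty input")
  q4 <- es_all > 0.5 & es_sum < 0.5
  tab <- matrix(c(sum(q4 & motif_flag), sum(q4 & !motif_flag),
                  sum(!q4 & motif_flag), sum(!q4 & !motif_flag)),
                2L, 2L, byrow = TRUE,
                dimnames = list(quadrant4 = c("yes", "no"),
                                motif = c("yes", "no")))
  degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
  ctab <- tab
  if (any(tab == 0L)) ctab <- tab + 0.5
  or <- (ctab[1, 1] * ctab[2, 2]) / (ctab[1, 2] * ctab[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, odds_ratio = or, p_value = p, degenerate = degenerate)
}

#' Best ungapped correlation between a PFM and a motif
#'
#' Slides the motif's one-hot matrix along the PFM's position
#' probability matrix (both directions, minimum overlap configurable)
#' and returns the maximum Pearson correlation over the overlapping
#' probability columns. Used to check whether a kernel recovered a
#' known or planted motif.
#'
#' @param pfm A `kernel_pfm` object.
#' @param motif Motif string over ACGT.
#' @param min_overlap Minimum number of overlapping positions.
#'   Default 4.
#' @return Maximum Pearson correlation across offsets.
#' @export
pfm_motif_correlation <- function(pfm, motif, min_overlap = 4L) {
  prob <- pfm$counts4 / rowSums(pfm$counts4)
  letters <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
  onehot <- t(vapply(letters,
                     function(ch) as.numeric(c("A", "C", "G", "T") == ch),
                     numeric(4)))
  w <- nrow(prob); m <- nrow(onehot)
  best <- -1
  for (shift in (-(m - min_overlap)):(w - min_overlap)) {
    p_idx <- max(1L, shift + 1L):min(w, shift + m)
    m_idx <- p_idx - shift
    if (length(p_idx) < min_overlap) next
    r <- suppressWarnings(stats::cor(as.vector(prob[p_idx, , drop = FALSE]),
                                     as.vector(onehot[m_idx, , drop = FALSE])))
    if (!is.na(r) && r > best) best <- r
  }
  best
}
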