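# A model whose first conv kernel is +1 exactly on the one-hot entries
# of "ACG" (width 3) and zero elsewhere, with zero bias.
acg_probe_model <- function() {
  cfg <- dismir_model_config(L = 20L, conv1_filters = 2L, conv1_width = 3L,
                             pool_width = 2L, lstm_units = 2L,
                             conv2_filters = 2L, conv2_width = 2L,
                             dense_units = c(3L, 2L), dropout = 0,
                             seed = 1L)
  m <- build_dismir_model(cfg)
  m$params$W1[, , 1] <- 0
  m$params$W1[1, 1, 1] <- 1  # A
  m$params$W1[2, 2, 1] <- 1  # C
  m$params$W1[3, 3, 1] <- 1  # G
  m$params$b1[] <- 0
  m
}

encode_plain <- function(seqs, meths = NULL) {
  if (is.null(meths)) meths <- strrep(".", nchar(seqs))
  reads <- data.frame(read_id = sprintf("r%d", seq_along(seqs)),
                      chrom = "c", start = 0L, strand = "+",
                      seq = seqs, meth = meths, stringsAsFactors = FALSE)
  encode_reads(reads, encoder_config(trim5 = 0L, length = nchar(seqs[1])))
}

test_that("a hand-built kernel's PFM concentrates on its motif", {
  m <- acg_probe_model()
  enc <- encode_plain(c("TTACGTTTTTTTTTTTTACG",
                        "ACGTTTTTTTTTTTTTTTTT",
                        "TTTTTTTACGTTTTTTTTTT"))
  # top fraction chosen so exactly the 4 perfect "ACG" windows win
  pfms <- kernel_pfm(m, enc, top_fraction = 4 / (3 * 18))
  pfm <- pfms[[1]]
  expect_equal(pfm$n_contributing, 4L)
  prob <- pfm$counts4 / rowSums(pfm$counts4)
  expect_equal(prob[1, ], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(prob[2, ], c(A = 0, C = 1, G = 0, T = 0))
  expect_equal(prob[3, ], c(A = 0, C = 0, G = 1, T = 0))
})

test_that("kernel PFMs equal the brute-force double loop", {
  set.seed(23)
  reads <- random_methyl_reads(12, len = 20)
  enc <- encode_reads(reads, encoder_config(trim5 = 0L, length = 20L))
  cfg <- dismir_model_config(L = 20L, conv1_filters = 3L, conv1_width = 5L,
                             pool_width = 2L, lstm_units = 2L,
                             conv2_filters = 2L, conv2_width = 2L,
                             dense_units = c(3L, 2L), seed = 9L)
  m <- build_dismir_model(cfg)
  for (tf in c(0.02, 0.1, 1.0)) {
    pfms <- kernel_pfm(m, enc, top_fraction = tf)
    for (k in seq_along(pfms)) {
      want <- oracle_pfm(m$params$W1[, , k], m$params$b1[k], enc$x, tf)
      expect_equal(unname(pfms[[k]]$counts4), want$counts4,
                   tolerance = 1e-9)
      expect_equal(unname(pfms[[k]]$counts5), want$counts5,
                   tolerance = 1e-9)
      # row-sum consistency between the 4- and 5-letter matrices
      expect_equal(rowSums(pfms[[k]]$counts4),
                   rowSums(pfms[[k]]$counts5), tolerance = 1e-9)
    }
  }
})

test_that("MEME export normalizes probabilities and round-trips", {
  pfm <- structure(list(kernel_id = 1L, width = 2L,
                        counts4 = matrix(c(2, 2, 0, 0, 1, 1, 1, 1), 2L, 4L,
                                         byrow = TRUE),
                        counts5 = NULL, n_contributing = 4L),
                   class = "kernel_pfm")
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(pfm), path)
  lines <- readLines(path)
  expect_true(any(grepl("^MEME version", lines)))
  i <- grep("letter-probability matrix", lines)
  mat <- do.call(rbind, lapply(strsplit(trimws(lines[i + 1:2]), " +"),
                               as.numeric))
  expect_equal(mat[1, ], c(0.5, 0.5, 0, 0))
  expect_equal(mat[2, ], c(0.25, 0.25, 0.25, 0.25))
  # empty list still writes a valid header
  write_meme(list(), path)
  expect_true(any(grepl("^MEME version", readLines(path))))
  # an all-zero row is an error naming the kernel
  bad <- pfm; bad$counts4[1, ] <- 0
  expect_error(write_meme(list(bad), path), "kernel 1")
})

test_that("delta scores are exact for closed-form scorers", {
  # scorer = mean methylation of CpGs on the scored portion
  mean_meth_scorer <- function(reads) {
    vapply(strsplit(reads$meth, "", fixed = TRUE), function(m) {
      mean(m[m %in% c("M", "U")] == "M")
    }, numeric(1))
  }
  set.seed(44)
  ref <- simulate_reference(sim_config(chrom_length = 2000L,
                                       n_switching_bins = 1L), seed = 12)
  region_seq <- substr(ref$sequences[[1]], 1, 500)
  cfg <- encoder_config(trim5 = 0L, length = 40L)
  ds <- delta_scores(mean_meth_scorer, region_seq, cfg = cfg,
                     read_length = 40L)
  expect_gt(nrow(ds), 0L)
  expect_true(all(ds$n_cpg >= 3L))
  expect_equal(ds$baseline, rep(1, nrow(ds)))
  # linear scorer: each single-site delta is -1/k, all-site delta is -1,
  # and the additivity diagnostic delta_sum == delta_all holds exactly
  for (i in seq_len(nrow(ds))) {
    expect_equal(ds$delta_single[[i]], rep(-1 / ds$n_cpg[i], ds$n_cpg[i]))
  }
  expect_equal(ds$delta_all, rep(-1, nrow(ds)))
  expect_equal(ds$delta_sum, ds$delta_all)
  # constant scorer: all deltas vanish
  ds0 <- delta_scores(function(reads) rep(0.7, nrow(reads)), region_seq,
                      cfg = cfg, read_length = 40L)
  expect_true(all(ds0$delta_all == 0) && all(ds0$delta_sum == 0))
})

test_that("windows with fewer than three scored CpGs are skipped", {
  # sequence with exactly two CpGs -> no qualifying windows
  seq2 <- paste0(strrep("A", 10), "CG", strrep("A", 10), "CG",
                 strrep("A", 16))
  ds <- delta_scores(function(reads) rep(0.5, nrow(reads)), seq2,
                     cfg = encoder_config(trim5 = 0L, length = 40L),
                     read_length = 40L)
  expect_equal(nrow(ds), 0L)
})

test_that("kernel-activated reads are found by maximum activation", {
  m <- acg_probe_model()
  seqs <- c(sprintf("TT%sTTTTTTTTTTTTTTT", c("ACG", "ACG")),
            rep("TTTTTTTTTTTTTTTTTTTT", 8))
  enc <- encode_plain(seqs)
  idx <- kernel_activated_reads(m, 1L, enc, top_fraction = 0.2)
  expect_setequal(idx, c(1L, 2L))
  # degenerate ranking warns and keeps stable order
  enc2 <- encode_plain(rep("TTTTTTTTTTTTTTTTTTTT", 10))
  expect_warning(idx2 <- kernel_activated_reads(m, 1L, enc2,
                                                top_fraction = 0.2),
                 "degenerate")
  expect_equal(idx2, c(1L, 2L))
  # fewer reads than 1/top_fraction still returns one read with warning
  # (the all-equal fixture also triggers the degenerate-ranking warning)
  expect_warning(
    expect_warning(idx3 <- kernel_activated_reads(m, 1L, enc2,
                                                  top_fraction = 0.001),
                   "fewer"),
    "degenerate")
  expect_equal(length(idx3), 1L)
})

test_that("effect size matches pair enumeration", {
  expect_equal(mwu_effect_size(c(1, 2, 3), c(4, 5, 6)), 1.0)
  expect_equal(mwu_effect_size(c(1, 2), c(1, 2)), 0.5)
  expect_equal(mwu_effect_size(c(1, 3), c(2, 4)), 0.75)
  set.seed(13)
  for (i in 1:100) {
    x <- sample(1:8, sample(2:10, 1), replace = TRUE)
    y <- sample(1:8, sample(2:10, 1), replace = TRUE)
    expect_equal(mwu_effect_size(x, y), oracle_mwu(x, y))
  }
  # complementarity for tie-free samples
  x <- c(0.1, 0.7, 1.3); y <- c(0.4, 2.2)
  expect_equal(mwu_effect_size(x, y) + mwu_effect_size(y, x), 1)
  expect_error(mwu_effect_size(numeric(0), 1), "non-empty")
})

test_that("Fisher's combined probability test matches closed forms", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  # df-4 closed form: (1 + chi2/2) * exp(-chi2/2)
  chi2 <- -2 * sum(log(c(0.5, 0.5)))
  expect_equal(fisher_combine(c(0.5, 0.5)), (1 + chi2 / 2) * exp(-chi2 / 2))
  expect_equal(round(fisher_combine(c(0.5, 0.5)), 4), 0.5966)
  # k = 1 is the identity
  expect_equal(fisher_combine(0.137), 0.137)
  # repeated small p-values reinforce each other
  combined <- vapply(1:5, function(k) fisher_combine(rep(0.1, k)),
                     numeric(1))
  expect_true(all(diff(combined) < 0))
  expect_error(fisher_combine(c(0.5, 0)), "> 0")
  expect_warning(fisher_combine(c(0.5, 1.7)), "truncated")
})

test_that("quadrant summary computes the corrected odds ratio", {
  # perfectly aligned: 10 motif kernels in quadrant 4, 10 others outside
  es_all <- c(rep(0.8, 10), rep(0.3, 10))
  es_sum <- c(rep(0.2, 10), rep(0.7, 10))
  flags <- c(rep(TRUE, 10), rep(FALSE, 10))
  qs <- quadrant_summary(es_all, es_sum, flags)
  expect_equal(unname(qs$table), matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(qs$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))
  expect_lt(qs$p_value, 0.001)
  # independence: odds ratio near 1 over simulation
  set.seed(99)
  or_null <- replicate(50, {
    q4 <- runif(60) < 0.4
    fl <- runif(60) < 0.5
    quadrant_summary(ifelse(q4, 0.8, 0.3), ifelse(q4, 0.2, 0.7),
                     fl)$odds_ratio
  })
  expect_lt(abs(mean(log(or_null))), 0.3)
  # degenerate table flagged
  qs2 <- quadrant_summary(rep(0.8, 5), rep(0.2, 5), rep(TRUE, 5))
  expect_true(qs2$degenerate)
})

test_that("PFM-motif correlation detects an embedded motif", {
  onehot_pfm <- function(motif) {
    letters <- strsplit(motif, "")[[1]]
    counts <- t(vapply(letters,
                       function(ch) as.numeric(c("A", "C", "G", "T") == ch),
                       numeric(4))) * 10
    structure(list(kernel_id = 1L, width = nchar(motif), counts4 = counts,
                   counts5 = NULL, n_contributing = 10L),
              class = "kernel_pfm")
  }
  expect_equal(pfm_motif_correlation(onehot_pfm("TACGTCAT"), "TACGTCAT"), 1)
  # shifted overlap still aligns
  expect_equal(pfm_motif_correlation(onehot_pfm("ATACGTCA"), "TACGTCAT"), 1)
  # an unrelated uniform PFM has no correlation
  unif <- onehot_pfm("AAAA")
  unif$counts4[] <- 2.5
  expect_lt(pfm_motif_correlation(unif, "TACGTCAT"), 0.3)
})
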