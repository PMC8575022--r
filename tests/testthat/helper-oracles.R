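# Independent oracles used to cross-check the package implementations.
# These are deliberately written from first principles (plain loops,
# enumeration, closed forms) and share no code with the package paths
# they verify.

# Golden-section maximization of a unimodal function on [lo, hi].
oracle_golden_section <- function(f, lo = 0, hi = 1, tol = 1e-7) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  cc <- b - gr * (b - a); dd <- a + gr * (b - a)
  fc <- f(cc); fd <- f(dd)
  while (b - a > tol) {
    if (fc > fd) {
      b <- dd; dd <- cc; fd <- fc
      cc <- b - gr * (b - a); fc <- f(cc)
    } else {
      a <- cc; cc <- dd; fc <- fd
      dd <- a + gr * (b - a); fd <- f(dd)
    }
  }
  (a + b) / 2
}

# Per-read CpG count and methylation ratio, recomputed by character
# enumeration.
oracle_cpgs <- function(meth) {
  vapply(strsplit(meth, "", fixed = TRUE),
         function(ch) sum(ch %in% c("M", "U")), integer(1))
}

oracle_ratio <- function(meth) {
  vapply(strsplit(meth, "", fixed = TRUE), function(ch) {
    m <- sum(ch == "M"); u <- sum(ch == "U")
    m / (m + u)
  }, numeric(1))
}

# Brute-force switching-region detector: enumerates every bin and
# recomputes read membership, filters and extrema from scratch.
oracle_detect_switching <- function(healthy, tumor, bins, min_reads,
                                    threshold, direction) {
  rows <- list()
  for (i in seq_len(nrow(bins))) {
    b <- bins[i, ]
    pick <- function(reads) {
      sel <- reads[reads$chrom == b$chrom & reads$start >= b$start &
                     reads$start < b$end, , drop = FALSE]
      sel[oracle_cpgs(sel$meth) >= 3L, , drop = FALSE]
    }
    hq <- pick(healthy); tq <- pick(tumor)
    if (nrow(hq) + nrow(tq) < min_reads) next
    if (nrow(hq) == 0L || nrow(tq) == 0L) next
    hr <- oracle_ratio(hq$meth); tr <- oracle_ratio(tq$meth)
    if (direction == "hypo") {
      H <- min(hr); Tv <- min(tr); delta <- H - Tv
    } else {
      H <- max(hr); Tv <- max(tr); delta <- Tv - H
    }
    if (delta > threshold) {
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = b$region_id, boundary_healthy = H,
        boundary_tumor = Tv, delta = delta, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(region_id = character(), boundary_healthy = numeric(),
                      boundary_tumor = numeric(), delta = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Brute-force switching-read flags given the oracle's region table.
oracle_switching_flags <- function(reads, oracle_regions, bins, direction) {
  flags <- rep(FALSE, nrow(reads))
  if (nrow(oracle_regions) == 0L) return(flags)
  binfo <- bins[match(oracle_regions$region_id, bins$region_id), ]
  for (k in seq_len(nrow(reads))) {
    if (oracle_cpgs(reads$meth[k]) < 3L) next
    hit <- which(binfo$chrom == reads$chrom[k] &
                   reads$start[k] >= binfo$start &
                   reads$start[k] < binfo$end)
    if (length(hit) != 1L) next
    ratio <- oracle_ratio(reads$meth[k])
    bh <- oracle_regions$boundary_healthy[hit]
    flags[k] <- if (direction == "hypo") ratio < bh else ratio > bh
  }
  flags
}

# Random toy cohort on 1-2 short chromosomes with 50-bp bins. Reads are
# 20 bp with methylation calls scattered over their cytosines.
random_toy_reads <- function(n, chrom_sizes, prefix) {
  chrom <- sample(names(chrom_sizes), n, replace = TRUE)
  start <- vapply(chrom, function(ch) {
    sample.int(chrom_sizes[[ch]] - 20L, 1L) - 1L
  }, integer(1))
  seq <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE,
                 prob = c(.2, .4, .2, .2)), collapse = "")
  }, character(1))
  meth <- vapply(seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    m <- rep(".", 20L)
    cs <- which(ch == "C")
    if (length(cs)) {
      m[cs] <- sample(c("M", "U", "."), length(cs), replace = TRUE,
                      prob = c(.4, .4, .2))
    }
    paste(m, collapse = "")
  }, character(1))
  data.frame(read_id = sprintf("%s%d", prefix, seq_len(n)), chrom = chrom,
             start = start, strand = "+", seq = seq, meth = meth,
             stringsAsFactors = FALSE)
}

random_toy_cohort <- function(seed) {
  set.seed(seed)
  n_chrom <- sample(1:2, 1L)
  chrom_sizes <- stats::setNames(sample(seq(120L, 900L, by = 37L), n_chrom),
                                 paste0("c", seq_len(n_chrom)))
  list(chrom_sizes = chrom_sizes,
       healthy = random_toy_reads(sample(5:25, 1L), chrom_sizes, "h"),
       tumor = random_toy_reads(sample(5:25, 1L), chrom_sizes, "t"),
       min_reads = sample(2:8, 1L),
       threshold = stats::runif(1, 0.05, 0.6),
       direction = sample(c("hypo", "hyper"), 1L))
}

# Brute-force kernel PFM: literal double loop over reads and offsets.
oracle_pfm <- function(W1_k, b1_k, X, top_fraction) {
  w <- dim(W1_k)[1L]
  n <- dim(X)[1L]; L <- dim(X)[2L]
  acts <- c(); info <- list()
  for (i in seq_len(n)) {
    for (off in seq_len(L - w + 1L)) {
      win <- matrix(X[i, off:(off + w - 1L), ], w, 5L)
      a <- sum(win * W1_k) + b1_k
      acts <- c(acts, a)
      info[[length(info) + 1L]] <- list(i = i, off = off)
    }
  }
  n_top <- max(1L, ceiling(top_fraction * length(acts)))
  top <- order(acts, decreasing = TRUE)[seq_len(n_top)]
  counts4 <- matrix(0, w, 4L); counts5 <- matrix(0, w, 5L)
  for (t in top) {
    i <- info[[t]]$i; off <- info[[t]]$off
    win <- matrix(X[i, off:(off + w - 1L), ], w, 5L)
    base <- win[, 1:4]; meth <- win[, 5L]
    counts4 <- counts4 + acts[t] * base
    c5 <- base; c5[, 2L] <- c5[, 2L] - meth
    counts5 <- counts5 + acts[t] * cbind(c5, meth, deparse.level = 0)
  }
  list(counts4 = counts4, counts5 = counts5)
}

# Effect size by explicit pair enumeration.
oracle_mwu <- function(x, y) {
  wins <- 0
  for (xi in x) for (yi in y) {
    wins <- wins + (yi > xi) + 0.5 * (yi == xi)
  }
  wins / (length(x) * length(y))
}

# Random reads with planted CpGs at a given per-base rate; used to
# build encodable fixtures without the simulator.
random_methyl_reads <- function(n, len = 71L, cg_rate = 0.1,
                                meth_state = c("random", "M", "U"),
                                prefix = "r") {
  meth_state <- match.arg(meth_state)
  reads <- lapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    cg <- which(stats::runif(len - 1L) < cg_rate)
    if (length(cg) > 1L) cg <- cg[c(TRUE, diff(cg) >= 2L)]
    s[cg] <- "C"; s[cg + 1L] <- "G"
    str <- paste(s, collapse = "")
    sites <- gregexpr("CG", str, fixed = TRUE)[[1L]]
    sites <- sites[sites != -1L]
    m <- rep(".", len)
    if (length(sites)) {
      m[sites] <- switch(meth_state,
                         random = sample(c("M", "U"), length(sites),
                                         replace = TRUE),
                         M = "M", U = "U")
    }
    data.frame(read_id = paste0(prefix, i), chrom = "c1", start = 0L,
               strand = "+", seq = str, meth = paste(m, collapse = ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, reads)
}

# Tiny model configuration used by fast unit tests.
tiny_model_config <- function(seed = 1L, epochs = 6L, ...) {
  dismir_model_config(L = 66L, conv1_filters = 8L, conv1_width = 8L,
                      lstm_units = 6L, conv2_filters = 6L,
                      conv2_width = 4L, dense_units = c(12L, 6L),
                      batch_size = 64L, epochs = epochs, patience = 6L,
                      seed = seed, ...)
}
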