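test_that("bin_genome tiles chromosomes with a final partial bin", {
  bins <- bin_genome(c(c1 = 1200L), 500L)
  expect_equal(bins$start, c(0L, 500L, 1000L))
  expect_equal(bins$end, c(500L, 1000L, 1200L))
  expect_equal(nrow(bin_genome(c(c1 = 500L), 500L)), 1L)
  expect_error(bin_genome(c(c1 = 1000L), 0L), "positive")
  expect_warning(bins2 <- bin_genome(c(c1 = 1000L, empty = 0L), 500L),
                 "zero-length")
  expect_equal(unique(bins2$chrom), "c1")
})

test_that("assign_reads keys on the start coordinate and the CpG filter", {
  bins <- bin_genome(c(c1 = 1500L), 500L)
  reads <- data.frame(
    read_id = c("a", "b", "c", "d"),
    chrom = "c1",
    start = c(499L, 500L, 10L, 1499L),
    strand = "+",
    seq = c("CCCGG", "CCCGG", "CCCGG", "CCCGG"),
    meth = c("MUM..", "MUM..", "MU...", "UUU.."),
    stringsAsFactors = FALSE)
  out <- assign_reads(reads, bins)
  # read c has 2 CpGs -> dropped
  expect_equal(out$read_id, c("a", "b", "d"))
  expect_equal(out$region_id, c("c1:0-500", "c1:500-1000", "c1:1000-1500"))
  expect_equal(attr(out, "n_low_cpg"), 1L)
  # read beyond the chromosome end is dropped with a warning
  reads$start[1] <- 2000L
  expect_warning(out2 <- assign_reads(reads, bins), "beyond")
  expect_false("a" %in% out2$read_id)
})

test_that("filter_regions applies the pooled 25-read rule and class guard", {
  bins <- bin_genome(c(c1 = 1500L), 500L)
  mk <- function(n, start, prefix) {
    if (n == 0L) return(empty <- data.frame(read_id = character(),
      chrom = character(), start = integer(), strand = character(),
      seq = character(), meth = character(), stringsAsFactors = FALSE))
    data.frame(read_id = sprintf("%s%d", prefix, 1:n), chrom = "c1",
               start = start, strand = "+", seq = "CCCGG", meth = "MUM..",
               stringsAsFactors = FALSE)
  }
  # bin 0: 24 pooled -> removed; bin 1: 13 + 12 -> kept;
  # bin 2: 30 healthy + 0 tumor -> removed (no tumor extremum)
  h <- rbind(mk(12, 0L, "h0"), mk(13, 500L, "h1"), mk(30, 1000L, "h2"))
  t <- rbind(mk(12, 0L, "t0"), mk(12, 500L, "t1"))
  idx <- region_index(assign_reads(h, bins), assign_reads(t, bins), bins)
  kept <- filter_regions(idx, 25L)
  expect_equal(kept$bins$region_id, "c1:500-1000")
})

test_that("switching-region detection applies the strict extrema rule", {
  bins <- bin_genome(c(c1 = 500L), 500L)
  mk <- function(ratios, prefix) {
    # 10 CpG positions let us hit exact ratios k/10
    do.call(rbind, lapply(seq_along(ratios), function(i) {
      m <- round(ratios[i] * 10)
      data.frame(read_id = paste0(prefix, i), chrom = "c1", start = 0L,
                 strand = "+", seq = strrep("CG", 10),
                 meth = paste0(strrep("M.", m), strrep("U.", 10 - m)),
                 stringsAsFactors = FALSE)
    }))
  }
  detect <- function(h_ratios, t_ratios, threshold, direction) {
    idx <- region_index(assign_reads(mk(h_ratios, "h"), bins),
                        assign_reads(mk(t_ratios, "t"), bins), bins)
    detect_switching_regions(filter_regions(idx, min_reads = 2L),
                             threshold, direction)
  }
  hit <- detect(c(0.9, 0.8, 1.0), c(0.2, 0.9), 0.3, "hypo")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$boundary_healthy, 0.8)
  expect_equal(hit$boundary_tumor, 0.2)
  expect_equal(hit$delta, 0.6)
  # delta exactly at the threshold is NOT emitted (strict inequality)
  expect_equal(nrow(detect(c(0.5), c(0.2), 0.3, "hypo")), 0L)
  # hyper direction compares maxima
  hyp <- detect(c(0.1, 0.2), c(0.9, 1.0), 0.5, "hyper")
  expect_equal(nrow(hyp), 1L)
  expect_equal(hyp$delta, 1.0 - 0.2)
})

test_that("switching-read flags use strict inequality and region scope", {
  regions <- structure(data.frame(
    chrom = "c1", start = 0L, end = 500L, region_id = "c1:0-500",
    name = "SR1", direction = "hypo", boundary_healthy = 0.8,
    boundary_tumor = 0.2, delta = 0.6, stringsAsFactors = FALSE),
    class = c("switching_regions", "data.frame"))
  mkread <- function(id, start, m_of_10) {
    data.frame(read_id = id, chrom = "c1", start = start, strand = "+",
               seq = strrep("CG", 10),
               meth = paste0(strrep("M.", m_of_10), strrep("U.", 10 - m_of_10)),
               stringsAsFactors = FALSE)
  }
  reads <- rbind(mkread("low", 10L, 5),    # ratio 0.5 < 0.8 -> switching
                 mkread("edge", 20L, 8),   # ratio 0.8, strict -> not
                 mkread("out", 600L, 0))   # outside any region
  expect_equal(flag_switching_reads(reads, regions), c(TRUE, FALSE, FALSE))
  # extraction keeps all qualifying region reads, flagged or not
  ext <- extract_region_reads(reads, regions)
  expect_equal(ext$read_id, c("low", "edge"))
  # FSR is the flagged fraction among extracted reads
  expect_equal(fsr(reads, regions), 0.5)
  expect_error(fsr(reads[3, ], regions), "undefined")
})

test_that("detection matches a brute-force oracle on random toy cohorts", {
  n_match <- 0L
  n_cohorts <- 200L
  for (s in seq_len(n_cohorts)) {
    toy <- random_toy_cohort(1000 + s)
    bins <- bin_genome(toy$chrom_sizes, 50L)
    idx <- region_index(assign_reads(toy$healthy, bins),
                        assign_reads(toy$tumor, bins), bins)
    got <- detect_switching_regions(
      filter_regions(idx, toy$min_reads), toy$threshold, toy$direction)
    want <- oracle_detect_switching(toy$healthy, toy$tumor, bins,
                                    toy$min_reads, toy$threshold,
                                    toy$direction)
    ids_equal <- setequal(got$region_id, want$region_id)
    vals_equal <- TRUE
    if (ids_equal && nrow(want) > 0L) {
      m <- match(want$region_id, got$region_id)
      vals_equal <- isTRUE(all.equal(got$boundary_healthy[m],
                                     want$boundary_healthy)) &&
        isTRUE(all.equal(got$boundary_tumor[m], want$boundary_tumor)) &&
        isTRUE(all.equal(got$delta[m], want$delta))
    }
    flags_equal <- TRUE
    if (ids_equal && nrow(want) > 0L) {
      test_reads <- rbind(toy$healthy, toy$tumor)
      flags_equal <- identical(
        flag_switching_reads(test_reads, got),
        oracle_switching_flags(test_reads, want, bins, toy$direction))
    }
    if (ids_equal && vals_equal && flags_equal) n_match <- n_match + 1L
  }
  expect_equal(n_match, n_cohorts)
})

test_that("raising the threshold never adds regions (monotonicity)", {
  toy <- random_toy_cohort(77)
  bins <- bin_genome(toy$chrom_sizes, 50L)
  idx <- filter_regions(
    region_index(assign_reads(toy$healthy, bins),
                 assign_reads(toy$tumor, bins), bins), 2L)
  counts <- vapply(seq(0, 0.9, by = 0.1), function(th) {
    nrow(detect_switching_regions(idx, th, "hypo"))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("flagged switching reads are a subset of extracted region reads", {
  fx_toy <- random_toy_cohort(31)
  bins <- bin_genome(fx_toy$chrom_sizes, 50L)
  idx <- filter_regions(
    region_index(assign_reads(fx_toy$healthy, bins),
                 assign_reads(fx_toy$tumor, bins), bins), 2L)
  regions <- detect_switching_regions(idx, 0.1, "hypo")
  all_reads <- rbind(fx_toy$healthy, fx_toy$tumor)
  flags <- flag_switching_reads(all_reads, regions)
  extracted <- extract_region_reads(all_reads, regions)
  expect_true(all(all_reads$read_id[flags] %in% extracted$read_id))
})
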