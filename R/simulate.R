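# Synthetic bisulfite-read simulator. Generates reference sequences
# with planted CpG sites, class-dependent per-read methylation levels
# (healthy high; tumor hypomethylated in a subset of bins), optional
# planted sequence motifs, mixtures at a known tumor fraction and
# variable depth — the statistical structure the detection method
# assumes, with full ground truth.

#' Simulation configuration
#'
#' Defaults describe the package's standard synthetic scenario: one
#' 165-kb chromosome of 330 bins (500 bp), 30 of them switching bins;
#' CpG density 0.1 per bp (switching regions are CpG-dense) so that
#' 80-bp reads usually carry well over the three CpGs required
#' downstream; healthy reads draw their per-read methylation level from
#' Beta(25.5, 4.5) (mean 0.85) and tumor reads in switching bins from
#' Beta(4.5, 25.5) (mean 0.15), with tumor reads in
#' background bins behaving like healthy ones; each CpG call flips with
#' probability 0.05 to model bisulfite technical noise.
#'
#' @param n_chroms Number of chromosomes. Default 1.
#' @param chrom_length Length of each chromosome in bp. Default 165000.
#' @param bin_size Bin width used for switching-bin truth. Default 500.
#' @param n_switching_bins Bins per genome carrying the tumor
#'   hypomethylation signal. Default 30.
#' @param cpg_density Expected CpG sites per bp. Default 0.1.
#' @param read_length Simulated read length. Default 80 (enough for a
#'   5-bp 5' trim plus a 66-bp model input).
#' @param healthy_meth,tumor_meth_switching Beta shape pairs for the
#'   per-read methylation level of healthy reads (all bins; also tumor
#'   reads in background bins) and tumor reads in switching bins.
#' @param flip_noise Per-site probability that a CpG call flips.
#'   Default 0.05. Must be below 0.5.
#' @param planted_motif Optional list: `seq` (motif string), `class`
#'   (`"tumor"` or `"healthy"`: reads of this origin receive the motif),
#'   `prob` (per-read insertion probability), `in_reference` (also
#'   overwrite the motif into each switching bin of the reference).
#' @param frac_reverse Fraction of reads emitted as reverse-strand
#'   reads (reverse-complemented with CpG-dyad methylation transfer).
#'   Default 0.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chroms = 1L, chrom_length = 165000L,
                       bin_size = 500L, n_switching_bins = 30L,
                       cpg_density = 0.1, read_length = 80L,
                       healthy_meth = c(25.5, 4.5),
                       tumor_meth_switching = c(4.5, 25.5),
                       flip_noise = 0.05, planted_motif = NULL,
                       frac_reverse = 0) {
  stopifnot(cpg_density > 0, flip_noise >= 0, flip_noise < 0.5,
            read_length > 0, frac_reverse >= 0, frac_reverse <= 1)
  if (cpg_density > 0.4) stop("cpg_density too high to place sites")
  if (!is.null(planted_motif)) {
    stopifnot(is.character(planted_motif$seq),
              nchar(planted_motif$seq) <= read_length)
    planted_motif$class <- match.arg(planted_motif$class,
                                     c("tumor", "healthy"))
    if (is.null(planted_motif$prob)) planted_motif$prob <- 0.3
    if (is.null(planted_motif$in_reference)) planted_motif$in_reference <- FALSE
  }
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 bin_size = as.integer(bin_size),
                 n_switching_bins = as.integer(n_switching_bins),
                 cpg_density = cpg_density,
                 read_length = as.integer(read_length),
                 healthy_meth = healthy_meth,
                 tumor_meth_switching = tumor_meth_switching,
                 flip_noise = flip_noise, planted_motif = planted_motif,
                 frac_reverse = frac_reverse),
            class = "sim_config")
}

#' Simulate a reference genome with planted CpG sites
#'
#' Background bases are i.i.d. uniform over ACGT; CpG dinucleotides are
#' planted at the configured density and accidental background CGs are
#' removed, so the final CG positions are exactly the CpG sites.
#' Switching bins are chosen uniformly among full-width bins and
#' recorded in the truth table. With `planted_motif$in_reference`, the
#' motif is written into each switching bin at a random offset.
#'
#' @param cfg A [sim_config].
#' @param seed Integer seed; the same seed reproduces the reference
#'   exactly.
#' @return A `sim_reference` list: `sequences` (named character vector),
#'   `cpg_sites` (list of 0-based C positions per chromosome), `bins`
#'   (bin table with `is_switching`), `chrom_sizes`, `cfg`.
#' @export
simulate_reference <- function(cfg = sim_config(), seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  chroms <- sprintf("sim%d", seq_len(cfg$n_chroms))
  chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)
  bins <- bin_genome(chrom_sizes, cfg$bin_size)
  full <- which(bins$end - bins$start == cfg$bin_size)
  if (cfg$n_switching_bins > length(full)) {
    stop("more switching bins requested than available bins")
  }
  sw <- sort(sample(full, cfg$n_switching_bins))
  bins$is_switching <- seq_len(nrow(bins)) %in% sw
  sequences <- character(0)
  for (ch in chroms) {
    len <- cfg$chrom_length
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    pos <- which(stats::runif(len - 1L) < cfg$cpg_density)  # 1-based C pos
    if (length(pos) > 1L) pos <- pos[c(TRUE, diff(pos) >= 2L)]
    s[pos] <- "C"; s[pos + 1L] <- "G"
    # remove accidental CGs so planted sites are the only CpGs
    str <- paste(s, collapse = "")
    cg <- gregexpr("CG", str, fixed = TRUE)[[1L]]
    cg <- cg[cg != -1L]
    stray <- setdiff(cg, pos)
    if (length(stray)) {
      s[stray] <- "A"
      str <- paste(s, collapse = "")
    }
    if (!is.null(cfg$planted_motif) && isTRUE(cfg$planted_motif$in_reference)) {
      mb <- bins[bins$chrom == ch & bins$is_switching, , drop = FALSE]
      motif <- cfg$planted_motif$seq
      for (i in seq_len(nrow(mb))) {
        off <- sample.int(cfg$bin_size - nchar(motif) + 1L, 1L)
        at <- mb$start[i] + off  # 1-based insert position
        substr(str, at, at + nchar(motif) - 1L) <- motif
      }
    }
    sequences[ch] <- str
  }
  cpg_sites <- lapply(sequences, function(str) {
    cg <- gregexpr("CG", str, fixed = TRUE)[[1L]]
    cg <- cg[cg != -1L]
    cg - 1L  # 0-based position of the C
  })
  structure(list(sequences = sequences, cpg_sites = cpg_sites,
                 bins = bins, chrom_sizes = chrom_sizes, cfg = cfg),
            class = "sim_reference")
}

#' Simulate one sample's reads
#'
#' Read start positions are uniform over the genome. Each read is
#' tumor-origin with probability `true_r` (forced to 1 for
#' `tumor_tissue` samples and 0 for `healthy_plasma`). A per-read
#' methylation level is drawn from the class- and bin-appropriate Beta
#' distribution, every CpG on the read is methylated independently at
#' that level, and each call then flips with the configured noise
#' probability. Optional motif insertion and reverse-strand emission
#' follow the configuration.
#'
#' @param reference A [simulate_reference] result.
#' @param class_label `healthy_plasma`, `tumor_tissue` or `test_plasma`.
#' @param true_r Tumor-derived read fraction for `test_plasma` samples.
#' @param n_reads Number of reads to draw.
#' @param sample_id Prefix for read identifiers.
#' @param seed Integer seed.
#' @return List with `reads` (methyl_reads data.frame) and `truth`
#'   (per-read `origin` and drawn methylation `level`).
#' @export
simulate_sample <- function(reference, class_label, true_r = 0,
                            n_reads = 1000L, sample_id = "s1",
                            seed = 1L) {
  cfg <- reference$cfg
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (class_label == "tumor_tissue") true_r <- 1
  if (class_label == "healthy_plasma") true_r <- 0
  stopifnot(true_r >= 0, true_r <= 1)
  chroms <- names(reference$sequences)
  lens <- nchar(reference$sequences)
  rl <- cfg$read_length
  chrom <- chroms[sample.int(length(chroms), n_reads, replace = TRUE,
                             prob = lens)]
  start <- floor(stats::runif(n_reads) *
                   (lens[match(chrom, chroms)] - rl + 1L))
  origin <- ifelse(stats::runif(n_reads) < true_r, "tumor", "healthy")
  seqs <- substr_vec(reference$sequences, chrom, start + 1L, start + rl)
  # per-read motif insertion for the enriched class
  pm <- cfg$planted_motif
  if (!is.null(pm) && pm$prob > 0) {
    target <- if (pm$class == "tumor") origin == "tumor" else origin == "healthy"
    hit <- target & stats::runif(n_reads) < pm$prob
    if (any(hit)) {
      offs <- sample.int(rl - nchar(pm$seq) + 1L, sum(hit), replace = TRUE)
      seqs[hit] <- vapply(seq_len(sum(hit)), function(i) {
        s <- seqs[hit][i]
        substr(s, offs[i], offs[i] + nchar(pm$seq) - 1L) <- pm$seq
        s
      }, character(1))
    }
  }
  # bin membership -> methylation level distribution
  bin_start <- (start %/% cfg$bin_size) * cfg$bin_size
  key <- sprintf("%s:%d", chrom, bin_start)
  bkey <- sprintf("%s:%d", reference$bins$chrom, reference$bins$start)
  in_switch <- reference$bins$is_switching[match(key, bkey)]
  in_switch[is.na(in_switch)] <- FALSE
  use_tumor_dist <- origin == "tumor" & in_switch
  level <- numeric(n_reads)
  level[!use_tumor_dist] <- stats::rbeta(sum(!use_tumor_dist),
                                         cfg$healthy_meth[1L],
                                         cfg$healthy_meth[2L])
  level[use_tumor_dist] <- stats::rbeta(sum(use_tumor_dist),
                                        cfg$tumor_meth_switching[1L],
                                        cfg$tumor_meth_switching[2L])
  cg_all <- gregexpr("CG", seqs, fixed = TRUE)
  meth <- vapply(seq_len(n_reads), function(i) {
    sites <- cg_all[[i]]
    m <- rep(".", rl)
    if (sites[1L] != -1L) {
      is_m <- stats::runif(length(sites)) < level[i]
      flip <- stats::runif(length(sites)) < cfg$flip_noise
      is_m <- xor(is_m, flip)
      m[sites] <- ifelse(is_m, "M", "U")
    }
    paste(m, collapse = "")
  }, character(1))
  reads <- data.frame(
    read_id = sprintf("%s_r%06d", sample_id, seq_len(n_reads)),
    chrom = chrom, start = as.integer(start), strand = "+",
    seq = seqs, meth = meth, stringsAsFactors = FALSE
  )
  if (cfg$frac_reverse > 0) {
    rev_idx <- which(stats::runif(n_reads) < cfg$frac_reverse)
    if (length(rev_idx)) {
      rc <- reverse_complement_reads(reads[rev_idx, , drop = FALSE])
      rc$read_id <- reads$read_id[rev_idx]  # same fragment, minus strand
      reads[rev_idx, ] <- rc
    }
  }
  truth <- data.frame(read_id = reads$read_id, origin = origin,
                      level = level, in_switching_bin = in_switch,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

# vectorized substring over a named sequence vector
substr_vec <- function(sequences, chrom, from, to) {
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    idx <- chrom == ch
    out[idx] <- substring(sequences[[ch]], from[idx], to[idx])
  }
  out
}

#' Simulate a cohort and write it to disk
#'
#' Writes one read TSV per sample, a per-read truth TSV, a chrom.sizes
#' file and a cohort manifest. Fully reproducible from `seed`.
#'
#' @param reference A [simulate_reference] result.
#' @param design Data.frame with columns `sample_id`, `class_label`,
#'   `true_r`, `n_reads`.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed; per-sample seeds are derived from it.
#' @return The manifest data.frame (invisibly also written as
#'   `manifest.tsv`).
#' @export
simulate_cohort <- function(reference, design, out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(sample_id = character(), class_label = character(),
                         file_path = character(), stringsAsFactors = FALSE)
  truths <- list()
  for (i in seq_len(nrow(design))) {
    sm <- simulate_sample(reference, design$class_label[i],
                          true_r = design$true_r[i],
                          n_reads = design$n_reads[i],
                          sample_id = design$sample_id[i],
                          seed = seed + i)
    f <- file.path(out_dir, paste0(design$sample_id[i], ".tsv"))
    write_methyl_tsv(sm$reads, f)
    sm$truth$sample_id <- design$sample_id[i]
    truths[[i]] <- sm$truth
    manifest <- rbind(manifest,
                      data.frame(sample_id = design$sample_id[i],
                                 class_label = design$class_label[i],
                                 file_path = paste0(design$sample_id[i], ".tsv"),
                                 stringsAsFactors = FALSE))
  }
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(truths)) {
    utils::write.table(do.call(rbind, truths),
                       file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(sprintf("%s\t%d", names(reference$chrom_sizes),
                     reference$chrom_sizes),
             file.path(out_dir, "chrom.sizes"))
  invisible(manifest)
}
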