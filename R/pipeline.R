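# End-to-end convenience layer tying the modules together: manifest ->
# switching regions -> labeled training set -> ensemble -> per-sample
# d-scores and tumor-fraction estimates.

read_sample_file <- function(path, meth_tag = "XM") {
  if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) {
    read_methyl_sam(path, meth_tag = meth_tag)
  } else {
    read_methyl_tsv(path)
  }
}

#' Detect switching regions from a training-cohort manifest
#'
#' Pools the qualifying reads of all `healthy_plasma` and
#' `tumor_tissue` samples in the manifest, filters bins by pooled read
#' support and detects switching regions.
#'
#' @param manifest Manifest data.frame (see [read_manifest]) or path.
#' @param chrom_sizes Named vector of chromosome lengths or path to a
#'   chrom.sizes file.
#' @param bin_size Bin width. Default 500.
#' @param min_reads Pooled-read filter. Default 25.
#' @param threshold Extrema-separation threshold. Default 0.3.
#' @param direction `"hypo"` (default) or `"hyper"`.
#' @param min_cpg Per-read CpG filter. Default 3.
#' @return A switching_regions data.frame.
#' @export
dismir_detect_regions <- function(manifest, chrom_sizes, bin_size = 500L,
                                  min_reads = 25L, threshold = 0.3,
                                  direction = "hypo", min_cpg = 3L) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(chrom_sizes)) chrom_sizes <- read_chrom_sizes(chrom_sizes)
  bins <- bin_genome(chrom_sizes, bin_size)
  pool <- function(class) {
    rows <- manifest[manifest$class_label == class, , drop = FALSE]
    if (nrow(rows) == 0L) stop("manifest has no ", class, " samples")
    do.call(rbind, lapply(rows$file_path, function(f) {
      assign_reads(read_sample_file(f), bins, min_cpg = min_cpg)
    }))
  }
  index <- region_index(pool("healthy_plasma"), pool("tumor_tissue"), bins)
  index <- filter_regions(index, min_reads = min_reads)
  detect_switching_regions(index, threshold = threshold,
                           direction = direction)
}

#' Build the labeled, balanced training set from a manifest
#'
#' Extracts all qualifying reads from switching regions for each
#' training sample, labels them by source (healthy plasma 0, tumor
#' tissue 1), trims and encodes them, balances the classes and reserves
#' a holdout for kernel visualization.
#'
#' @param manifest Manifest data.frame or path.
#' @param regions A switching_regions table.
#' @param cfg An [encoder_config].
#' @param seed Seed for balancing/holdout sampling.
#' @param reserve_fraction Holdout fraction. Default 0.2.
#' @return List with `train` and `reserved` `encoded_reads`.
#' @export
dismir_training_set <- function(manifest, regions,
                                cfg = encoder_config(), seed = 1L,
                                reserve_fraction = 0.2) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  lab_map <- c(healthy_plasma = 0, tumor_tissue = 1)
  rows <- manifest[manifest$class_label %in% names(lab_map), , drop = FALSE]
  pieces <- lapply(seq_len(nrow(rows)), function(i) {
    reads <- extract_region_reads(read_sample_file(rows$file_path[i]),
                                  regions)
    reads <- trim_reads(reads, cfg)
    reads$label <- lab_map[[rows$class_label[i]]]
    reads
  })
  all_reads <- do.call(rbind, pieces)
  if (is.null(all_reads) || nrow(all_reads) == 0L) {
    stop("no qualifying training reads in switching regions")
  }
  encoded <- encode_reads(all_reads, cfg, labels = all_reads$label)
  balance_and_split(encoded, reserve_fraction = reserve_fraction,
                    seed = seed)
}

#' Score a sample's switching-region reads
#'
#' Extracts qualifying reads from switching regions, trims, encodes and
#' computes (ensemble-averaged) d-scores.
#'
#' @param model A `dismir_model` or `dismir_ensemble`.
#' @param reads A methyl_reads data.frame (one sample).
#' @param regions A switching_regions table.
#' @param cfg An [encoder_config].
#' @return Data.frame `read_id`, `region`, `dscore` (possibly empty).
#' @export
dismir_score_sample <- function(model, reads, regions,
                                cfg = encoder_config()) {
  rr <- extract_region_reads(reads, regions)
  rr <- trim_reads(rr, cfg)
  if (nrow(rr) == 0L) {
    return(data.frame(read_id = character(), region = character(),
                      dscore = numeric(), stringsAsFactors = FALSE))
  }
  encoded <- encode_reads(rr, cfg)
  data.frame(read_id = rr$read_id, region = rr$region_id,
             dscore = ensemble_dscore(model, encoded),
             stringsAsFactors = FALSE)
}

#' Estimate the tumor fraction of one sample end-to-end
#'
#' @inheritParams dismir_score_sample
#' @param grid_step Grid resolution for the posterior search.
#' @return A `tumor_fraction_estimate` (see [estimate_tumor_fraction]).
#' @export
dismir_estimate_sample <- function(model, reads, regions,
                                   cfg = encoder_config(),
                                   grid_step = 0.001) {
  scores <- dismir_score_sample(model, reads, regions, cfg)
  if (nrow(scores) == 0L) stop("no scorable reads in switching regions")
  estimate_tumor_fraction(scores$dscore, grid_step = grid_step)
}

#' Wrap a trained model as a read scorer
#'
#' Returns a function mapping a methyl_reads data.frame to d-scores
#' (trim + encode + predict), for use with [delta_scores].
#'
#' @param model A `dismir_model` or `dismir_ensemble`.
#' @param cfg An [encoder_config].
#' @return A function `reads -> numeric`.
#' @export
dismir_read_scorer <- function(model, cfg = encoder_config()) {
  function(reads) {
    trimmed <- trim_reads(reads, cfg)
    if (nrow(trimmed) != nrow(reads)) {
      stop("scorer received reads shorter than trim5 + L")
    }
    ensemble_dscore(model, encode_reads(trimmed, cfg))
  }
}
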