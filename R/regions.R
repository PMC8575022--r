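#' Tile the genome into fixed-width bins
#'
#' Non-overlapping bins of `bin_size` bp anchored at position 0 of each
#' chromosome; a final partial bin is included. Coordinates are 0-based
#' half-open.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths
#'   (see [read_chrom_sizes]).
#' @param bin_size Bin width in bp. Default 500.
#' @return Data.frame with columns `chrom`, `start`, `end`, `region_id`.
#' @export
bin_genome <- function(chrom_sizes, bin_size = 500L) {
  if (length(bin_size) != 1L || !is.finite(bin_size) || bin_size <= 0) {
    stop("bin_size must be a positive integer")
  }
  bin_size <- as.integer(bin_size)
  zero <- chrom_sizes <= 0L
  if (any(zero)) {
    warning("skipping zero-length chromosomes: ",
            paste(names(chrom_sizes)[zero], collapse = ", "))
    chrom_sizes <- chrom_sizes[!zero]
  }
  pieces <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq.int(0L, len - 1L, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$region_id <- sprintf("%s:%d-%d", bins$chrom, bins$start, bins$end)
  bins
}

#' Assign qualifying reads to genome bins
#'
#' Each read with three or more CpG calls is assigned to the single bin
#' containing its start coordinate (the 5'-most aligned base), so every
#' read belongs to exactly one non-overlapping bin. Reads with fewer
#' CpGs, or starting beyond the binned chromosome end, are dropped; the
#' counts are returned as attributes `n_low_cpg` and `n_out_of_range`.
#'
#' @param reads A methyl_reads data.frame.
#' @param bins Bin table from [bin_genome].
#' @param min_cpg Minimum CpG calls for a read to qualify. Default 3.
#' @return The qualifying subset of `reads` with added columns
#'   `region_id`, `cpgs` and `meth_ratio`.
#' @export
assign_reads <- function(reads, bins, min_cpg = 3L) {
  ncpg <- cpg_count(reads)
  keep <- ncpg >= min_cpg
  n_low <- sum(!keep)
  out <- reads[keep, , drop = FALSE]
  ncpg <- ncpg[keep]
  bin_size <- max(bins$end - bins$start)
  chrom_ends <- tapply(bins$end, bins$chrom, max)
  bin_start <- (out$start %/% bin_size) * bin_size
  rid <- sprintf("%s:%d-%d", out$chrom, bin_start,
                 pmin(bin_start + bin_size,
                      as.integer(chrom_ends[out$chrom])))
  in_range <- !is.na(chrom_ends[out$chrom]) &
    out$start < as.integer(chrom_ends[out$chrom])
  in_range[is.na(in_range)] <- FALSE
  valid <- in_range & rid %in% bins$region_id
  n_oob <- sum(!valid)
  if (n_oob > 0L) {
    warning(n_oob, " reads beyond chromosome ends or on unknown ",
            "chromosomes; dropped")
  }
  out <- out[valid, , drop = FALSE]
  out$region_id <- rid[valid]
  out$cpgs <- ncpg[valid]
  out$meth_ratio <- methylation_ratio(out)
  rownames(out) <- NULL
  attr(out, "n_low_cpg") <- n_low
  attr(out, "n_out_of_range") <- n_oob
  out
}

#' Build a per-region read index for a training cohort
#'
#' Pools assigned reads (see [assign_reads]) from healthy-plasma and
#' tumor-tissue training samples into one index used by region filtering
#' and switching-region detection.
#'
#' @param healthy_reads,tumor_reads Assigned read tables pooled over
#'   the training samples of each class.
#' @param bins Bin table from [bin_genome].
#' @return A `region_index` list with elements `healthy`, `tumor`,
#'   `bins`.
#' @export
region_index <- function(healthy_reads, tumor_reads, bins) {
  structure(list(healthy = healthy_reads, tumor = tumor_reads,
                 bins = bins),
            class = "region_index")
}

#' Filter regions by pooled read support
#'
#' Keeps regions whose pooled qualifying-read count across all training
#' samples is at least `min_reads`, and where both classes contribute at
#' least one read (the class extrema must be computable).
#'
#' @param index A [region_index].
#' @param min_reads Minimum pooled read count. Default 25.
#' @return The index restricted to supported regions.
#' @export
filter_regions <- function(index, min_reads = 25L) {
  stopifnot(inherits(index, "region_index"))
  nh <- table(index$healthy$region_id)
  nt <- table(index$tumor$region_id)
  ids <- union(names(nh), names(nt))
  h <- as.integer(nh[ids]); h[is.na(h)] <- 0L
  t <- as.integer(nt[ids]); t[is.na(t)] <- 0L
  keep <- ids[h + t >= min_reads & h >= 1L & t >= 1L]
  index$bins <- index$bins[index$bins$region_id %in% keep, , drop = FALSE]
  index$healthy <- index$healthy[index$healthy$region_id %in% keep, , drop = FALSE]
  index$tumor <- index$tumor[index$tumor$region_id %in% keep, , drop = FALSE]
  index
}

#' Detect switching regions
#'
#' For the hypomethylated direction, a region is a switching region when
#' the minimum per-read methylation ratio among healthy-plasma reads
#' (`H_min`) exceeds the minimum among tumor-tissue reads (`T_min`) by
#' more than `threshold`; `delta = H_min - T_min`. For the
#' hypermethylated direction the class maxima are compared instead and
#' `delta = T_max - H_max`. Both comparisons are strict.
#'
#' @param index A filtered [region_index] (see [filter_regions]).
#' @param threshold Minimum separation of the class extrema. Default 0.3
#'   (the hypermethylated direction is conventionally run at 0.5).
#' @param direction `"hypo"` or `"hyper"`.
#' @param extrema_quantile Optional quantile in `[0, 0.5)` replacing the
#'   true extremum (0 keeps the true min/max; small values trade
#'   sensitivity for robustness to outlier reads). Default 0.
#' @return A `switching_regions` data.frame with columns `chrom`,
#'   `start`, `end`, `region_id`, `name`, `direction`,
#'   `boundary_healthy`, `boundary_tumor`, `delta`, `n_reads_healthy`,
#'   `n_reads_tumor`.
#' @export
detect_switching_regions <- function(index, threshold = 0.3,
                                     direction = c("hypo", "hyper"),
                                     extrema_quantile = 0) {
  stopifnot(inherits(index, "region_index"))
  direction <- match.arg(direction)
  stopifnot(extrema_quantile >= 0, extrema_quantile < 0.5)
  ids <- intersect(unique(index$healthy$region_id),
                   unique(index$tumor$region_id))
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), region_id = character(),
                      name = character(), direction = character(),
                      boundary_healthy = numeric(),
                      boundary_tumor = numeric(), delta = numeric(),
                      n_reads_healthy = integer(),
                      n_reads_tumor = integer(), stringsAsFactors = FALSE)
  if (length(ids) == 0L) return(structure(empty, class = c("switching_regions", "data.frame")))
  extremum <- function(x) {
    if (direction == "hypo") {
      if (extrema_quantile > 0) stats::quantile(x, extrema_quantile, names = FALSE)
      else min(x)
    } else {
      if (extrema_quantile > 0) stats::quantile(x, 1 - extrema_quantile, names = FALSE)
      else max(x)
    }
  }
  h_split <- split(index$healthy$meth_ratio, index$healthy$region_id)
  t_split <- split(index$tumor$meth_ratio, index$tumor$region_id)
  h_ext <- vapply(h_split[ids], extremum, numeric(1))
  t_ext <- vapply(t_split[ids], extremum, numeric(1))
  delta <- if (direction == "hypo") h_ext - t_ext else t_ext - h_ext
  keep <- delta > threshold
  if (!any(keep)) return(structure(empty, class = c("switching_regions", "data.frame")))
  ids <- ids[keep]
  bins <- index$bins[match(ids, index$bins$region_id), , drop = FALSE]
  out <- data.frame(
    chrom = bins$chrom, start = bins$start, end = bins$end,
    region_id = ids,
    name = sprintf("SR%d", seq_along(ids)),
    direction = direction,
    boundary_healthy = unname(h_ext[keep]),
    boundary_tumor = unname(t_ext[keep]),
    delta = unname(delta[keep]),
    n_reads_healthy = lengths(h_split[ids]),
    n_reads_tumor = lengths(t_split[ids]),
    stringsAsFactors = FALSE
  )
  # sort genomically for stable output
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$name <- sprintf("SR%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  structure(out, class = c("switching_regions", "data.frame"))
}

# region_id of the (non-overlapping) region containing each read's
# start coordinate; NA when the read's bin is not a switching region.
match_read_region <- function(reads, regions) {
  out <- rep(NA_character_, nrow(reads))
  if (nrow(regions) == 0L || nrow(reads) == 0L) return(out)
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    sel <- which(reads$chrom == ch)
    if (length(sel) == 0L) next
    i <- findInterval(reads$start[sel], r$start)
    ok <- i >= 1L & reads$start[sel] < r$end[pmax(i, 1L)]
    out[sel[ok]] <- r$region_id[i[ok]]
  }
  out
}

#' Flag switching reads in a sample
#'
#' A qualifying read in a hypomethylated switching region is a switching
#' read when its methylation ratio is strictly below the healthy
#' boundary `H_min`; in a hypermethylated region, strictly above
#' `H_max`. Reads outside any switching region, or with fewer than
#' `min_cpg` CpG calls, are never flagged.
#'
#' @param reads A methyl_reads data.frame.
#' @param regions A switching_regions table.
#' @param min_cpg Minimum CpG calls. Default 3.
#' @return Logical vector along the rows of `reads`.
#' @export
flag_switching_reads <- function(reads, regions, min_cpg = 3L) {
  if (nrow(reads) == 0L) return(logical(0))
  rid <- match_read_region(reads, regions)
  qual <- cpg_count(reads) >= min_cpg & !is.na(rid)
  flag <- rep(FALSE, nrow(reads))
  if (!any(qual)) return(flag)
  idx <- match(rid[qual], regions$region_id)
  ratio <- methylation_ratio(reads[qual, , drop = FALSE])
  bh <- regions$boundary_healthy[idx]
  dir <- regions$direction[idx]
  flag[qual] <- ifelse(dir == "hypo", ratio < bh, ratio > bh)
  flag
}

#' Extract all qualifying reads from switching regions
#'
#' Returns every read with at least `min_cpg` CpG calls whose bin is a
#' switching region — not only the switching reads. These reads are the
#' input to the deep model.
#'
#' @inheritParams flag_switching_reads
#' @return The subset of `reads`, with `region_id`, `cpgs` and
#'   `meth_ratio` columns added.
#' @export
extract_region_reads <- function(reads, regions, min_cpg = 3L) {
  rid <- match_read_region(reads, regions)
  ncpg <- cpg_count(reads)
  keep <- !is.na(rid) & ncpg >= min_cpg
  out <- reads[keep, , drop = FALSE]
  out$region_id <- rid[keep]
  out$cpgs <- ncpg[keep]
  out$meth_ratio <- if (nrow(out)) methylation_ratio(out) else numeric(0)
  rownames(out) <- NULL
  out
}

#' Fraction of switching reads
#'
#' Model-free baseline statistic: the number of switching reads divided
#' by the number of qualifying reads in switching regions.
#'
#' @inheritParams flag_switching_reads
#' @return A single number in `[0, 1]`.
#' @export
fsr <- function(reads, regions, min_cpg = 3L) {
  region_reads <- extract_region_reads(reads, regions, min_cpg)
  if (nrow(region_reads) == 0L) {
    stop("no qualifying reads in switching regions; FSR undefined")
  }
  mean(flag_switching_reads(region_reads, regions, min_cpg))
}
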