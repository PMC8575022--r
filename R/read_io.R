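#' Read methylation-annotated reads from the 6-column TSV dialect
#'
#' The dialect has one aligned bisulfite read per line with six
#' tab-separated columns: `read_id`, `chrom`, `start` (0-based leftmost
#' aligned position), `strand` (`+`/`-`), `seq` (over `A,C,G,T,N`) and
#' `meth`. The `meth` string has the same length as `seq` and uses `M`
#' (methylated CpG cytosine), `U` (unmethylated CpG cytosine) and `.`
#' (any other base). Lines starting with `#` are skipped.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `read_id`, `chrom`, `start`,
#'   `strand`, `seq`, `meth` (a "methyl_reads" table).
#' @export
read_methyl_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(empty_methyl_reads())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L)) {
    stop("line ", which(nf != 6L)[1L], ": expected 6 tab-separated fields, got ",
         nf[nf != 6L][1L])
  }
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(start)) {
    stop("line ", which(is.na(start))[1L], ": malformed start coordinate '",
         m[is.na(start), 3L][1L], "'")
  }
  reads <- data.frame(
    read_id = m[, 1L], chrom = m[, 2L], start = start,
    strand = m[, 4L], seq = toupper(m[, 5L]), meth = m[, 6L],
    stringsAsFactors = FALSE
  )
  validate_methyl_reads(reads, context = "line")
  reads
}

empty_methyl_reads <- function() {
  data.frame(read_id = character(), chrom = character(),
             start = integer(), strand = character(),
             seq = character(), meth = character(),
             stringsAsFactors = FALSE)
}

#' Validate a methyl_reads table
#'
#' Checks the per-read invariants: `meth` and `seq` have equal length,
#' every `M`/`U` call sits on a `C` base, `start >= 0`, non-empty
#' chromosome names, and restricted alphabets.
#'
#' @param reads A methyl_reads data.frame.
#' @param context Label used in error messages ("line" or "read").
#' @return The validated table, invisibly.
#' @export
validate_methyl_reads <- function(reads, context = "read") {
  if (nrow(reads) == 0L) return(invisible(reads))
  bad <- nchar(reads$meth) != nchar(reads$seq)
  if (any(bad)) {
    stop(context, " ", which(bad)[1L], ": meth length ",
         nchar(reads$meth)[bad][1L], " != seq length ",
         nchar(reads$seq)[bad][1L])
  }
  if (any(reads$start < 0L)) {
    stop(context, " ", which(reads$start < 0L)[1L], ": negative start")
  }
  if (any(!nzchar(reads$chrom))) {
    stop(context, " ", which(!nzchar(reads$chrom))[1L], ": empty chrom")
  }
  if (any(grepl("[^ACGTN]", reads$seq))) {
    stop(context, " ", which(grepl("[^ACGTN]", reads$seq))[1L],
         ": seq has characters outside A,C,G,T,N")
  }
  if (any(grepl("[^MU.]", reads$meth))) {
    stop(context, " ", which(grepl("[^MU.]", reads$meth))[1L],
         ": meth has characters outside M,U,.")
  }
  # every M/U must sit on a C (read-orientation representation)
  call_pos <- gregexpr("[MU]", reads$meth)
  for (i in seq_len(nrow(reads))) {
    p <- call_pos[[i]]
    if (p[1L] == -1L) next
    bases <- substring(reads$seq[i], p, p)
    if (any(bases != "C")) {
      stop(context, " ", i, ": methylation call over non-C base '",
           bases[bases != "C"][1L], "'")
    }
  }
  invisible(reads)
}

#' Write a methyl_reads table to the 6-column TSV dialect
#'
#' @param reads A methyl_reads data.frame.
#' @param path Output path.
#' @export
write_methyl_tsv <- function(reads, path) {
  header <- "#read_id\tchrom\tstart\tstrand\tseq\tmeth"
  body <- sprintf("%s\t%s\t%d\t%s\t%s\t%s", reads$read_id, reads$chrom,
                  reads$start, reads$strand, reads$seq, reads$meth)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read methylation-annotated reads from SAM/BAM
#'
#' Expects a per-read string tag (Bismark-style `XM` by default) whose
#' characters map one-to-one to the stored read bases. The mapping to
#' the internal alphabet is `Z` to `M` (methylated CpG), `z` to `U`
#' (unmethylated CpG), everything else to `.`; non-CpG methylation
#' contexts are deliberately dropped. Coordinates are converted to
#' 0-based; strand comes from FLAG bit 0x10. Unmapped reads are skipped;
#' reads missing the tag are skipped and counted in the
#' `n_missing_tag` attribute of the result.
#'
#' @param path Path to a BAM file, or a SAM text file (converted via
#'   [Rsamtools::asBam] in a temporary directory).
#' @param meth_tag Name of the methylation-call tag. Default `"XM"`.
#' @param mapping Named character vector mapping tag characters to
#'   `M`/`U`; unmapped characters become `.`.
#' @return A methyl_reads data.frame (see [read_methyl_tsv]).
#' @export
read_methyl_sam <- function(path, meth_tag = "XM",
                            mapping = c(Z = "M", z = "U")) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "seq", "flag"),
    tag = meth_tag,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  tag <- res$tag[[meth_tag]]
  n <- length(res$qname)
  if (n == 0L) {
    out <- empty_methyl_reads()
    attr(out, "n_missing_tag") <- 0L
    return(out)
  }
  has_tag <- !is.na(tag)
  n_missing <- sum(!has_tag)
  if (n_missing > 0L) {
    warning(n_missing, " reads missing tag ", meth_tag, "; skipped")
  }
  meth_raw <- tag[has_tag]
  meth <- translate_meth_alphabet(meth_raw, mapping)
  out <- data.frame(
    read_id = res$qname[has_tag],
    chrom = as.character(res$rname)[has_tag],
    start = res$pos[has_tag] - 1L,
    strand = ifelse(bitwAnd(res$flag[has_tag], 16L) > 0L, "-", "+"),
    seq = as.character(res$seq)[has_tag],
    meth = meth,
    stringsAsFactors = FALSE
  )
  validate_methyl_reads(out)
  attr(out, "n_missing_tag") <- n_missing
  out
}

translate_meth_alphabet <- function(x, mapping) {
  from <- names(mapping)
  # chartr wants one-to-one; map everything not in `from` to '.'
  out <- chartr(paste(from, collapse = ""),
                paste(unname(mapping), collapse = ""), x)
  gsub(sprintf("[^%s]", paste(unname(mapping), collapse = "")), ".", out)
}

#' Number of CpG methylation calls on a read
#'
#' Counts `M` plus `U` characters of the methylation string. Reads need
#' three or more CpG sites to qualify for region statistics and model
#' input.
#'
#' @param meth Character vector of methylation strings (or a
#'   methyl_reads data.frame).
#' @return Integer vector of CpG counts.
#' @export
cpg_count <- function(meth) {
  if (is.data.frame(meth)) meth <- meth$meth
  nchar(gsub("[^MU]", "", meth))
}

#' Per-read methylation ratio
#'
#' Fraction of called CpG sites that are methylated: `#M / (#M + #U)`.
#'
#' @param meth Character vector of methylation strings (or a
#'   methyl_reads data.frame).
#' @return Numeric vector in `[0, 1]`.
#' @export
methylation_ratio <- function(meth) {
  if (is.data.frame(meth)) meth <- meth$meth
  n_m <- nchar(gsub("[^M]", "", meth))
  n_u <- nchar(gsub("[^U]", "", meth))
  tot <- n_m + n_u
  if (any(tot == 0L)) {
    stop("methylation_ratio undefined for reads with no CpG calls (",
         sum(tot == 0L), " such reads)")
  }
  n_m / tot
}

#' Read a UCSC chrom.sizes file
#'
#' @param path Two-column TSV: chromosome name, length.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "integer"))
  stats::setNames(tab$length, tab$chrom)
}

#' Write switching regions to BED6+3
#'
#' Columns: chrom, start, end, name, score (`round(1000 * |delta|)`),
#' strand (`.`), then direction, boundary_healthy and boundary_tumor at
#' six decimal places. Coordinates are 0-based half-open as in BED.
#'
#' @param regions A switching_regions data.frame
#'   (see [detect_switching_regions]).
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) > 0 && any(regions$end <= regions$start)) {
    stop("region with end <= start at row ",
         which(regions$end <= regions$start)[1L])
  }
  lines <- character(0)
  if (nrow(regions) > 0) {
    name <- if ("name" %in% names(regions)) regions$name
            else sprintf("SR%d", seq_len(nrow(regions)))
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s\t%.6f\t%.6f",
                     regions$chrom, regions$start, regions$end, name,
                     as.integer(round(1000 * abs(regions$delta))),
                     regions$direction,
                     regions$boundary_healthy, regions$boundary_tumor)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read switching regions from BED6+3
#'
#' Inverse of [write_regions_bed]. `delta` is reconstructed from the
#' stored boundaries according to the direction.
#'
#' @param path BED6+3 path.
#' @return A switching_regions data.frame.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      direction = character(),
                      boundary_healthy = numeric(),
                      boundary_tumor = numeric(), delta = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9L)) {
    stop("line ", which(lengths(parts) != 9L)[1L],
         ": expected 9 BED6+3 fields")
  }
  m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
  bh <- as.numeric(m[, 8L]); bt <- as.numeric(m[, 9L])
  dir <- m[, 7L]
  out <- data.frame(
    chrom = m[, 1L], start = as.integer(m[, 2L]), end = as.integer(m[, 3L]),
    region_id = sprintf("%s:%s-%s", m[, 1L], m[, 2L], m[, 3L]),
    name = m[, 4L], direction = dir,
    boundary_healthy = bh, boundary_tumor = bt,
    delta = ifelse(dir == "hypo", bh - bt, bt - bh),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("switching_regions", "data.frame"))
}

#' Write and read per-read d-score tables
#'
#' TSV with columns `read_id`, `region`, `dscore`; d-scores are stored
#' at six decimal places, so a write/read round-trip is lossless to that
#' precision.
#'
#' @param scores Data.frame with columns `read_id`, `region`, `dscore`.
#' @param path Output path.
#' @export
write_dscores <- function(scores, path) {
  stopifnot(all(c("read_id", "region", "dscore") %in% names(scores)))
  header <- "read_id\tregion\tdscore"
  body <- sprintf("%s\t%s\t%.6f", scores$read_id, scores$region,
                  scores$dscore)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_dscores
#' @return `read_dscores` returns the table; malformed rows (wrong field
#'   count, non-numeric d-score, d-score outside `[0, 1]`) raise an error
#'   naming the line.
#' @export
read_dscores <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || lines[1L] != "read_id\tregion\tdscore") {
    stop("missing d-score header line")
  }
  lines <- lines[-1L]
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(), region = character(),
                      dscore = numeric(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("line ", which(lengths(parts) != 3L)[1L] + 1L,
         ": expected 3 fields")
  }
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  d <- suppressWarnings(as.numeric(m[, 3L]))
  bad <- is.na(d) | d < 0 | d > 1
  if (any(bad)) {
    stop("line ", which(bad)[1L] + 1L, ": invalid d-score '",
         m[bad, 3L][1L], "'")
  }
  data.frame(read_id = m[, 1L], region = m[, 2L], dscore = d,
             stringsAsFactors = FALSE)
}

#' Read a cohort manifest
#'
#' TSV with columns `sample_id`, `class_label` (one of `healthy_plasma`,
#' `tumor_tissue`, `test_plasma`) and `file_path` (resolved relative to
#' the manifest's directory when not absolute).
#'
#' @param path Manifest path.
#' @return Data.frame with the three columns, paths resolved.
#' @export
read_manifest <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", comment.char = "")
  stopifnot(all(c("sample_id", "class_label", "file_path") %in% names(tab)))
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicated sample_id in manifest: ",
         tab$sample_id[duplicated(tab$sample_id)][1L])
  }
  bad <- !tab$class_label %in% c("healthy_plasma", "tumor_tissue", "test_plasma")
  if (any(bad)) stop("unknown class_label '", tab$class_label[bad][1L], "'")
  rel <- !grepl("^/", tab$file_path)
  tab$file_path[rel] <- file.path(dirname(path), tab$file_path[rel])
  tab
}
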