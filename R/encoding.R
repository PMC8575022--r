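#' Encoder configuration
#'
#' @param trim5 Bases removed from the 5' end (read orientation) to
#'   avoid adapter influence. Default 5.
#' @param length Unified model input length L after trimming. Default 66.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(trim5 = 5L, length = 66L) {
  stopifnot(trim5 >= 0L, length > 0L)
  structure(list(trim5 = as.integer(trim5), length = as.integer(length)),
            class = "encoder_config")
}

#' Trim reads to the unified model input length
#'
#' Drops the first `trim5` bases, then keeps the first `length` bases of
#' the remainder (3' trim). Reads shorter than `trim5 + length` are
#' rejected, not padded; the number rejected is returned in the
#' `n_rejected` attribute.
#'
#' @param reads A methyl_reads data.frame.
#' @param cfg An [encoder_config].
#' @return The trimmed subset of `reads`; `start` is advanced by `trim5`
#'   for forward-strand reads (the 5' end of a reverse-strand read is
#'   the reference-rightmost base, so `start` is unchanged there).
#' @export
trim_reads <- function(reads, cfg = encoder_config()) {
  need <- cfg$trim5 + cfg$length
  keep <- nchar(reads$seq) >= need
  out <- reads[keep, , drop = FALSE]
  out$seq <- substr(out$seq, cfg$trim5 + 1L, need)
  out$meth <- substr(out$meth, cfg$trim5 + 1L, need)
  fwd <- out$strand == "+"
  out$start[fwd] <- out$start[fwd] + cfg$trim5
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Encode trimmed reads as L x 5 matrices
#'
#' Row i of a read's matrix is the one-hot encoding of base i over
#' (A, C, G, T) — all zero for N — plus a fifth methylation channel that
#' is 1 where the methylation call is `M` and 0 otherwise (`U` and `.`
#' are both 0; the base channels already distinguish C from non-C).
#'
#' @param reads A methyl_reads data.frame, already trimmed to length L.
#' @param cfg An [encoder_config]; all reads must have length
#'   `cfg$length`.
#' @param labels Optional numeric vector of per-read class labels
#'   (0 = healthy plasma, 1 = tumor tissue).
#' @return An `encoded_reads` list: `x`, an `n x L x 5` array, and
#'   `info`, a data.frame with `read_id`, `region_id` (if present) and
#'   `label`.
#' @export
encode_reads <- function(reads, cfg = encoder_config(), labels = NULL) {
  L <- cfg$length
  if (nrow(reads) > 0 && any(nchar(reads$seq) != L)) {
    stop("all reads must be trimmed to length ", L,
         " before encoding (see trim_reads)")
  }
  n <- nrow(reads)
  x <- array(0, dim = c(n, L, 5L))
  if (n > 0) {
    seq_mat <- matrix(unlist(strsplit(reads$seq, "", fixed = TRUE)),
                      nrow = n, byrow = TRUE)
    meth_mat <- matrix(unlist(strsplit(reads$meth, "", fixed = TRUE)),
                       nrow = n, byrow = TRUE)
    bases <- c("A", "C", "G", "T")
    for (b in seq_along(bases)) {
      x[, , b][seq_mat == bases[b]] <- 1
    }
    bad <- meth_mat == "M" & seq_mat != "C"
    if (any(bad)) {
      stop("methylation call 'M' over a non-C base in read ",
           reads$read_id[which(rowSums(bad) > 0)[1L]])
    }
    x[, , 5L][meth_mat == "M"] <- 1
  }
  info <- data.frame(read_id = reads$read_id, stringsAsFactors = FALSE)
  if ("region_id" %in% names(reads)) info$region_id <- reads$region_id
  info$label <- if (is.null(labels)) NA_real_ else labels
  structure(list(x = x, info = info), class = "encoded_reads")
}

#' Reverse-complement a read, transferring CpG-dyad methylation
#'
#' The sequence is reverse-complemented. For every CpG dinucleotide on
#' the original read, the methylation state (`M`/`U`) of its cytosine is
#' transferred to the cytosine of the complementary-strand CpG — after
#' reverse-complementing, again a `C` followed by `G`. All other
#' positions become `.`; methylation calls on cytosines not part of a
#' CpG dinucleotide within the read have no dyad partner and are
#' dropped. The raw and reverse-complement read therefore share the
#' methylation state at every CpG dyad. Applying the operation twice
#' returns the dyad-borne state exactly.
#'
#' @param reads A methyl_reads data.frame.
#' @return A methyl_reads data.frame of the same shape; `strand` is
#'   flipped and `read_id` gains an `_RC` suffix.
#' @export
reverse_complement_reads <- function(reads) {
  n <- nrow(reads)
  out <- reads
  out$read_id <- paste0(reads$read_id, "_RC")
  out$strand <- ifelse(reads$strand == "+", "-", "+")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (i in seq_len(n)) {
    s <- strsplit(reads$seq[i], "", fixed = TRUE)[[1L]]
    m <- strsplit(reads$meth[i], "", fixed = TRUE)[[1L]]
    len <- length(s)
    rc <- rev(unname(comp[s]))
    newm <- rep(".", len)
    # CpG at original positions (j, j+1): its dyad cytosine is the
    # complement of the G, which lands at output position len - j.
    cg <- which(s[-len] == "C" & s[-1L] == "G")
    for (j in cg) {
      if (m[j] %in% c("M", "U")) newm[len - j] <- m[j]
    }
    out$seq[i] <- paste(rc, collapse = "")
    out$meth[i] <- paste(newm, collapse = "")
  }
  out
}

#' Balance classes and reserve a holdout for kernel visualization
#'
#' Downsamples the majority class uniformly at random to the minority
#' count, then holds out a uniformly random 20% of the balanced pool for
#' kernel visualization; the remainder is the training pool. The split
#' is reproducible from `seed`.
#'
#' @param encoded An [encode_reads] result with labels 0/1 for all reads.
#' @param reserve_fraction Fraction reserved. Default 0.2.
#' @param seed Integer seed.
#' @return List with `train` and `reserved`, both `encoded_reads`.
#' @export
balance_and_split <- function(encoded, reserve_fraction = 0.2, seed = 1L) {
  lab <- encoded$info$label
  i0 <- which(lab == 0); i1 <- which(lab == 1)
  if (length(i0) == 0L || length(i1) == 0L) {
    stop("both classes must be present to balance")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- min(length(i0), length(i1))
  keep <- c(sample(i0, n), sample(i1, n))
  n_res <- round(reserve_fraction * length(keep))
  res_idx <- sample(keep, n_res)
  train_idx <- setdiff(keep, res_idx)
  list(train = subset_encoded(encoded, sort(train_idx)),
       reserved = subset_encoded(encoded, sort(res_idx)))
}

subset_encoded <- function(encoded, idx) {
  structure(list(x = encoded$x[idx, , , drop = FALSE],
                 info = encoded$info[idx, , drop = FALSE]),
            class = "encoded_reads")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
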