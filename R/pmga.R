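#' Extract the 3l x 3l obs/exp neighborhood of a gene
#'
#' The gene body of `l` bins plus upstream and downstream flanks of `l` bins
#' each. Genes whose flanks run off the chromosome are skipped (`NULL`).
#'
#' @param oe an [compute_obs_exp()] map.
#' @param start,end gene coordinates (bp, 0-based half-open).
#' @return list with `block` (matrix), `bins` (row/col bin indices), or
#'   `NULL` if the window does not fit.
#' @export
extract_block <- function(oe, start, end) {
  bins <- gene_bins(start, end, oe$resolution)
  l <- length(bins)
  if (l < 1) return(NULL)
  win <- seq.int(bins[1] - l, bins[l] + l)
  if (win[1] < 1 || win[length(win)] > n_bins(oe)) return(NULL)
  list(block = oe$values[win, win], bins = win, l = l)
}

rescale_weights <- function(src, target) {
  if (src < target) stop("cannot upsample: source smaller than target")
  # W[j, i] = length of overlap between source pixel i ([i-1, i)) and
  # destination pixel j ([ (j-1)*src/target, j*src/target ))
  W <- matrix(0, target, src)
  edges <- seq(0, src, length.out = target + 1)
  for (j in seq_len(target)) {
    ov <- pmin(seq_len(src), edges[j + 1]) - pmax(seq_len(src) - 1, edges[j])
    ov[ov < 0] <- 0
    W[j, ] <- ov
  }
  W
}

#' Rescale a block to a fixed pseudo-size by area-weighted averaging
#'
#' Each destination pixel is the area-weighted average of the source pixels it
#' covers (fractional overlaps for non-integer ratios). `NA` source pixels are
#' excluded from both numerator and denominator; a destination pixel is `NA`
#' only when all its contributors are. Mean-preserving for unmasked input.
#'
#' @param block square (or rectangular, with `target` of length 2) matrix.
#' @param target destination size(s).
#' @return `target x target` matrix.
#' @export
rescale_to <- function(block, target) {
  if (length(target) == 1) target <- c(target, target)
  Wr <- rescale_weights(nrow(block), target[1])
  Wc <- rescale_weights(ncol(block), target[2])
  valid <- !is.na(block)
  b0 <- block
  b0[!valid] <- 0
  num <- Wr %*% b0 %*% t(Wc)
  den <- Wr %*% (valid + 0) %*% t(Wc)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Orient a pileup block in the transcription forward direction
#'
#' Reverse-strand blocks are rotated 180 degrees (both axes flipped) so that
#' the TSS always sits at the start of the middle third. An involution.
#'
#' @param block square matrix.
#' @param strand "+" or "-".
#' @return oriented matrix.
#' @export
orient_block <- function(block, strand) {
  if (strand == "-") {
    idx <- rev(seq_len(nrow(block)))
    block[idx, idx]
  } else block
}

#' Intra-gene pile-up meta-gene analysis
#'
#' For each gene in a cluster: extract the 3l x 3l obs/exp neighborhood,
#' rescale it to `target x target` (default 60) by averaging, orient it in
#' the transcription forward direction, and aggregate element-wise across
#' genes with per-pixel valid counts.
#'
#' @param oe an [compute_obs_exp()] map.
#' @param genes stranded `GRanges` of the cluster's genes.
#' @param target pseudo-matrix size (default 60).
#' @param cluster cluster label carried into the result.
#' @return list of class `pileup_result`: `mean` (target x target), `n`
#'   genes aggregated, `n_skipped`, `cluster`.
#' @export
pmga_intra <- function(oe, genes, target = 60, cluster = NA_character_) {
  if (!length(genes)) stop("empty cluster")
  acc <- matrix(0, target, target)
  cntm <- matrix(0, target, target)
  n_used <- 0L
  n_skipped <- 0L
  for (k in seq_along(genes)) {
    blk <- extract_block(oe,
                         GenomicRanges::start(genes)[k] - 1,
                         GenomicRanges::end(genes)[k])
    if (is.null(blk) || nrow(blk$block) < target) {
      n_skipped <- n_skipped + 1L
      next
    }
    r <- rescale_to(blk$block, target)
    r <- orient_block(r, as.character(GenomicRanges::strand(genes)[k]))
    ok <- !is.na(r)
    acc[ok] <- acc[ok] + r[ok]
    cntm <- cntm + ok
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no eligible gene in cluster")
  m <- acc / cntm
  m[cntm == 0] <- NA_real_
  structure(list(mean = m, n = n_used, n_skipped = n_skipped,
                 cluster = cluster), class = "pileup_result")
}

#' @export
print.pileup_result <- function(x, ...) {
  cat(sprintf("<pileup_result> %dx%d, n = %d (skipped %d)%s\n",
              nrow(x$mean), ncol(x$mean), x$n, x$n_skipped,
              if (is.na(x$cluster)) "" else paste0(", cluster ", x$cluster)))
  invisible(x)
}

#' Inter-gene pile-up of distal gene pairs
#'
#' For each ordered pair of genes separated (midpoint to midpoint) by at
#' least `min_sep` and at most `max_sep` bp, the off-diagonal obs/exp region
#' of size 3l1 x 3l2 centered on the two gene midpoints is rescaled per-axis
#' to `target x target` (default 30), each axis flipped independently so both
#' genes read in the forward direction, and aggregated. Pairs whose 3l
#' windows overlap or leave the map are skipped.
#'
#' @param oe an [compute_obs_exp()] map.
#' @param genes stranded `GRanges`.
#' @param min_sep,max_sep midpoint separation window in bp (defaults
#'   128 kb and 2 Mb).
#' @param target pseudo-matrix size (default 30).
#' @param cluster label carried into the result.
#' @return `pileup_result` with `n` = pairs aggregated.
#' @export
pmga_inter <- function(oe, genes, min_sep = 128e3, max_sep = 2e6,
                       target = 30, cluster = NA_character_) {
  st <- GenomicRanges::start(genes) - 1
  en <- GenomicRanges::end(genes)
  strand <- as.character(GenomicRanges::strand(genes))
  mid <- (st + en) / 2
  acc <- matrix(0, target, target)
  cntm <- matrix(0, target, target)
  n_used <- 0L
  n_skipped <- 0L
  ng <- length(genes)
  for (i in seq_len(ng - 1)) for (j in seq.int(i + 1, ng)) {
    sep <- abs(mid[j] - mid[i])
    if (sep <= min_sep || sep >= max_sep) next
    a <- if (mid[i] <= mid[j]) i else j
    b <- if (mid[i] <= mid[j]) j else i
    wa <- gene_window_bins(oe, st[a], en[a])
    wb <- gene_window_bins(oe, st[b], en[b])
    if (is.null(wa) || is.null(wb) ||
        length(intersect(wa, wb)) > 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    blk <- oe$values[wa, wb, drop = FALSE]
    r <- rescale_to(blk, c(target, target))
    if (strand[a] == "-") r <- r[rev(seq_len(target)), ]
    if (strand[b] == "-") r <- r[, rev(seq_len(target))]
    ok <- !is.na(r)
    acc[ok] <- acc[ok] + r[ok]
    cntm <- cntm + ok
    n_used <- n_used + 1L
  }
  if (n_used == 0L)
    return(structure(list(mean = NULL, n = 0L, n_skipped = n_skipped,
                          cluster = cluster), class = "pileup_result"))
  m <- acc / cntm
  m[cntm == 0] <- NA_real_
  structure(list(mean = m, n = n_used, n_skipped = n_skipped,
                 cluster = cluster), class = "pileup_result")
}

gene_window_bins <- function(oe, start, end) {
  bins <- gene_bins(start, end, oe$resolution)
  l <- length(bins)
  if (l < 1) return(NULL)
  win <- seq.int(bins[1] - l, bins[l] + l)
  if (win[1] < 1 || win[length(win)] > n_bins(oe)) return(NULL)
  win
}

#' ChIP meta-gene profile over gene clusters
#'
#' Discretizes each gene's 3l domain (flank, body, flank) into `n_bins`
#' equal bins, computes base-pair-weighted coverage per bin, flips
#' reverse-strand genes, and averages over the cluster. The gene body spans
#' bins 21-40 of the default 60.
#'
#' @param track `GRanges` with `score`.
#' @param genes stranded `GRanges`.
#' @param n_bins profile length (default 60).
#' @return list: `profile` (length `n_bins`), `n` genes used.
#' @export
chip_metagene <- function(track, genes, n_bins = 60) {
  acc <- numeric(n_bins)
  n_used <- 0L
  for (k in seq_along(genes)) {
    st <- GenomicRanges::start(genes)[k] - 1
    en <- GenomicRanges::end(genes)[k]
    l <- en - st
    chrom <- as.character(GenomicRanges::seqnames(genes)[k])
    p <- bin_coverage(track, chrom, st - l, en + l, n_bins)
    if (as.character(GenomicRanges::strand(genes)[k]) == "-") p <- rev(p)
    acc <- acc + p
    n_used <- n_used + 1L
  }
  list(profile = acc / n_used, n = n_used)
}

#' Off-diagonal pileup of peak pairs
#'
#' For every pair of peaks with genomic (midpoint) distance within
#' `dist_range`, averages the fixed-size obs/exp window centered at the
#' peak-pair pixel. Pairs whose window leaves the map are skipped.
#'
#' @param oe an [compute_obs_exp()] map.
#' @param peaks `GRanges` of peak intervals (precomputed, e.g. top third by
#'   fold-change).
#' @param window half-width in bins of the square window (default 10).
#' @param dist_range genomic distance filter in bp (default 160-320 kb).
#' @return list: `mean` ((2w+1)^2 matrix or `NULL`), `n_pairs`, `n_skipped`.
#' @export
peak_pileup <- function(oe, peaks, window = 10, dist_range = c(160e3, 320e3)) {
  mids <- (GenomicRanges::start(peaks) - 1 + GenomicRanges::end(peaks)) / 2
  mids <- sort(mids)
  res <- oe$resolution
  nb <- n_bins(oe)
  w <- window
  size <- 2 * w + 1
  acc <- matrix(0, size, size)
  cntm <- matrix(0, size, size)
  n_used <- 0L
  n_skipped <- 0L
  np <- length(mids)
  if (np >= 2) for (i in seq_len(np - 1)) for (j in seq.int(i + 1, np)) {
    d <- mids[j] - mids[i]
    if (d < dist_range[1] || d > dist_range[2]) next
    bi <- floor(mids[i] / res) + 1
    bj <- floor(mids[j] / res) + 1
    if (bi - w < 1 || bi + w > nb || bj - w < 1 || bj + w > nb) {
      n_skipped <- n_skipped + 1L
      next
    }
    blk <- oe$values[seq.int(bi - w, bi + w), seq.int(bj - w, bj + w)]
    ok <- !is.na(blk)
    acc[ok] <- acc[ok] + blk[ok]
    cntm <- cntm + ok
    n_used <- n_used + 1L
  }
  if (n_used == 0L)
    return(list(mean = NULL, n_pairs = 0L, n_skipped = n_skipped))
  m <- acc / cntm
  m[cntm == 0] <- NA_real_
  list(mean = m, n_pairs = n_used, n_skipped = n_skipped)
}
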