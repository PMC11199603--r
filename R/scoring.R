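#' Choose the working resolution for a gene
#'
#' Returns the coarsest available resolution `r` satisfying
#' `gene length > 20 * r`, which maximizes counts per pixel while keeping at
#' least 20 bins along the gene. Genes shorter than 20x the finest available
#' resolution are excluded (`NA`).
#'
#' @param gene_length gene length in bp.
#' @param available numeric vector of available resolutions (bp).
#' @return resolution in bp, or `NA_real_` if no resolution qualifies.
#' @export
choose_resolution <- function(gene_length, available) {
  available <- sort(as.numeric(available))
  ok <- available[gene_length > 20 * available]
  if (!length(ok)) NA_real_ else max(ok)
}

#' Base-pair-weighted coverage per bin
#'
#' Mean track value over each bin of a regular grid, weighting each track
#' interval by its base-pair overlap with the bin; uncovered base pairs count
#' as zero coverage (bedGraph semantics). Bin boundaries may be fractional.
#'
#' @param track `GRanges` with a `score` column.
#' @param chrom chromosome to use.
#' @param start,end region in bp (0-based half-open).
#' @param n_bins number of equal bins over the region.
#' @return numeric vector of length `n_bins`.
#' @export
bin_coverage <- function(track, chrom, start, end, n_bins) {
  keep <- as.character(GenomicRanges::seqnames(track)) == chrom
  t0 <- GenomicRanges::start(track)[keep] - 1 # back to 0-based half-open
  t1 <- GenomicRanges::end(track)[keep]
  sc <- S4Vectors::mcols(track)$score[keep]
  edges <- seq(start, end, length.out = n_bins + 1)
  out <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    ov <- pmin(t1, edges[b + 1]) - pmax(t0, edges[b])
    ov[ov < 0] <- 0
    out[b] <- sum(ov * sc) / (edges[b + 1] - edges[b])
  }
  out
}

#' Intra-gene contact (IC) score
#'
#' Mean obs/exp value `c_ij` over all unmasked bin pairs `i < j` inside the
#' gene body: `IC = sum_{i<j} c_ij / (N(N-1)/2)` where `N` is the number of
#' gene bins at the working resolution. The diagonal is excluded. `NA` when
#' fewer than two gene bins exist or all pairs are masked.
#'
#' @param oe an [compute_obs_exp()] map.
#' @param start,end gene coordinates in bp (0-based half-open).
#' @return IC score (dimensionless).
#' @export
ic_score <- function(oe, start, end) {
  bins <- gene_bins(start, end, oe$resolution)
  bins <- bins[bins >= 1 & bins <= n_bins(oe)]
  if (length(bins) < 2) return(NA_real_)
  block <- oe$values[bins, bins]
  ut <- block[upper.tri(block)]
  if (all(is.na(ut))) return(NA_real_)
  mean(ut, na.rm = TRUE)
}

#' Pol II enrichment (IR) score
#'
#' Mean of the per-bin track coverage `p_i` over the `N` gene-body bins at
#' the working resolution: `IR = sum_i p_i / N`. Coverage per bin is
#' base-pair-weighted.
#'
#' @param track `GRanges` with `score`.
#' @param chrom,start,end gene location (bp, 0-based half-open).
#' @param resolution working resolution in bp.
#' @return IR score (track units).
#' @export
ir_score <- function(track, chrom, start, end, resolution) {
  n <- floor((end - start) / resolution)
  if (n < 1) return(NA_real_)
  p <- bin_coverage(track, chrom, start, start + n * resolution, n)
  mean(p)
}

#' Score genes: per-gene IC and IR
#'
#' Driver over a gene annotation. For each gene the working resolution is
#' chosen with [choose_resolution()] among the supplied matrices, the obs/exp
#' map computed (once per matrix), and IC/IR evaluated over the gene body.
#' Genes shorter than `min_length` bp, or too short for every available
#' resolution, are excluded (reported via the `excluded` attribute).
#'
#' @param matrices a [contact_matrix()] or list of them (one per resolution).
#' @param track `GRanges` coverage track (or `NULL` to skip IR).
#' @param genes stranded `GRanges` of genes (ids in `name` if present).
#' @param min_length minimum gene length in bp (default 1 kb).
#' @return data.frame with columns gene, chrom, start, end, strand,
#'   resolution, N, IC, IR.
#' @export
score_genes <- function(matrices, track, genes, min_length = 1000) {
  if (inherits(matrices, "contact_matrix")) matrices <- list(matrices)
  res_avail <- vapply(matrices, function(m) m$resolution, numeric(1))
  oes <- lapply(matrices, function(m)
    if (inherits(m, "obs_exp_matrix")) m else compute_obs_exp(m))
  ids <- if (!is.null(S4Vectors::mcols(genes)$name))
    as.character(S4Vectors::mcols(genes)$name)
  else sprintf("gene%03d", seq_along(genes))
  start <- GenomicRanges::start(genes) - 1
  end <- GenomicRanges::end(genes)
  len <- end - start
  rows <- list()
  excluded <- character()
  for (k in seq_along(genes)) {
    if (len[k] < min_length) {
      excluded <- c(excluded, ids[k])
      next
    }
    r <- choose_resolution(len[k], res_avail)
    if (is.na(r)) {
      excluded <- c(excluded, ids[k])
      next
    }
    oe <- oes[[which(res_avail == r)[1]]]
    chrom <- as.character(GenomicRanges::seqnames(genes)[k])
    ic <- ic_score(oe, start[k], end[k])
    ir <- if (is.null(track)) NA_real_ else
      ir_score(track, chrom, start[k], end[k], r)
    rows[[length(rows) + 1]] <- data.frame(
      gene = ids[k], chrom = chrom, start = start[k], end = end[k],
      strand = as.character(GenomicRanges::strand(genes)[k]),
      resolution = r, N = floor(len[k] / r), IC = ic, IR = ir,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), chrom = character(), start = numeric(),
               end = numeric(), strand = character(), resolution = numeric(),
               N = integer(), IC = numeric(), IR = numeric())
  attr(out, "excluded") <- excluded
  out
}

#' Cluster genes by Pol II enrichment and length
#'
#' Assigns each gene an integer IR bin (`round(log2(IR))`) and a dyadic
#' length bin (..., "32-64 kb", "64-128 kb", ...). Genes with `IR <= 0` fall
#' into the lowest occupied IR bin. Clusters with fewer than `min_members`
#' genes are flagged as under-powered for map pileups.
#'
#' @param scores data.frame from [score_genes()].
#' @param min_members minimum cluster size for pileups (default 25).
#' @return `scores` with added columns ir_bin, length_bin, cluster,
#'   cluster_n, underpowered.
#' @export
cluster_genes <- function(scores, min_members = 25) {
  ir <- scores$IR
  bad <- !is.na(ir) & ir <= 0
  irb <- rep(NA_integer_, length(ir))
  irb[!bad & !is.na(ir)] <- as.integer(round(log2(ir[!bad & !is.na(ir)])))
  if (any(bad)) {
    low <- if (any(!bad & !is.na(ir))) min(irb, na.rm = TRUE) else 0L
    irb[bad] <- low
    message(sum(bad), " gene(s) with IR <= 0 assigned to lowest IR bin")
  }
  len <- scores$end - scores$start
  lb <- floor(log2(len / 1000))
  length_bin <- sprintf("%g-%g kb", 2^lb, 2^(lb + 1))
  cluster <- paste0("IR", irb, "|", length_bin)
  cl_n <- table(cluster)
  scores$ir_bin <- irb
  scores$length_bin <- length_bin
  scores$cluster <- cluster
  scores$cluster_n <- as.integer(cl_n[cluster])
  scores$underpowered <- scores$cluster_n < min_members
  scores
}

#' Compare per-gene scores between two conditions
#'
#' Per-gene log2 fold-changes of IC and IR between matched score tables, and
#' their Spearman rank correlation (average ranks on ties). Genes missing
#' from either condition are dropped and counted.
#'
#' @param a,b data.frames from [score_genes()] (conditions A and B).
#' @return list with `table` (gene, dIC, dIR), `spearman`, `n_dropped`,
#'   `constant` (TRUE when a correlation is undefined because one variable
#'   is constant).
#' @export
compare_conditions <- function(a, b) {
  common <- intersect(a$gene, b$gene)
  n_dropped <- (nrow(a) - length(common)) + (nrow(b) - length(common))
  ia <- a[match(common, a$gene), ]
  ib <- b[match(common, b$gene), ]
  tab <- data.frame(
    gene = common,
    dIC = log2(ib$IC / ia$IC),
    dIR = log2(ib$IR / ia$IR))
  ok <- is.finite(tab$dIC) & is.finite(tab$dIR)
  constant <- sum(ok) < 2 ||
    sd(tab$dIC[ok]) == 0 || sd(tab$dIR[ok]) == 0
  rho <- if (constant) NA_real_ else
    cor(rank(tab$dIC[ok]), rank(tab$dIR[ok])) # Spearman via average ranks
  list(table = tab, spearman = rho, n_dropped = n_dropped,
       constant = constant)
}

#' Filter genes by track occupancy quantile
#'
#' Removes genes whose mean occupancy (base-pair-weighted track mean over the
#' gene body) exceeds the given quantile of the per-gene occupancy
#' distribution. Used e.g. to exclude genes with high cohesin (SMC1a)
#' occupancy.
#'
#' @param genes stranded `GRanges`.
#' @param track `GRanges` with `score`.
#' @param quantile occupancy quantile above which genes are removed;
#'   1 removes none, 0 removes every gene above the minimum.
#' @return subset of `genes`.
#' @export
filter_by_track <- function(genes, track, quantile = 0.75) {
  occ <- vapply(seq_along(genes), function(k) {
    bin_coverage(track,
                 as.character(GenomicRanges::seqnames(genes)[k]),
                 GenomicRanges::start(genes)[k] - 1,
                 GenomicRanges::end(genes)[k], 1)
  }, numeric(1))
  thr <- stats::quantile(occ, quantile, names = FALSE)
  genes[occ <= thr]
}
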