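#' Specification for a synthetic chromosome
#'
#' Defines a synthetic chromosome with a power-law distance decay contact
#' matrix, implanted intra-gene enrichment, TSS-TTS loops and promoter
#' stripes, plus a Pol II-like coverage track (gene-body plateau with Gaussian
#' TSS/TTS peaks). The generator emulates the statistical patterns the
#' scoring and pile-up stages assume, with known ground truth.
#'
#' @param chrom_length chromosome length in bp.
#' @param resolution contact-map bin size in bp.
#' @param genes data.frame with columns `start`, `end` (bp, 0-based
#'   half-open), `strand` ("+"/"-"); optional `enrichment` (intra-gene
#'   contact multiplier g >= 1), `loop_strength`, `stripe_strength`,
#'   `plateau` (track level over the gene body), `id`.
#' @param decay_exponent exponent of the baseline decay
#'   `contact(d) = (d/resolution + 1)^-exponent`.
#' @param noise_level sigma of multiplicative lognormal pixel noise (mean 1);
#'   0 disables noise.
#' @param track_bin bedGraph bin width in bp for the coverage track.
#' @param background track background level outside genes.
#' @param tss_height,tts_height,peak_width Gaussian peak heights at TSS/TTS
#'   and their s.d. in bp.
#' @param seed RNG seed used by the generators.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(chrom_length, resolution,
                       genes = NULL,
                       decay_exponent = 1, noise_level = 0,
                       track_bin = NULL, background = 0.1,
                       tss_height = 0, tts_height = 0, peak_width = 500,
                       seed = 1L) {
  if (is.null(genes))
    genes <- data.frame(start = numeric(), end = numeric(),
                        strand = character())
  genes <- as.data.frame(genes)
  if (!all(c("start", "end", "strand") %in% names(genes)))
    stop("genes needs start, end, strand columns")
  if (is.null(genes$enrichment)) genes$enrichment <- rep(1, nrow(genes))
  if (is.null(genes$loop_strength)) genes$loop_strength <- rep(1, nrow(genes))
  if (is.null(genes$stripe_strength)) genes$stripe_strength <- rep(1, nrow(genes))
  if (is.null(genes$plateau)) genes$plateau <- rep(1, nrow(genes))
  if (is.null(genes$id)) genes$id <- sprintf("gene%03d", seq_len(max(nrow(genes), 0)))
  if (nrow(genes)) {
    if (any(genes$start < 0 | genes$end > chrom_length))
      stop("genes must lie within [0, chrom_length)")
    if (any(genes$end <= genes$start)) stop("genes must have positive length")
    if (any(genes$enrichment < 1)) stop("enrichment_factor must be >= 1")
    if (any(genes$plateau < 0) || background < 0 ||
        tss_height < 0 || tts_height < 0)
      stop("track levels must be non-negative")
    if (!all(genes$strand %in% c("+", "-"))) stop("strand must be + or -")
  }
  if (is.null(track_bin)) track_bin <- min(resolution, 200)
  structure(list(
    chrom_length = chrom_length, resolution = resolution, genes = genes,
    decay_exponent = decay_exponent, noise_level = noise_level,
    track_bin = track_bin, background = background,
    tss_height = tss_height, tts_height = tts_height,
    peak_width = peak_width, seed = as.integer(seed),
    chrom = "chrS"), class = "synth_spec")
}

gene_bins <- function(start, end, resolution) {
  b0 <- floor(start / resolution)
  n <- floor((end - start) / resolution)
  if (n < 1) return(integer())
  seq.int(b0 + 1, b0 + n) # 1-based bin indices
}

tss_tts_bins <- function(g, resolution) {
  bins <- gene_bins(g$start, g$end, resolution)
  if (g$strand == "+") c(tss = bins[1], tts = bins[length(bins)])
  else c(tss = bins[length(bins)], tts = bins[1])
}

#' Generate a synthetic contact matrix
#'
#' Baseline expectation depends only on bin separation
#' (`(d + 1)^-decay_exponent` in bins); within each gene body all pairwise
#' expectations are multiplied by the gene's enrichment factor g; the TSS-TTS
#' pixel neighborhood is multiplied by `loop_strength` and the TSS row/column
#' within the gene by `stripe_strength`. Multiplicative lognormal noise with
#' unit mean is applied per pixel and the two triangles are averaged so the
#' output stays symmetric and positive. Genes whose bin ranges overlap with
#' conflicting enrichment factors are rejected.
#'
#' @param spec a [synth_spec()].
#' @return a [contact_matrix()].
#' @export
synth_contact_matrix <- function(spec) {
  set.seed(spec$seed)
  res <- spec$resolution
  nb <- ceiling(spec$chrom_length / res)
  d <- abs(row(diag(nb)) - col(diag(nb)))
  base <- (d + 1)^(-spec$decay_exponent)
  fac <- matrix(1, nb, nb)
  g <- spec$genes
  if (nrow(g)) {
    owner <- rep(NA_integer_, nb)
    for (k in seq_len(nrow(g))) {
      bins <- gene_bins(g$start[k], g$end[k], res)
      prev <- owner[bins]
      clash <- !is.na(prev) & g$enrichment[prev] != g$enrichment[k]
      if (any(clash))
        stop("overlapping genes with conflicting enrichment factors: ",
             g$id[k], " vs ", g$id[prev[clash][1]])
      owner[bins] <- k
      fac[bins, bins] <- g$enrichment[k]
    }
    for (k in seq_len(nrow(g))) {
      bins <- gene_bins(g$start[k], g$end[k], res)
      at <- tss_tts_bins(g[k, ], res)
      if (g$loop_strength[k] != 1) {
        nbh <- function(b) intersect(b + (-1:1), seq_len(nb))
        fac[nbh(at["tss"]), nbh(at["tts"])] <-
          fac[nbh(at["tss"]), nbh(at["tts"])] * g$loop_strength[k]
        fac[nbh(at["tts"]), nbh(at["tss"])] <-
          fac[nbh(at["tts"]), nbh(at["tss"])] * g$loop_strength[k]
      }
      if (g$stripe_strength[k] != 1) {
        body <- setdiff(bins, at["tss"])
        fac[at["tss"], body] <- fac[at["tss"], body] * g$stripe_strength[k]
        fac[body, at["tss"]] <- fac[body, at["tss"]] * g$stripe_strength[k]
      }
    }
  }
  obs <- base * fac
  if (spec$noise_level > 0) {
    sig <- spec$noise_level
    eps <- matrix(rlnorm(nb * nb, meanlog = -sig^2 / 2, sdlog = sig), nb, nb)
    obs <- obs * eps
    obs <- (obs + t(obs)) / 2
  }
  contact_matrix(obs, res, spec$chrom)
}

#' Generate a synthetic Pol II-like coverage track
#'
#' Constant background, a plateau over each gene body, and Gaussian peaks at
#' the TSS and TTS (for reverse-strand genes the TSS peak sits at the right
#' genomic edge). Values are evaluated at bin midpoints on a regular grid of
#' `track_bin`-bp intervals.
#'
#' @param spec a [synth_spec()].
#' @return a `GRanges` with a `score` column (bedGraph-style).
#' @export
synth_track <- function(spec) {
  set.seed(spec$seed + 1L)
  bw <- spec$track_bin
  starts <- seq(0, spec$chrom_length - 1, by = bw)
  ends <- pmin(starts + bw, spec$chrom_length)
  mid <- (starts + ends) / 2
  val <- rep(spec$background, length(mid))
  g <- spec$genes
  for (k in seq_len(nrow(g))) {
    body <- mid >= g$start[k] & mid < g$end[k]
    val[body] <- val[body] + g$plateau[k]
    tss <- if (g$strand[k] == "+") g$start[k] else g$end[k]
    tts <- if (g$strand[k] == "+") g$end[k] else g$start[k]
    if (spec$tss_height > 0)
      val <- val + spec$tss_height * exp(-(mid - tss)^2 / (2 * spec$peak_width^2))
    if (spec$tts_height > 0)
      val <- val + spec$tts_height * exp(-(mid - tts)^2 / (2 * spec$peak_width^2))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = spec$chrom,
    ranges = IRanges::IRanges(start = starts + 1, end = ends),
    score = val)
  gr
}

#' Synthetic gene annotation as GRanges
#' @param spec a [synth_spec()].
#' @return a stranded `GRanges` with gene ids in `name`.
#' @export
synth_genes <- function(spec) {
  g <- spec$genes
  if (nrow(g) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = spec$chrom,
    ranges = IRanges::IRanges(start = g$start + 1, end = g$end),
    strand = g$strand, name = g$id)
}

#' Write a synthetic fixture to disk
#'
#' Emits the contact matrix (dense text), coverage track (bedGraph) and gene
#' annotation (BED, 0-based half-open) so the scoring stages can read them
#' back identically. Regeneration with the same spec (same seed) produces
#' identical files.
#'
#' @param spec a [synth_spec()].
#' @param outdir output directory (created if missing).
#' @return named character vector of file paths.
#' @export
write_fixture <- function(spec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(outdir, "matrix.tsv"),
             track = file.path(outdir, "track.bedGraph"),
             genes = file.path(outdir, "genes.bed"))
  write_contact_matrix(synth_contact_matrix(spec), paths["matrix"])
  trk <- synth_track(spec)
  rtracklayer::export.bedGraph(trk, paths["track"])
  genes <- synth_genes(spec)
  rtracklayer::export.bed(genes, paths["genes"])
  paths
}

#' Read a coverage track (bedGraph)
#' @param path bedGraph file.
#' @return `GRanges` with `score`.
#' @export
read_track <- function(path) {
  rtracklayer::import.bedGraph(path)
}

#' Read gene annotation (BED or GTF)
#'
#' BED input is converted from its on-disk 0-based half-open convention by
#' the importer; GTF gene records are used as-is.
#'
#' @param path BED or GTF file.
#' @param format "bed" or "gtf" (guessed from the extension by default).
#' @return stranded `GRanges`.
#' @export
read_genes <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE))
      "gtf" else "bed"
  gr <- rtracklayer::import(path, format = format)
  if (format == "gtf" && "type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  gr
}
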