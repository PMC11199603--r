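flat_oe <- function(n, res = 1000) {
  oe <- contact_matrix(matrix(1, n, n), res)
  class(oe) <- c("obs_exp_matrix", "contact_matrix")
  oe
}

test_that("extract_block takes the gene body plus equal flanks", {
  oe <- flat_oe(40)
  # gene occupying 0-based bins [10, 20) -> window bins [0, 30)
  blk <- extract_block(oe, 10 * 1000, 20 * 1000)
  expect_equal(blk$bins, 1:30)
  expect_equal(dim(blk$block), c(30, 30))
  expect_equal(blk$l, 10)
  # block center equals the gene midpoint bin
  expect_equal(blk$bins[15] + 0.5, 15.5)
  # a gene at the chromosome edge is skipped
  expect_null(extract_block(oe, 2 * 1000, 12 * 1000))
  expect_null(extract_block(oe, 32 * 1000, 38 * 1000))
})

test_that("rescale_to area-averages and preserves the mean", {
  expect_equal(rescale_to(matrix(1, 120, 120), 60), matrix(1, 60, 60))
  # integer ratio: each output pixel is the mean of its 2x2 source block
  set.seed(21)
  m <- matrix(rnorm(120^2), 120, 120)
  r <- rescale_to(m, 60)
  want <- matrix(0, 60, 60)
  for (i in 1:60) for (j in 1:60)
    want[i, j] <- mean(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_equal(r, want, tolerance = 1e-12)
  expect_equal(mean(r), mean(m), tolerance = 1e-12)
  # constancy under non-integer ratio, and mean within 1%
  expect_equal(rescale_to(matrix(3, 90, 90), 60), matrix(3, 60, 60))
  m2 <- matrix(runif(90^2), 90, 90)
  expect_equal(mean(rescale_to(m2, 60)), mean(m2), tolerance = 0.01)
  # never upsample
  expect_error(rescale_to(matrix(1, 30, 30), 60), "upsample")
  # masked pixels drop out of numerator and denominator
  m3 <- matrix(1, 120, 120)
  m3[1, 2] <- NA
  m3[3, 4] <- 5
  r3 <- rescale_to(m3, 60)
  expect_equal(r3[1, 1], 1)      # NA contributor excluded
  expect_equal(r3[2, 2], 2)      # (1+1+1+5)/4
  m4 <- matrix(1, 120, 120)
  m4[1:2, 1:2] <- NA
  expect_true(is.na(rescale_to(m4, 60)[1, 1]))
})

test_that("orientation rotates reverse-strand blocks 180 degrees", {
  b <- matrix(0, 60, 60)
  b[1, 1] <- 1
  expect_equal(orient_block(b, "+"), b)
  r <- orient_block(b, "-")
  expect_equal(r[60, 60], 1)
  expect_equal(sum(r), 1)
  expect_equal(orient_block(orient_block(b, "-"), "-"), b)
})

test_that("intra-gene pileup aggregates oriented rescaled blocks", {
  set.seed(5)
  n <- 200
  v <- matrix(runif(n * n, 0.5, 1.5), n, n)
  v <- (v + t(v)) / 2
  oe <- contact_matrix(v, 1000)
  class(oe) <- c("obs_exp_matrix", "contact_matrix")
  g1 <- c(40e3, 80e3)
  g2 <- c(120e3, 160e3)
  genes <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(c(g1[1], g2[1]) + 1, c(g1[2], g2[2])),
    strand = c("+", "-"))
  single <- pmga_intra(oe, genes[1])
  want1 <- rescale_to(extract_block(oe, g1[1], g1[2])$block, 60)
  expect_equal(single$mean, want1)
  both <- pmga_intra(oe, genes)
  want2 <- orient_block(rescale_to(extract_block(oe, g2[1], g2[2])$block, 60),
                        "-")
  expect_equal(both$mean, (want1 + want2) / 2)
  expect_equal(both$n, 2L)
  # a cluster of identical blocks equals the single block
  genes3 <- rep(genes[1], 5)
  expect_equal(pmga_intra(oe, genes3)$mean, want1)
  expect_error(pmga_intra(oe, genes[0]), "empty")
})

test_that("implanted TSS-TTS loops enrich the pileup corner", {
  spec <- synth_spec(
    chrom_length = 8e6, resolution = 5000,
    genes = data.frame(start = seq(5e5, 6.5e6, by = 6e5),
                       end = seq(5e5, 6.5e6, by = 6e5) + 2e5,
                       strand = rep(c("+", "-"), length.out = 11),
                       enrichment = 1.2, loop_strength = 4),
    seed = 2, noise_level = 0.1)
  oe <- compute_obs_exp(synth_contact_matrix(spec))
  pr <- pmga_intra(oe, synth_genes(spec))
  # TSS row 21, TTS column 40 in the 60x60 pseudo-matrix
  corner <- pr$mean[20:22, 39:41]
  expect_gt(mean(corner), median(pr$mean, na.rm = TRUE))
})

test_that("inter-gene pileup filters by separation and flips per strand", {
  oe <- flat_oe(400, 1000)
  genes <- GenomicRanges::GRanges(
    "chrS",
    IRanges::IRanges(c(50e3, 250e3) + 1, c(70e3, 270e3)),
    strand = c("+", "+"))
  pr <- pmga_inter(oe, genes, min_sep = 128e3, max_sep = 2e6)
  expect_equal(pr$n, 1L)
  expect_equal(pr$mean, matrix(1, 30, 30))
  # pair separation below the window: nothing aggregated
  expect_equal(pmga_inter(oe, genes, min_sep = 300e3)$n, 0L)
  # brute-force pair enumeration on a constructed gene set
  set.seed(13)
  starts <- sort(sample(seq(30e3, 360e3, by = 1e3), 8))
  gl <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(starts + 1, starts + 10e3), strand = "+")
  mids <- starts + 5e3
  want <- 0L
  for (i in 1:7) for (j in (i + 1):8) {
    sep <- abs(mids[j] - mids[i])
    if (sep > 40e3 && sep < 200e3) {
      w1 <- genefold:::gene_window_bins(oe, starts[i], starts[i] + 10e3)
      w2 <- genefold:::gene_window_bins(oe, starts[j], starts[j] + 10e3)
      if (!is.null(w1) && !is.null(w2) && !length(intersect(w1, w2)))
        want <- want + 1L
    }
  }
  got <- pmga_inter(oe, gl, min_sep = 40e3, max_sep = 200e3)
  expect_equal(got$n, want)
  # implanted body-body enrichment shows up in the center, not the border
  v2 <- matrix(1, 400, 400)
  b1 <- 51:70
  b2 <- 251:270
  v2[b1, b2] <- 3
  v2[b2, b1] <- 3
  oe2 <- flat_oe(400)
  oe2$values <- v2
  pr2 <- pmga_inter(oe2, genes, min_sep = 128e3, max_sep = 2e6)
  center <- pr2$mean[11:20, 11:20]
  border <- pr2$mean[c(1:5, 26:30), c(1:5, 26:30)]
  expect_gt(mean(center), mean(border))
  expect_equal(mean(center), 3)
})

test_that("chip metagene is flat on constant tracks and strand-aware", {
  const <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(1, 4e6), score = 2.5)
  genes <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(1e6 + 1, 1.2e6), strand = "+")
  prof <- chip_metagene(const, genes)
  expect_equal(prof$profile, rep(2.5, 60))
  # synthetic TSS peak lands at the start of the middle third
  spec_f <- one_gene_spec(chrom_length = 4e6, start = 1e6, end = 1.2e6,
                          plateau = 1, tss_height = 8, peak_width = 2000,
                          background = 0)
  pf <- chip_metagene(synth_track(spec_f),
                      GenomicRanges::GRanges(
                        "chrS", IRanges::IRanges(1e6 + 1, 1.2e6), strand = "+"))
  expect_true(which.max(pf$profile) %in% 20:22)
  # reverse-strand gene: peak at the genomic right edge, same profile bin
  spec_r <- one_gene_spec(chrom_length = 4e6, start = 1e6, end = 1.2e6,
                          strand = "-", plateau = 1, tss_height = 8,
                          peak_width = 2000, background = 0)
  pr <- chip_metagene(synth_track(spec_r),
                      GenomicRanges::GRanges(
                        "chrS", IRanges::IRanges(1e6 + 1, 1.2e6), strand = "-"))
  expect_true(which.max(pr$profile) %in% 20:22)
})

test_that("peak-pair pileup enumerates pairs in the distance window", {
  oe <- flat_oe(3000, 1000)
  # no pair in range
  pk <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(c(100e3, 150e3) + 1, width = 200))
  out <- peak_pileup(oe, pk)
  expect_equal(out$n_pairs, 0L)
  expect_null(out$mean)
  # implanted loops at all in-range peak pairs
  mids <- seq(500e3, 2.4e6, by = 110e3)
  v <- matrix(1, 3000, 3000)
  want <- 0L
  for (i in seq_along(mids)) for (j in seq_along(mids)) {
    if (i < j && abs(mids[j] - mids[i]) >= 160e3 &&
        abs(mids[j] - mids[i]) <= 320e3) {
      bi <- floor(mids[i] / 1000) + 1
      bj <- floor(mids[j] / 1000) + 1
      v[bi, bj] <- v[bj, bi] <- 10
      want <- want + 1L
    }
  }
  oe2 <- flat_oe(3000)
  oe2$values <- v
  pk2 <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(mids - 100 + 1, mids + 100))
  out2 <- peak_pileup(oe2, pk2)
  expect_equal(out2$n_pairs, want)
  expect_gt(want, 0L)
  # center pixel is the maximum of the averaged window
  expect_equal(which.max(out2$mean), 221L)
})
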