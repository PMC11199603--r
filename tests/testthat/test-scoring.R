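test_that("compute_expected matches brute-force per-diagonal means", {
  # exact distance function
  n <- 40
  f <- function(d) 1 / (d + 2)
  v <- outer(1:n, 1:n, function(i, j) f(abs(i - j)))
  m <- contact_matrix(v, 1000)
  expect_equal(compute_expected(m), f(0:(n - 1)))
  # all ones
  m1 <- contact_matrix(matrix(1, 10, 10), 1000)
  expect_equal(compute_expected(m1), rep(1, 10))
  # random with mask vs loop oracle
  set.seed(42)
  r <- matrix(rexp(30 * 30), 30, 30)
  r <- (r + t(r)) / 2
  mask <- c(4L, 17L, 18L)
  mr <- contact_matrix(r, 1000, mask = mask)
  expect_equal(compute_expected(mr), brute_expected(r, mask))
})

test_that("obs/exp normalizes diagonals to 1, is scale-invariant, masked", {
  set.seed(7)
  n <- 50
  r <- matrix(rexp(n * n) + 0.1, n, n)
  r <- (r + t(r)) / 2
  m <- contact_matrix(r, 1000, mask = c(3L, 30L))
  oe <- compute_obs_exp(m)
  # every unmasked diagonal averages to 1
  for (d in c(0, 1, 5, 20, n - 1)) {
    i <- seq_len(n - d)
    vals <- oe$values[cbind(i, i + d)]
    expect_equal(mean(vals, na.rm = TRUE), 1, tolerance = 1e-9)
  }
  # scale invariance
  m2 <- contact_matrix(2 * r, 1000, mask = c(3L, 30L))
  expect_equal(compute_obs_exp(m2)$values, oe$values)
  # spot checks against hand division
  e <- compute_expected(m)
  set.seed(8)
  for (k in 1:10) {
    i <- sample(setdiff(1:n, c(3, 30)), 1)
    j <- sample(setdiff(1:n, c(3, 30)), 1)
    expect_equal(oe$values[i, j], r[i, j] / e[abs(i - j) + 1])
  }
  # masked rows propagate
  expect_true(all(is.na(oe$values[3, ])))
})

test_that("resolution rule picks the coarsest with >20 bins per gene", {
  avail <- c(100, 800, 1600, 3200, 50000)
  expect_equal(choose_resolution(110e3, avail), 3200)
  expect_true(is.na(choose_resolution(1900, avail)))
  expect_equal(choose_resolution(2100, avail), 100)
  # enumeration oracle over random lengths
  set.seed(3)
  for (len in round(runif(50, 500, 2e6))) {
    ok <- avail[20 * avail < len]
    want <- if (length(ok)) max(ok) else NA_real_
    expect_identical(choose_resolution(len, avail), want)
  }
})

test_that("IC is the enumerated mean over upper-triangle gene pairs", {
  n <- 30
  res <- 1000
  oe_flat <- compute_obs_exp(contact_matrix(matrix(1, n, n), res))
  expect_equal(ic_score(oe_flat, 10 * res, 16 * res), 1)
  # N = 2: single pair
  v <- matrix(1, n, n)
  v[11, 12] <- v[12, 11] <- 2
  oe <- contact_matrix(matrix(1, n, n), res)
  oe$values <- v
  class(oe) <- c("obs_exp_matrix", "contact_matrix")
  expect_equal(ic_score(oe, 10 * res, 12 * res), 2)
  # N = 6 random block vs enumeration
  set.seed(9)
  r <- matrix(runif(n * n), n, n)
  r <- (r + t(r)) / 2
  oe$values <- r
  got <- ic_score(oe, 4 * res, 10 * res)
  bins <- 5:10
  acc <- c()
  for (a in seq_along(bins)) for (b in seq_along(bins))
    if (a < b) acc <- c(acc, r[bins[a], bins[b]])
  expect_length(acc, 15)
  expect_equal(got, mean(acc))
})

test_that("IR handles constant, per-bin and partial-overlap tracks", {
  gr <- function(starts, ends, scores)
    GenomicRanges::GRanges("chrS", IRanges::IRanges(starts + 1, ends),
                           score = scores)
  expect_equal(ir_score(gr(0, 10000, 3), "chrS", 2000, 8000, 1000), 3)
  t2 <- gr(c(0, 1000, 2000, 3000), c(1000, 2000, 3000, 4000), 1:4)
  expect_equal(ir_score(t2, "chrS", 0, 4000, 1000), 2.5)
  # partial overlaps vs base-pair oracle at 1-bp granularity
  t3 <- gr(c(0, 1500, 3700), c(1500, 3700, 6000), c(2, 5, 1))
  got <- ir_score(t3, "chrS", 1000, 5000, 2000)
  bp <- rep(0, 6000)
  bp[1:1500] <- 2; bp[1501:3700] <- 5; bp[3701:6000] <- 1
  want <- mean(c(mean(bp[1001:3000]), mean(bp[3001:5000])))
  expect_equal(got, want)
})

test_that("IR/length clustering uses log2 bins and flags small clusters", {
  sc <- data.frame(
    gene = sprintf("g%02d", 1:26),
    start = 0, end = c(rep(70e3, 25), 40e3),
    IR = c(rep(1.0, 24), 6, 0),
    IC = 1)
  out <- cluster_genes(sc, min_members = 25)
  expect_equal(out$ir_bin[1], 0L)       # log2(1) = 0
  expect_equal(out$length_bin[1], "64-128 kb")
  expect_equal(out$ir_bin[25], 3L)      # log2(6) ~ 2.58 -> 3
  # 24-member cluster is under-powered
  expect_true(all(out$underpowered[1:24]))
  # IR <= 0 goes to the lowest bin
  expect_equal(out$ir_bin[26], min(out$ir_bin))
})

test_that("condition comparison computes fold-changes and Spearman", {
  set.seed(11)
  a <- data.frame(gene = sprintf("g%02d", 1:30),
                  IC = runif(30, 0.5, 3), IR = runif(30, 0.1, 8))
  # identical: zero fold-changes, undefined correlation
  same <- compare_conditions(a, a)
  expect_true(all(same$table$dIC == 0))
  expect_true(same$constant)
  expect_true(is.na(same$spearman))
  # doubled IC: exactly 1 bit everywhere
  b <- a
  b$IC <- 2 * a$IC
  expect_equal(compare_conditions(a, b)$table$dIC, rep(1, 30))
  # random: equals stats::cor spearman
  b2 <- data.frame(gene = a$gene, IC = runif(30, 0.5, 3), IR = runif(30, 0.1, 8))
  cc <- compare_conditions(a, b2)
  want <- cor(cc$table$dIC, cc$table$dIR, method = "spearman")
  expect_equal(cc$spearman, want)
  # missing genes are dropped and counted
  cc2 <- compare_conditions(a[1:20, ], b2[6:30, ])
  expect_equal(cc2$n_dropped, 15)
})

test_that("occupancy quantile filter removes the expected genes", {
  genes <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(seq(1, by = 2e4, length.out = 20), width = 1e4),
    strand = "+")
  # bimodal occupancy: first 10 genes low (1), last 10 high (9)
  occ <- rep(c(1, 9), each = 10)
  trk <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(seq(1, by = 2e4, length.out = 20), width = 1e4),
    score = occ)
  expect_length(filter_by_track(genes, trk, quantile = 1), 20)
  expect_length(filter_by_track(genes, trk, quantile = 0.5), 10)
  kept <- filter_by_track(genes, trk, quantile = 0.5)
  expect_true(all(GenomicRanges::start(kept) %in%
                  GenomicRanges::start(genes)[1:10]))
  # quantile 0: everything above the minimum goes
  expect_length(filter_by_track(genes, trk, quantile = 0), 10)
})

test_that("IC rises monotonically with the implanted enrichment factor", {
  gs <- c(1, 1.5, 2, 3)
  ics <- vapply(gs, function(g) {
    spec <- one_gene_spec(g = g, noise = 0, chrom_length = 4e6,
                          start = 1.9e6, end = 2e6)
    ic_score(compute_obs_exp(synth_contact_matrix(spec)), 1.9e6, 2e6)
  }, numeric(1))
  expect_identical(order(ics), seq_along(gs))
  expect_equal(cor(rank(gs), rank(ics)), 1)
})

test_that("score_genes excludes short genes and logs them", {
  spec <- synth_spec(
    chrom_length = 2e6, resolution = 5000,
    genes = data.frame(start = c(1e5, 5e5), end = c(1e5 + 800, 7e5),
                       strand = c("+", "+")))
  cm <- synth_contact_matrix(spec)
  sc <- score_genes(cm, synth_track(spec), synth_genes(spec))
  expect_equal(nrow(sc), 1)
  expect_equal(attr(sc, "excluded"), "gene001")
})
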