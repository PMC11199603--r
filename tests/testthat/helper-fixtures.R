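# Shared fixture builders; everything is generated in code at test time.

one_gene_spec <- function(g = 2, loop = 1, stripe = 1, noise = 0, seed = 1,
                          chrom_length = 2e6, resolution = 5000,
                          start = 9e5, end = 1e6, strand = "+",
                          plateau = 1, ...) {
  synth_spec(
    chrom_length = chrom_length, resolution = resolution,
    genes = data.frame(start = start, end = end, strand = strand,
                       enrichment = g, loop_strength = loop,
                       stripe_strength = stripe, plateau = plateau),
    noise_level = noise, seed = seed, ...)
}

# independent brute-force per-diagonal expectation (loop-based oracle)
brute_expected <- function(values, mask = integer()) {
  n <- nrow(values)
  ok <- !(seq_len(n) %in% mask)
  out <- rep(NA_real_, n)
  for (d in 0:(n - 1)) {
    acc <- 0
    cnt <- 0
    for (i in seq_len(n - d)) {
      if (ok[i] && ok[i + d]) {
        acc <- acc + values[i, i + d]
        cnt <- cnt + 1
      }
    }
    if (cnt > 0) out[d + 1] <- acc / cnt
  }
  out
}

# R-side total Hamiltonian from a trajectory's final state (independent of
# the kernel's bookkeeping): bending + E * number of listed pairs
r_total_energy <- function(traj) {
  p <- traj$final_pos
  pp <- traj$params
  b <- diff(p)
  cosab <- rowSums(b[-nrow(b), , drop = FALSE] * b[-1, , drop = FALSE]) / 2
  bend <- pp$kappa * sum(1 - cosab)
  pairs <- sum(lengths(traj$final_lists)) / 2
  bend + pp$E * pairs
}

# small coupled run used by several tests
small_polymer <- function(N = 250, n_gene = 30, dens = 0.5, E = -3,
                          valency = Inf, mcs = 2e4, burn = 5e3,
                          snap = 100, seed = 1, ...) {
  tp <- tasep_params(n_gene, alpha = dens, beta = 1 - dens, gamma = 1)
  pp <- polymer_params(N, genes = list(list(start = (N - n_gene) %/% 2 + 1,
                                            tasep = tp)),
                       E = E, valency = valency)
  polymer_run(pp, mcs = mcs, burn_in = burn, snapshot_every = snap,
              seed = seed, ...)
}

# fabricate a minimal polymer_traj from an explicit snapshot position array
# (n_snap x 3R, unwrapped integer FCC coordinates)
fake_traj <- function(pos, box = c(100, 100, 100), monomer_nm = 50,
                      snapshot_every = 1, gene_span = NULL) {
  R <- ncol(pos) / 3
  if (is.null(gene_span)) gene_span <- c(1, R)
  tp <- tasep_params(gene_span[2] - gene_span[1] + 1,
                     alpha = 0, beta = 0, gamma = 0)
  pp <- structure(list(
    n_monomers = R, genes = list(list(start = gene_span[1], tasep = tp)),
    kappa = 0, E = 0, valency = 12L, box = as.integer(box),
    monomer_bp = 2000, monomer_nm = monomer_nm, dt = 5e-5),
    class = "polymer_params")
  structure(list(pos = pos, params = pp, record = c(1L, R),
                 snapshot_every = snapshot_every),
            class = "polymer_traj")
}
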