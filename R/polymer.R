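#' Choose a periodic box for a chain at a target lattice fill
#'
#' FCC sites are the integer triples with even coordinate sum; a box of even
#' dimensions Lx x Ly x Lz holds `Lx*Ly*Lz/2` sites, and the fill fraction is
#' `n / sites`. The initial serpentine configuration requires `Lx == Lz`
#' (both even) and even `Ly`. The search minimizes the deviation from the
#' requested fill subject to the chain fitting.
#'
#' @param n_monomers chain length.
#' @param fill target fill fraction (default 0.5, the chromatin-density
#'   calibration).
#' @return integer vector `c(Lx, Ly, Lz)`.
#' @export
polymer_box <- function(n_monomers, fill = 0.5) {
  best <- NULL
  best_err <- Inf
  for (L in seq(6, 200, by = 2)) {
    ly_t <- 2 * n_monomers / (fill * L^2) # sites = L^2*Ly/2
    for (Ly in unique(pmax(2, c(2 * floor(ly_t / 2), 2 * ceiling(ly_t / 2))))) {
      cap <- (Ly / 2) * L * (L / 2) + max(Ly / 2 - 1, 0)
      if (cap < n_monomers) next
      achieved <- n_monomers / (L^2 * Ly / 2)
      # fill deviations below 1.5% are equivalent in practice; among those,
      # prefer near-cubic boxes (thin boxes put a collapsed gene in contact
      # with its own periodic images)
      err <- 100 * max(abs(achieved - fill) - 0.015, 0) + abs(log(L / Ly))
      if (err < best_err) {
        best_err <- err
        best <- c(L, Ly, L)
      }
    }
  }
  if (is.null(best)) stop("no feasible box found")
  as.integer(best)
}

#' Parameters for the TASEP-decorated lattice polymer
#'
#' A self-avoiding semi-flexible chain of `n_monomers` on an FCC lattice with
#' periodic boundaries, bending rigidity `kappa` (kT), and short-range
#' attraction `E` (kT) between Pol II-bound monomers in lattice contact,
#' subject to a maximum number of simultaneous interaction partners
#' (`valency`; `Inf` caps at the FCC coordination number 12, i.e. unlimited
#' in practice). One or more genes carry TASEP occupancy dynamics; all other
#' monomers are neutral. One monomer represents `monomer_bp` bp and
#' `monomer_nm` nm (defaults 2 kb / 50 nm).
#'
#' @param n_monomers total chain length.
#' @param genes list of gene descriptors: each a list with `start` (1-based
#'   chain index of the TSS monomer) and `tasep` (a [tasep_params()], whose
#'   `n` sets the gene length). Default: one 50-monomer gene centered on the
#'   chain with uniform-density rates at `alpha/gamma = 0.5`.
#' @param kappa bending rigidity in kT (default 1.2).
#' @param E interaction strength in kT (default -3, attractive).
#' @param valency maximum simultaneous interaction partners per Pol II-bound
#'   monomer.
#' @param fill lattice fill fraction (default 0.5).
#' @param box optional explicit `c(Lx, Ly, Lz)`; derived from `fill`
#'   otherwise.
#' @param monomer_bp,monomer_nm coarse-graining of one monomer.
#' @return object of class `polymer_params`.
#' @export
polymer_params <- function(n_monomers, genes = NULL, kappa = 1.2, E = -3,
                           valency = Inf, fill = 0.5, box = NULL,
                           monomer_bp = 2000, monomer_nm = 50) {
  if (is.null(genes)) {
    tp <- tasep_params(n = 50, alpha = 0.5, beta = 0.5, gamma = 1)
    genes <- list(list(start = floor((n_monomers - 50) / 2) + 1, tasep = tp))
  }
  for (g in genes) {
    stopifnot(g$start >= 1, g$start + g$tasep$n - 1 <= n_monomers)
  }
  if (length(genes) > 1) {
    spans <- lapply(genes, function(g) seq(g$start, g$start + g$tasep$n - 1))
    if (length(Reduce(intersect, spans)) > 0 ||
        any(duplicated(unlist(spans))))
      stop("gene spans overlap")
  }
  dts <- vapply(genes, function(g) g$tasep$dt, numeric(1))
  if (length(unique(dts)) > 1) stop("all genes must share the same dt")
  if (is.null(box)) box <- polymer_box(n_monomers, fill)
  stopifnot(length(box) == 3, all(box %% 2 == 0), box[1] == box[3])
  val <- if (is.infinite(valency)) 12L else as.integer(valency)
  stopifnot(val >= 1, val <= 12)
  structure(list(n_monomers = as.integer(n_monomers), genes = genes,
                 kappa = kappa, E = E, valency = val,
                 valency_unlimited = is.infinite(valency),
                 fill = n_monomers / (prod(box) / 2), box = as.integer(box),
                 monomer_bp = monomer_bp, monomer_nm = monomer_nm,
                 dt = dts[1]),
            class = "polymer_params")
}

gene_span <- function(pp, gene = 1) {
  g <- pp$genes[[gene]]
  seq.int(g$start, g$start + g$tasep$n - 1)
}

#' Run the coupled TASEP-polymer kinetic Monte Carlo
#'
#' Each MCS performs one TASEP sweep per gene (binding, unbinding, n-1
#' elongation attempts, promoter switch) followed by `n_monomers` local
#' polymer trial moves (single-monomer relocations to vacant FCC sites
#' compatible with both chain neighbors, Metropolis-accepted on the change
#' in bending plus interaction energy). Interaction lists are re-resolved
#' after every accepted polymer move and every occupancy change: existing
#' pairs persist while both partners stay Pol II-bound and lattice-adjacent,
#' and freed slots are refilled in random order up to the valency cap.
#' Pol II-Pol II interactions never impede elongation (TASEP moves are
#' energy-independent).
#'
#' Positions are stored unwrapped (periodic wrapping is applied only for
#' collision and contact detection), so gyration radii and MSDs need no
#' unwrapping step.
#'
#' @param pp a [polymer_params()].
#' @param mcs total MCS to simulate.
#' @param burn_in MCS discarded before snapshots begin.
#' @param snapshot_every snapshot cadence in MCS.
#' @param seed integer seed (kernel RNG and occupancy-draw RNG).
#' @param record `c(first, last)` 1-based chain span to record in snapshots;
#'   default: union of gene spans padded by one gene length each side.
#' @param init_occupancy "stationary" (Bernoulli at the phase-rule bulk
#'   density), "empty", or a list of explicit 0/1 vectors per gene.
#' @param check_invariants run the full invariant sweep (connectivity,
#'   excluded volume, list symmetry/valency) at every snapshot.
#' @param audit recompute the total Hamiltonian from scratch around every
#'   accepted move and track the worst disagreement with the incremental
#'   energy (slow; for verification runs).
#' @return object of class `polymer_traj`.
#' @export
polymer_run <- function(pp, mcs, burn_in = 0, snapshot_every = 1000,
                        seed = 1, record = NULL,
                        init_occupancy = "stationary",
                        check_invariants = TRUE, audit = FALSE) {
  genes <- pp$genes
  starts <- vapply(genes, function(g) g$start, numeric(1))
  lens <- vapply(genes, function(g) g$tasep$n, numeric(1))
  if (is.null(record)) {
    lo <- max(1, min(starts) - max(lens))
    hi <- min(pp$n_monomers, max(starts + lens - 1) + max(lens))
    record <- c(lo, hi)
  }
  probs <- lapply(genes, function(g) tasep_probs(g$tasep))
  set.seed(seed)
  init_occ <- lapply(seq_along(genes), function(k) {
    if (is.list(init_occupancy)) return(as.integer(init_occupancy[[k]]))
    if (identical(init_occupancy, "empty")) return(integer(lens[k]))
    rbinom(lens[k], 1, tasep_bulk_density(genes[[k]]$tasep))
  })
  out <- polymer_run_cpp(pp$n_monomers, pp$box[1], pp$box[2], pp$box[3],
                         pp$kappa, pp$E, pp$valency,
                         as.integer(starts - 1), as.integer(lens),
                         probs, init_occ,
                         mcs, burn_in, snapshot_every,
                         as.integer(record[1] - 1),
                         as.integer(record[2] - record[1] + 1),
                         check_invariants, audit, seed)
  out$params <- pp
  out$record <- as.integer(record)
  out$snapshot_every <- snapshot_every
  class(out) <- "polymer_traj"
  out
}

#' @export
print.polymer_traj <- function(x, ...) {
  cat(sprintf(
    "<polymer_traj> N = %d in %s box, %d snapshots, acceptance %.2f\n",
    x$params$n_monomers, paste(x$params$box, collapse = "x"),
    nrow(x$pos), x$acceptance))
  invisible(x)
}

#' Verify structural invariants of a trajectory's final state
#'
#' R-side sweep independent of the kernel's internal checks: chain
#' connectivity (consecutive monomers on nearest-neighbor FCC sites), parity
#' of all sites, excluded volume (distinct wrapped sites), interaction-list
#' symmetry, valency cap, and that every listed pair is Pol II-bound and
#' lattice-adjacent.
#'
#' @param traj a [polymer_run()] result.
#' @return TRUE invisibly; errors on violation.
#' @export
polymer_verify_state <- function(traj) {
  p <- traj$final_pos
  s <- traj$final_s
  box <- traj$params$box
  n <- nrow(p)
  if (any((rowSums(p)) %% 2 != 0)) stop("off-lattice site (odd parity)")
  b <- diff(p)
  ok <- rowSums(abs(b)) == 2 & apply(abs(b) <= 1, 1, all)
  if (!all(ok)) stop("broken bond at monomer ", which(!ok)[1])
  wrapped <- sweep(p, 2, box, function(a, L) ((a %% L) + L) %% L)
  key <- wrapped[, 1] * box[2] * box[3] + wrapped[, 2] * box[3] + wrapped[, 3]
  if (anyDuplicated(key)) stop("excluded-volume violation")
  lists <- traj$final_lists
  val <- traj$params$valency
  for (i in seq_len(n)) {
    li <- lists[[i]]
    if (length(li) > val) stop("valency cap exceeded at monomer ", i)
    if (length(li) && s[i] == 0) stop("unbound monomer ", i, " has partners")
    for (j in li) {
      if (!(i %in% lists[[j]])) stop("asymmetric pair ", i, "-", j)
      if (s[j] == 0) stop("pair with unbound partner ", i, "-", j)
      d <- (p[i, ] - p[j, ]) %% box
      d <- ifelse(d > box / 2, d - box, d)
      if (!(sum(abs(d)) == 2 && all(abs(d) <= 1)))
        stop("non-adjacent pair ", i, "-", j)
    }
  }
  invisible(TRUE)
}
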