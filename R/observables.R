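#' Simulated contact map from a trajectory
#'
#' Two monomers are in contact when they occupy nearest-neighbor FCC sites
#' (the same proximity criterion as the interaction term). Counts are
#' averaged over snapshots; the resulting matrix is symmetric, non-negative,
#' and carries the monomer coarse-graining as its resolution.
#'
#' @param traj a [polymer_run()] trajectory (or list of replicate
#'   trajectories with identical recording, averaged together).
#' @return a [contact_matrix()] over the recorded span.
#' @export
sim_contact_map <- function(traj) {
  trajs <- if (inherits(traj, "polymer_traj")) list(traj) else traj
  pp <- trajs[[1]]$params
  R <- trajs[[1]]$record[2] - trajs[[1]]$record[1] + 1
  acc <- matrix(0, R, R)
  nt <- 0
  for (tr in trajs) {
    acc <- acc + contacts_from_snapshots_cpp(
      tr$pos, R, pp$box[1], pp$box[2], pp$box[3]) * nrow(tr$pos)
    nt <- nt + nrow(tr$pos)
  }
  contact_matrix(acc / nt, pp$monomer_bp,
                 chrom = sprintf("sim:%d-%d", trajs[[1]]$record[1],
                                 trajs[[1]]$record[2]))
}

#' IC score of a simulated gene
#'
#' Obs/exp normalization of the simulated contact map restricted to the
#' recorded region, then the mean obs/exp over all monomer pairs inside the
#' gene span (the same IC definition as for experimental maps).
#'
#' By default the distance-decay expectation is computed from background
#' (non-gene) bins only. On a genome-sized map the expectation is dominated
#' by background anyway, but on a desk-scale simulated region a condensed
#' gene contributes a sizable share of the pairs at short separations and
#' would deflate its own enrichment; masking the gene bins when estimating
#' the expectation removes that self-contamination.
#'
#' @param traj trajectory or list of replicates.
#' @param gene index of the gene in `params$genes`.
#' @param cm optional precomputed [sim_contact_map()].
#' @param expected "background" (default) estimates the distance decay from
#'   non-gene bins; "all" uses every recorded bin.
#' @return IC score.
#' @export
sim_ic <- function(traj, gene = 1, cm = NULL,
                   expected = c("background", "all")) {
  expected <- match.arg(expected)
  tr1 <- if (inherits(traj, "polymer_traj")) traj else traj[[1]]
  if (is.null(cm)) cm <- sim_contact_map(traj)
  span <- gene_span(tr1$params, gene) - tr1$record[1] + 1
  if (expected == "background") {
    cmb <- cm
    allgenes <- unlist(lapply(seq_along(tr1$params$genes), function(g)
      gene_span(tr1$params, g) - tr1$record[1] + 1))
    cmb$mask <- as.integer(allgenes[allgenes >= 1 & allgenes <= n_bins(cm)])
    e <- compute_expected(cmb)
    n <- n_bins(cm)
    oe_vals <- cm$values / matrix(e[abs(row(cm$values) - col(cm$values)) + 1], n, n)
  } else {
    oe_vals <- compute_obs_exp(cm)$values
  }
  block <- oe_vals[span, span]
  mean(block[upper.tri(block)], na.rm = TRUE)
}

#' Radius of gyration time series
#'
#' `RG = sqrt(mean |r_i - r_mean|^2)` over the monomers of a span, per
#' snapshot, in nm (the lattice coordinate unit is `monomer_nm/sqrt(2)`,
#' the FCC bond length being `monomer_nm`).
#'
#' @param traj a [polymer_run()] trajectory.
#' @param span 1-based chain indices (default: gene 1).
#' @return numeric vector, one RG (nm) per snapshot.
#' @export
radius_of_gyration <- function(traj, span = NULL) {
  pp <- traj$params
  if (is.null(span)) span <- gene_span(pp, 1)
  ridx <- span - traj$record[1] + 1
  stopifnot(all(ridx >= 1), all(ridx <= traj$record[2] - traj$record[1] + 1))
  unit <- pp$monomer_nm / sqrt(2)
  cols <- as.vector(rbind(3 * (ridx - 1) + 1, 3 * (ridx - 1) + 2,
                          3 * (ridx - 1) + 3))
  P <- traj$pos[, cols, drop = FALSE] * unit
  ns <- nrow(P)
  m <- length(ridx)
  rg <- numeric(ns)
  xi <- seq(1, 3 * m, by = 3)
  for (t in seq_len(ns)) {
    xyz <- matrix(P[t, ], ncol = 3, byrow = TRUE)
    ctr <- colMeans(xyz)
    rg[t] <- sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
  }
  rg
}

#' Time- and ensemble-averaged mean-squared displacement
#'
#' MSD over logarithmically spaced snapshot lags, averaged over all time
#' origins, the selected monomers, and (when a list is given) replicate
#' trajectories. Interior gene monomers are the default analysis set to
#' avoid end effects.
#'
#' @param traj trajectory or list of replicates.
#' @param monomers 1-based chain indices; default: interior half of gene 1
#'   (central 50% of the gene span).
#' @param n_lags number of log-spaced lags (default 20).
#' @param max_lag_frac largest lag as a fraction of the trajectory length.
#' @return data.frame: lag_snapshots, lag_mcs, msd_um2 (ensemble MSD in
#'   square microns).
#' @export
msd <- function(traj, monomers = NULL, n_lags = 20, max_lag_frac = 0.5) {
  trajs <- if (inherits(traj, "polymer_traj")) list(traj) else traj
  pp <- trajs[[1]]$params
  if (is.null(monomers)) {
    sp <- gene_span(pp, 1)
    q <- floor(length(sp) / 4)
    monomers <- sp[(q + 1):(length(sp) - q)]
  }
  ridx <- monomers - trajs[[1]]$record[1] + 1
  ns <- min(vapply(trajs, function(t) nrow(t$pos), numeric(1)))
  lags <- unique(round(exp(seq(log(1), log(max(2, ns * max_lag_frac)),
                               length.out = n_lags))))
  unit_um <- pp$monomer_nm / sqrt(2) / 1000
  acc <- numeric(length(lags))
  cnt <- numeric(length(lags))
  for (tr in trajs) {
    for (li in seq_along(lags)) {
      L <- lags[li]
      if (L >= nrow(tr$pos)) next
      for (m in ridx) {
        cols <- 3 * (m - 1) + (1:3)
        d <- (tr$pos[-(1:L), cols, drop = FALSE] -
              tr$pos[1:(nrow(tr$pos) - L), cols, drop = FALSE]) * unit_um
        acc[li] <- acc[li] + sum(d^2)
        cnt[li] <- cnt[li] + nrow(d)
      }
    }
  }
  keep <- cnt > 0
  data.frame(lag_snapshots = lags[keep],
             lag_mcs = lags[keep] * trajs[[1]]$snapshot_every,
             msd_um2 = (acc / cnt)[keep])
}

#' Power-law fit of an MSD curve
#'
#' Linear least squares in log-log space: `MSD = D * lag^delta`, with the
#' lag expressed in MCS. The fit window defaults to lags between 10 and 1000
#' snapshots.
#'
#' @param msd_df data.frame from [msd()].
#' @param window `c(min, max)` lag window in snapshots.
#' @return object of class `msd_fit`: `D` (um^2 / MCS^delta), `delta`,
#'   `residual` (RMS of log residuals), `window`, `n_points`.
#' @export
fit_powerlaw <- function(msd_df, window = c(10, 1000)) {
  sel <- msd_df$lag_snapshots >= window[1] &
    msd_df$lag_snapshots <= window[2] & msd_df$msd_um2 > 0
  if (sum(sel) < 3) stop("fewer than 3 positive MSD points in fit window")
  fit <- lm(log(msd_um2) ~ log(lag_mcs), data = msd_df[sel, ])
  structure(list(D = exp(coef(fit)[[1]]), delta = coef(fit)[[2]],
                 residual = sqrt(mean(fit$residuals^2)),
                 window = window, n_points = sum(sel)),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("<msd_fit> MSD = %.3g * t^%.3f (t in MCS), rms resid %.3g\n",
              x$D, x$delta, x$residual))
  invisible(x)
}

#' Calibrate the MCS duration against live-imaging MSD
#'
#' Matches the simulated subdiffusive MSD prefactor to a reference
#' experimental law `MSD = ref_D * t^0.5` (micron^2, seconds; default the
#' typical yeast value 0.01). With the simulated `MSD = D * n^delta` (n in
#' MCS) and `t = n * tau`, the calibration solves
#' `D * (t/tau)^delta = ref_D * t^0.5`, which requires `delta ~ 0.5`:
#' `tau = (D / ref_D)^(1/delta)`. Refused when the fitted exponent is too
#' far from 1/2 for the time mapping to be meaningful.
#'
#' @param fit an [fit_powerlaw()] result (D in um^2/MCS^delta).
#' @param ref_D reference prefactor in um^2/s^0.5.
#' @param delta_tol admissible |delta - 0.5|.
#' @return seconds per MCS.
#' @export
calibrate_time <- function(fit, ref_D = 0.01, delta_tol = 0.1) {
  if (abs(fit$delta - 0.5) > delta_tol)
    stop(sprintf(
      "calibration requires a ~t^0.5 regime; fitted delta = %.3f", fit$delta))
  (fit$D / ref_D)^(1 / fit$delta)
}

#' Burst-conditioned structural statistics
#'
#' Splits the gyration-radius series by the instantaneous promoter state,
#' rank-correlates the instantaneous gene Pol II density with RG, and
#' tabulates the number of concurrently elongating trains.
#'
#' @param traj a [polymer_run()] trajectory with bursting enabled.
#' @param gene gene index.
#' @return list: `rg_on`, `rg_off` (nm samples), `median_on`, `median_off`,
#'   `density_rg_cor` (Spearman), `train_table`.
#' @export
burst_conditioned_stats <- function(traj, gene = 1) {
  rg <- radius_of_gyration(traj, gene_span(traj$params, gene))
  on <- traj$promoter[, gene] == 1
  dens <- traj$gene_density[, gene]
  rho_cor <- if (sd(dens) == 0 || sd(rg) == 0) NA_real_ else
    cor(rank(dens), rank(rg))
  list(rg_on = rg[on], rg_off = rg[!on],
       median_on = median(rg[on]), median_off = median(rg[!on]),
       density_rg_cor = rho_cor,
       train_table = table(traj$trains[, gene]))
}

#' Inter-gene contact analysis of a two-gene trajectory
#'
#' Obs/exp over the recorded region, then the mean enrichment of the
#' body-body block between the two genes, the flank-flank background at the
#' same genomic separation, and the four TSS/TTS cross-contact pixels
#' (3x3-neighborhood means).
#'
#' @param traj trajectory (or replicate list) with two gene spans.
#' @return list: `body_body`, `flank_flank`, `colocalization`
#'   (body/flank ratio), `tss_tss`, `tss_tts`, `tts_tss`, `tts_tts`.
#' @export
inter_gene_analysis <- function(traj) {
  tr1 <- if (inherits(traj, "polymer_traj")) traj else traj[[1]]
  pp <- tr1$params
  stopifnot(length(pp$genes) >= 2)
  oe <- compute_obs_exp(sim_contact_map(traj))
  s1 <- gene_span(pp, 1) - tr1$record[1] + 1
  s2 <- gene_span(pp, 2) - tr1$record[1] + 1
  body <- mean(oe$values[s1, s2], na.rm = TRUE)
  # flank background: windows of the same lengths just outside the two genes,
  # at the same center separation
  l1 <- length(s1)
  l2 <- length(s2)
  f1 <- s1 - l1
  f2 <- s2 + l2
  R <- nrow(oe$values)
  flank <- if (min(f1) >= 1 && max(f2) <= R)
    mean(oe$values[f1, f2], na.rm = TRUE) else NA_real_
  px <- function(i, j) {
    ii <- intersect(i + (-1:1), seq_len(R))
    jj <- intersect(j + (-1:1), seq_len(R))
    mean(oe$values[ii, jj], na.rm = TRUE)
  }
  tss1 <- s1[1]; tts1 <- s1[l1]
  tss2 <- s2[1]; tts2 <- s2[l2]
  list(body_body = body, flank_flank = flank,
       colocalization = body / flank,
       tss_tss = px(tss1, tss2), tss_tts = px(tss1, tts2),
       tts_tss = px(tts1, tss2), tts_tts = px(tts1, tts2))
}
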