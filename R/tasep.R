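#' TASEP parameters for Pol II transcription dynamics
#'
#' A gene of `n` monomers with Pol II loading at the TSS at rate `alpha`,
#' initiation (first hop) at `gamma0`, elongation at `gamma`, unloading at
#' the TTS at `beta`, and an optional two-state bursting promoter switching
#' on/off at `k_on`/`k_off`. Rates are per minute; one Monte Carlo step lasts
#' `dt` minutes (default 5e-5 min = 3 ms, the MSD-calibrated step duration).
#' Per-attempt probabilities `rate * dt` are capped at 0.1 to bound
#' discretization bias.
#'
#' With the monomer size of 2 kb used throughout, `gamma = 1`/min corresponds
#' to an elongation speed of 2 kb/min.
#'
#' @param n gene length in monomers (>= 2).
#' @param alpha,beta,gamma rates in 1/min.
#' @param gamma0 initiation (first-hop) rate, default `gamma`.
#' @param k_on,k_off promoter switching rates (1/min); `NULL` disables
#'   bursting.
#' @param dt MCS duration in minutes.
#' @return object of class `tasep_params`.
#' @export
tasep_params <- function(n, alpha, beta, gamma, gamma0 = gamma,
                         k_on = NULL, k_off = NULL, dt = 5e-5) {
  stopifnot(n >= 2, alpha >= 0, beta >= 0, gamma >= 0, gamma0 >= 0)
  burst <- !is.null(k_on) || !is.null(k_off)
  if (burst && (is.null(k_on) || is.null(k_off)))
    stop("supply both k_on and k_off, or neither")
  if (!burst) { k_on <- 0; k_off <- 0 }
  rates <- c(alpha = alpha, beta = beta, gamma = gamma, gamma0 = gamma0,
             k_on = k_on, k_off = k_off)
  if (any(rates * dt > 0.1))
    stop("rate * dt exceeds 0.1 for: ",
         paste(names(rates)[rates * dt > 0.1], collapse = ", "),
         "; reduce dt")
  structure(list(n = as.integer(n), alpha = alpha, beta = beta,
                 gamma = gamma, gamma0 = gamma0, k_on = k_on, k_off = k_off,
                 burst = burst, dt = dt), class = "tasep_params")
}

tasep_probs <- function(p) {
  list(pa = p$alpha * p$dt, pb = p$beta * p$dt, pg = p$gamma * p$dt,
       pg0 = p$gamma0 * p$dt, pon = p$k_on * p$dt, poff = p$k_off * p$dt,
       burst = p$burst, start_on = TRUE)
}

#' Approximate stationary bulk density of the open TASEP
#'
#' Phase rule of the open boundary TASEP: low density `alpha/gamma` when
#' loading limits, high density `1 - beta/gamma` when unloading limits,
#' maximal current 1/2 otherwise. Used to draw initial occupancies close to
#' stationarity.
#' @param p a [tasep_params()].
#' @return density in (0, 1).
#' @export
tasep_bulk_density <- function(p) {
  if (p$alpha <= 0) return(0)
  if (p$gamma <= 0) return(p$alpha / (p$alpha + p$beta))
  a <- p$alpha / p$gamma
  b <- p$beta / p$gamma
  if (p$burst) a <- a * p$k_on / (p$k_on + p$k_off) # effective loading
  if (a < b && a < 0.5) a
  else if (b < a && b < 0.5) 1 - b
  else 0.5
}

#' Run the TASEP kernel
#'
#' Simulates `steps` MCS of the kinetic Monte Carlo TASEP (one binding
#' attempt, one unbinding attempt, n-1 random elongation attempts per MCS,
#' then one promoter-switch attempt when bursting is enabled). The first
#' `burn_in` MCS are discarded from all averages; occupancy snapshots are
#' kept every `thin` MCS thereafter.
#'
#' @param params a [tasep_params()].
#' @param steps,burn_in total and discarded MCS.
#' @param thin snapshot interval in MCS.
#' @param seed integer seed for the kernel's RNG.
#' @param init "empty", "stationary" (Bernoulli draw at the phase-rule bulk
#'   density), or an explicit 0/1 vector of length `n`.
#' @return object of class `tasep_run`: per-site mean `density` with
#'   batch-mean `density_se`, thinned `occupancy` snapshots, promoter state
#'   and elongating-train count per snapshot, unloading/transit event times
#'   (in MCS), and bookkeeping fields.
#' @export
tasep_run <- function(params, steps, burn_in = 0, thin = 100, seed = 1,
                      init = "stationary") {
  pr <- tasep_probs(params)
  if (is.character(init)) {
    init <- match.arg(init, c("stationary", "empty"))
    init_occ <- if (init == "empty") integer(params$n) else {
      set.seed(seed)
      rbinom(params$n, 1, tasep_bulk_density(params))
    }
  } else {
    stopifnot(length(init) == params$n)
    init_occ <- as.integer(init)
  }
  out <- tasep_run_cpp(params$n, pr$pa, pr$pb, pr$pg, pr$pg0,
                       pr$pon, pr$poff, pr$burst, pr$start_on,
                       steps, burn_in, thin, init_occ, seed)
  out$params <- params
  class(out) <- "tasep_run"
  out
}

#' @export
print.tasep_run <- function(x, ...) {
  cat(sprintf("<tasep_run> n = %d, %g MCS sampled, mean density %.3f\n",
              x$params$n, x$sampled_mcs, mean(x$density)))
  invisible(x)
}

#' Time-averaged Pol II density profile
#' @param run a [tasep_run()] (or coupled polymer run's gene component).
#' @return data.frame: site (1-based), x = site/n, density, se.
#' @export
mean_density <- function(run) {
  n <- run$params$n
  if (max(run$density_se) > 0.05)
    warning("density standard errors exceed 0.05; trajectory may be too short")
  data.frame(site = seq_len(n), x = seq_len(n) / n,
             density = run$density, se = run$density_se)
}

#' Derived bursting quantities
#'
#' Closed forms for the two-state bursting promoter: effective binding rate
#' `alpha_eff = alpha * k_on / (k_on + k_off)`, burst frequency
#' `k_on * k_off / (k_on + k_off)` (bursts per minute), and train size
#' `alpha / k_off` (mean Pol II loaded per burst).
#'
#' @param params a [tasep_params()] with bursting enabled.
#' @return list: alpha_eff, burst_frequency, train_size.
#' @export
burst_derived <- function(params) {
  if (!params$burst) {
    return(list(alpha_eff = params$alpha, burst_frequency = 0,
                train_size = Inf))
  }
  kon <- params$k_on
  koff <- params$k_off
  ts <- if (koff == 0) {
    warning("k_off = 0: train size diverges")
    Inf
  } else params$alpha / koff
  list(alpha_eff = params$alpha * kon / (kon + koff),
       burst_frequency = kon * koff / (kon + koff),
       train_size = ts)
}

#' Transcription observables from a TASEP trajectory
#'
#' Unloading (transcription) rate, mean Pol II transit time and the effective
#' elongation rate relative to the unobstructed expectation
#' `1/gamma0 + (n-2)/gamma + 1/beta`, plus the elongating-train count series.
#'
#' @param run a [tasep_run()].
#' @return list: transcription_rate (events/min), mean_transit_min,
#'   eff_elongation (dimensionless, ~1 at low density), trains (per
#'   snapshot), n_unloads.
#' @export
transcription_observables <- function(run) {
  p <- run$params
  rate_per_mcs <- run$n_unloads / run$sampled_mcs
  t_free <- 1 / p$gamma0 + (p$n - 2) / p$gamma + 1 / p$beta
  mt <- if (length(run$transit_times)) mean(run$transit_times) * p$dt else NA_real_
  eff <- if (is.na(mt)) {
    warning("no completed transits; effective elongation rate undefined")
    NA_real_
  } else t_free / mt
  list(transcription_rate = rate_per_mcs / p$dt,
       mean_transit_min = mt,
       eff_elongation = eff,
       trains = run$trains,
       n_unloads = run$n_unloads)
}

#' Exact stationary distribution of the small-n TASEP kernel
#'
#' Enumerates all `2^n` occupancy states and builds the exact one-MCS
#' transition matrix of the kernel's attempt schedule (binding, unbinding,
#' then n-1 uniform-random elongation attempts), then extracts the stationary
#' distribution from its eigenvector at eigenvalue 1. Practical for n <= 10.
#' Bursting is not included.
#'
#' @param params a [tasep_params()] without bursting.
#' @return list: `pi` (stationary probabilities over states), `states`
#'   (2^n x n occupancy matrix), `density` (stationary per-site mean).
#' @export
tasep_exact_stationary <- function(params) {
  stopifnot(!params$burst, params$n <= 12)
  n <- params$n
  pr <- tasep_probs(params)
  ns <- 2^n
  states <- t(vapply(0:(ns - 1), function(s)
    as.integer(intToBits(s)[1:n]), integer(n)))
  idx <- function(s) sum(s * 2^(0:(n - 1))) + 1
  # binding attempt at site 1
  Pb <- diag(ns)
  for (k in 1:ns) if (states[k, 1] == 0) {
    s2 <- states[k, ]; s2[1] <- 1
    Pb[k, k] <- 1 - pr$pa
    Pb[k, idx(s2)] <- pr$pa
  }
  # unbinding attempt at site n
  Pu <- diag(ns)
  for (k in 1:ns) if (states[k, n] == 1) {
    s2 <- states[k, ]; s2[n] <- 0
    Pu[k, k] <- 1 - pr$pb
    Pu[k, idx(s2)] <- pr$pb
  }
  # one elongation attempt: site i uniform in 1..n-1
  Pe <- matrix(0, ns, ns)
  for (k in 1:ns) {
    for (i in 1:(n - 1)) {
      p <- if (i == 1) pr$pg0 else pr$pg
      if (states[k, i] == 1 && states[k, i + 1] == 0) {
        s2 <- states[k, ]; s2[i] <- 0; s2[i + 1] <- 1
        Pe[k, idx(s2)] <- Pe[k, idx(s2)] + p / (n - 1)
        Pe[k, k] <- Pe[k, k] + (1 - p) / (n - 1)
      } else {
        Pe[k, k] <- Pe[k, k] + 1 / (n - 1)
      }
    }
  }
  Pel <- diag(ns)
  for (r in seq_len(n - 1)) Pel <- Pel %*% Pe
  P <- Pb %*% Pu %*% Pel
  ev <- eigen(t(P))
  v <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi <- v / sum(v)
  list(pi = pi, states = states, density = as.numeric(t(states) %*% pi))
}
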