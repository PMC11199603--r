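#' Mean-field steady-state Pol II density profile
#'
#' Solves the continuum mean-field steady state of the TASEP,
#' \deqn{(2n)^{-1} \rho''(x) + (2\rho(x) - 1)\rho'(x) = 0,}
#' on x in \[0, 1\] with Dirichlet boundaries `rho0 = rho(0)`,
#' `rho1 = rho(1)`, by damped Newton iteration on a central finite-difference
#' grid. Equal boundary values return the constant solution exactly. The
#' sup-norm residual of the discrete equations is reported and must pass
#' `tol`.
#'
#' For rates (alpha, beta, gamma) the natural boundary values are
#' `rho(0) = alpha/gamma` and `rho(1) = 1 - beta/gamma`; in the uniform
#' regime `beta/gamma = 1 - alpha/gamma` these coincide and the profile is
#' flat at `alpha/gamma`.
#'
#' @param n gene length in monomers (sets the diffusion term `1/(2n)`).
#' @param rho0,rho1 boundary densities in \[0, 1\].
#' @param grid number of grid intervals (default 400).
#' @param tol residual tolerance (sup-norm, default 1e-10).
#' @param max_iter Newton iteration cap.
#' @return list: `x`, `rho`, `residual`, `iterations`.
#' @export
solve_meanfield <- function(n, rho0, rho1, grid = 400, tol = 1e-10,
                            max_iter = 100) {
  stopifnot(rho0 >= 0, rho0 <= 1, rho1 >= 0, rho1 <= 1, n >= 2)
  x <- seq(0, 1, length.out = grid + 1)
  if (rho0 == rho1) {
    return(list(x = x, rho = rep(rho0, grid + 1), residual = 0,
                iterations = 0L))
  }
  h <- 1 / grid
  rho <- rho0 + (rho1 - rho0) * x # linear initial guess
  interior <- 2:grid
  resid_fun <- function(r) {
    (r[interior + 1] - 2 * r[interior] + r[interior - 1]) / (2 * n * h^2) +
      (2 * r[interior] - 1) * (r[interior + 1] - r[interior - 1]) / (2 * h)
  }
  it <- 0L
  repeat {
    it <- it + 1L
    Fv <- resid_fun(rho)
    if (max(abs(Fv)) < tol || it > max_iter) break
    m <- grid - 1
    J <- matrix(0, m, m)
    for (k in seq_len(m)) {
      i <- k + 1
      dp <- (rho[i + 1] - rho[i - 1]) / (2 * h)
      # d/drho_i
      J[k, k] <- -2 / (2 * n * h^2) + 2 * dp
      if (k > 1) J[k, k - 1] <- 1 / (2 * n * h^2) - (2 * rho[i] - 1) / (2 * h)
      if (k < m) J[k, k + 1] <- 1 / (2 * n * h^2) + (2 * rho[i] - 1) / (2 * h)
    }
    step <- tryCatch(solve(J, -Fv), error = function(e)
      stop("mean-field solver: singular Jacobian (residual ",
           format(max(abs(Fv))), ")"))
    lambda <- 1
    repeat { # damping: keep rho in [0,1] and reduce the residual
      cand <- rho
      cand[interior] <- rho[interior] + lambda * step
      cand <- pmin(pmax(cand, 0), 1)
      if (max(abs(resid_fun(cand))) < max(abs(Fv)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    rho <- cand
  }
  res <- max(abs(resid_fun(rho)))
  if (res > tol)
    stop(sprintf("mean-field solver did not converge: residual %.3e", res))
  list(x = x, rho = rho, residual = res, iterations = it)
}
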