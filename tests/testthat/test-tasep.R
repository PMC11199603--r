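test_that("parameter validation enforces the probability cap", {
  expect_error(tasep_params(50, alpha = 3000, beta = 1, gamma = 1),
               "rate \\* dt")
  expect_error(tasep_params(1, alpha = 1, beta = 1, gamma = 1))
  expect_error(tasep_params(10, alpha = 1, beta = 1, gamma = 1, k_on = 0.1),
               "both k_on and k_off")
})

test_that("degenerate rate limits behave as required", {
  # no loading: the gene stays empty forever
  p <- tasep_params(10, alpha = 0, beta = 1, gamma = 1, dt = 0.05)
  r <- tasep_run(p, steps = 5000, burn_in = 0, thin = 10, seed = 1,
                 init = "empty")
  expect_true(all(r$occupancy == 0))
  expect_true(all(r$density == 0))
  # frozen elongation: a mid-gene Pol II never moves
  p2 <- tasep_params(10, alpha = 0, beta = 0, gamma = 0, dt = 0.05)
  s0 <- integer(10)
  s0[5] <- 1L
  r2 <- tasep_run(p2, steps = 2000, burn_in = 0, thin = 10, seed = 2,
                  init = s0)
  expect_true(all(r2$occupancy[, 5] == 1))
  expect_true(all(r2$occupancy[, -5] == 0))
})

test_that("small-n occupancy matches the exact one-MCS chain", {
  p <- tasep_params(3, alpha = 900, beta = 1400, gamma = 2000,
                    gamma0 = 1600, dt = 5e-5)
  ex <- tasep_exact_stationary(p)
  expect_equal(sum(ex$pi), 1)
  expect_true(all(ex$pi > 0))
  r <- tasep_run(p, steps = 1.5e6, burn_in = 2e5, thin = 10, seed = 3)
  emp_state <- colMeans(
    outer(r$occupancy %*% 2^(0:2), 0:7, "==")[, 1, ])
  expect_lt(max(abs(emp_state - ex$pi)), 0.01)
  expect_lt(max(abs(r$density - ex$density)), 0.01)
})

test_that("uniform-profile parameters give a flat profile at alpha/gamma", {
  g <- 2000
  p <- tasep_params(20, alpha = 0.3 * g, beta = 0.7 * g, gamma = g)
  r <- tasep_run(p, steps = 3e5, burn_in = 1e5, thin = 1000, seed = 4)
  md <- mean_density(r)
  bulk <- md$density[5:16]
  expect_true(all(abs(bulk - 0.3) < 3 * pmax(md$se[5:16], 1e-3) + 0.01))
})

test_that("the symmetric bursting promoter is on half the time", {
  p <- tasep_params(5, alpha = 100, beta = 100, gamma = 200,
                    k_on = 400, k_off = 400, dt = 2e-4)
  r <- tasep_run(p, steps = 2e5, burn_in = 1e4, thin = 1, seed = 5)
  expect_equal(mean(r$promoter), 0.5, tolerance = 0.03)
  # empirical switching rates recover k
  pm <- r$promoter
  k_off_hat <- mean(pm[-length(pm)] == 1 & pm[-1] == 0) /
    mean(pm[-length(pm)] == 1) / p$dt
  k_on_hat <- mean(pm[-length(pm)] == 0 & pm[-1] == 1) /
    mean(pm[-length(pm)] == 0) / p$dt
  expect_equal(k_off_hat, 400, tolerance = 0.1)
  expect_equal(k_on_hat, 400, tolerance = 0.1)
  # k_off = 0: never switches off
  p2 <- tasep_params(5, alpha = 100, beta = 100, gamma = 200,
                     k_on = 100, k_off = 0, dt = 2e-4)
  r2 <- tasep_run(p2, steps = 1e4, burn_in = 0, thin = 1, seed = 6)
  expect_true(all(r2$promoter == 1))
})

test_that("bursting closed forms follow the two-state algebra", {
  p <- tasep_params(10, alpha = 6, beta = 5, gamma = 10,
                    k_on = 0.02, k_off = 0.02)
  bd <- burst_derived(p)
  expect_equal(bd$alpha_eff, 3)
  expect_equal(bd$burst_frequency, 0.01)
  expect_equal(bd$train_size, 300)
  # alpha = 0: empty trains
  p0 <- tasep_params(10, alpha = 0, beta = 5, gamma = 10,
                     k_on = 0.02, k_off = 0.02)
  expect_equal(burst_derived(p0)$train_size, 0)
  # k_off -> 0 diverges with a warning
  pInf <- tasep_params(10, alpha = 6, beta = 5, gamma = 10,
                       k_on = 0.02, k_off = 0)
  expect_warning(bdInf <- burst_derived(pInf), "diverges")
  expect_equal(bdInf$train_size, Inf)
  # bursting disabled: alpha_eff = alpha
  pno <- tasep_params(10, alpha = 6, beta = 5, gamma = 10)
  expect_equal(burst_derived(pno)$alpha_eff, 6)
})

test_that("transit times and currents follow TASEP expectations", {
  g <- 1000
  # near-empty gene: transit ~ 1/gamma0 + (n-2)/gamma + 1/beta
  p <- tasep_params(10, alpha = 0.002 * g, beta = 0.5 * g, gamma = g,
                    gamma0 = 0.5 * g, dt = 1e-4)
  r <- tasep_run(p, steps = 2e6, burn_in = 1e4, thin = 1000, seed = 7,
                 init = "empty")
  obs <- transcription_observables(r)
  t_free <- 1 / p$gamma0 + (p$n - 2) / p$gamma + 1 / p$beta
  se <- sd(r$transit_times * p$dt) / sqrt(length(r$transit_times))
  expect_gt(length(r$transit_times), 50)
  expect_lt(abs(obs$mean_transit_min - t_free), 3 * se + 0.02 * t_free)
  expect_equal(obs$eff_elongation, 1, tolerance = 0.1)
  # low-density limit: unloading rate approaches the loading rate alpha
  expect_equal(obs$transcription_rate, p$alpha, tolerance = 0.15)
  # uniform regime: current = rho (1 - rho) gamma, maximal near rho = 0.5
  # (small rate*dt to keep discretization bias below the finite-n corrections)
  current <- vapply(c(0.2, 0.5, 0.8), function(a) {
    pu <- tasep_params(50, alpha = a * g, beta = (1 - a) * g, gamma = g,
                       dt = 2e-5)
    ru <- tasep_run(pu, steps = 6e5, burn_in = 1e5, thin = 1000,
                    seed = round(100 * a))
    transcription_observables(ru)$transcription_rate
  }, numeric(1))
  expect_gt(current[2], current[1])
  expect_gt(current[2], current[3])
  want <- c(0.2, 0.5, 0.8) * (1 - c(0.2, 0.5, 0.8)) * g
  expect_equal(current, want, tolerance = 0.12)
})

test_that("the mean-field solver honors its contracts", {
  # equal boundaries: exactly constant
  mf <- solve_meanfield(50, 0.3, 0.3)
  expect_identical(mf$rho, rep(0.3, length(mf$x)))
  expect_identical(mf$residual, 0)
  # generic boundaries: tight residual, monotone interpolation of BCs
  mf2 <- solve_meanfield(50, 0.2, 0.6, tol = 1e-9)
  expect_lt(mf2$residual, 1e-9)
  expect_equal(mf2$rho[1], 0.2)
  expect_equal(mf2$rho[length(mf2$rho)], 0.6)
  expect_true(all(mf2$rho >= 0 & mf2$rho <= 1))
})
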