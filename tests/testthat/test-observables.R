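test_that("volume fraction follows the bead-volume definition", {
  expect_equal(volume_fraction(rep(1000, 5), 72), 72 * pi / 6 / 1000,
               tolerance = 1e-12)
  expect_equal(volume_fraction(rep(1000, 5), 72), 0.0377, tolerance = 1e-3)
  # doubling the mean volume halves phi; linear in particle count
  expect_equal(volume_fraction(rep(2000, 5), 72),
               volume_fraction(rep(1000, 5), 72) / 2)
  expect_equal(volume_fraction(rep(1000, 5), 36) +
                 volume_fraction(rep(1000, 5), 36),
               volume_fraction(rep(1000, 5), 72))
  expect_error(volume_fraction(numeric(0), 10), "empty")
})

test_that("mean pressure block averaging handles simple streams", {
  expect_equal(mean_pressure(rep(0.3, 100))$mean, 0.3)
  expect_equal(mean_pressure(rep(0.3, 100))$stderr, 0)
  expect_equal(mean_pressure(rep(c(0.2, 0.4), 50))$mean, 0.3)
  expect_error(mean_pressure(rep(0.3, 5)), "too few")
})

test_that("bulk modulus reproduces analytic isotherms", {
  # ideal gas: V = N kT / P, beta_T = P exactly at the centered point
  N <- 1000
  P <- c(0.5, 1, 2)
  res <- bulk_modulus(P, N / P)
  expect_equal(res$beta_T[2], 1.0, tolerance = 1e-12)
  expect_false(any(res$flagged))

  # incompressible: kappa = 0, beta = Inf, flagged
  res2 <- bulk_modulus(c(1, 2, 3), rep(10, 3))
  expect_true(all(res2$flagged))
  expect_true(all(is.infinite(res2$beta_T)))

  # exponential EOS V = V0 exp(-cP): kappa_T = c for any V0
  cc <- 0.7
  P3 <- seq(0.5, 1.5, by = 0.05)
  for (V0 in c(1, 250)) {
    res3 <- bulk_modulus(P3, V0 * exp(-cc * P3))
    inner <- res3$kappa_T[2:(length(P3) - 1)]
    expect_equal(inner, rep(cc, length(inner)), tolerance = 1e-3)
  }
  expect_error(bulk_modulus(c(1, 2), c(2, 1)), "at least 3")
  expect_error(bulk_modulus(c(2, 1, 3), c(3, 2, 1)), "increasing")
})

test_that("fluctuation and isotherm modulus estimators agree on a WCA fluid", {
  p <- model_parameters()
  top <- wca_fluid(125, rho = 0.4, seed = 6)
  Ps <- c(0.3, 0.4, 0.5)
  runs <- lapply(seq_along(Ps), function(i)
    run_npt(top, p, target_pressure = Ps[i], n_equil_steps = 10000,
            n_prod_steps = 40000, sample_every = 20, seed = 20 + i))
  vols <- sapply(runs, function(r) mean(r$samples$V))
  fd <- bulk_modulus(Ps, vols)
  fl <- bulk_modulus_fluctuation(runs[[2]]$samples, kT = 1.0)
  expect_equal(fl$beta_T, fd$beta_T[2], tolerance = 0.35)
})

test_that("scaling-exponent fit recovers known limits", {
  N <- c(10, 20, 40, 80)
  expect_equal(fit_scaling_exponent(N, 0.3 * N)$nu, 1.0, tolerance = 1e-12)
  expect_equal(fit_scaling_exponent(N, 1.7 * sqrt(N))$nu, 0.5,
               tolerance = 1e-12)
  expect_error(fit_scaling_exponent(c(10, 20), c(1, 2)), "at least 3")
})

test_that("pressure of attractive dilute fluid sits below rho kT, repulsive dense above", {
  p_att <- model_parameters(lambda_mtx = 1)
  top <- wca_fluid(100, rho = 0.2, seed = 7)
  out <- run_md(top, p_att, "nvt", n_steps = 20000, sample_every = 50, seed = 3)
  rho <- 100 / top$box_length^3
  expect_lt(mean(out$samples$P_inst), rho * 1.0)

  p_rep <- model_parameters(lambda_mtx = 0)
  top2 <- wca_fluid(100, rho = 0.6, seed = 8)
  out2 <- run_md(top2, p_rep, "nvt", n_steps = 20000, sample_every = 50,
                 seed = 4)
  rho2 <- 100 / top2$box_length^3
  expect_gt(mean(out2$samples$P_inst), rho2 * 1.0)
})

test_that("Monte Carlo and Langevin chain sampling agree on chain size", {
  # same Hamiltonian, two independent samplers: pivot+bead Metropolis MC
  # versus the Langevin engine
  p <- model_parameters()
  mc <- mean(sample_chain_rg(20, 0.646, n_sweeps = 20000, burn_sweeps = 2000,
                             seed = 3))
  p$lambda_mtx <- 0.646
  top <- single_chain_topology(20)
  eq <- run_md(top, p, "langevin", n_steps = 60000, sample_every = 0,
               seed = 11)
  pr <- run_md(top, p, "langevin", n_steps = 400000, sample_every = 200,
               seed = 12, state = eq$state, record_rg = TRUE)
  md <- mean(pr$samples$Rg2)
  expect_lt(abs(mc - md) / md, 0.06)
})
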