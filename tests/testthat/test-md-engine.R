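test_that("cell-list forces equal the direct sum and the R oracle", {
  p <- model_parameters(lambda_mtx = 0.3, lambda_emb = 0.9, lambda_cr = 0.1)
  for (seed in 1:3) {
    top <- random_config(30, L = 5.0, min_dist = 0.85, seed = seed,
                         species = rep(c("matrix_segment", "embedded_segment"),
                                       15),
                         bonds = cbind(c(1L, 3L, 5L), c(2L, 4L, 6L)))
    cell <- compute_forces(top, p)
    direct <- compute_forces(top, p, direct = TRUE)
    expect_equal(cell$forces, direct$forces, tolerance = 1e-12)
    expect_equal(cell$virial, direct$virial, tolerance = 1e-12)
    oracle <- oracle_forces(top, p)
    expect_equal(cell$forces, oracle$forces, tolerance = 1e-9)
    expect_equal(cell$energy, oracle$energy, tolerance = 1e-10)
    expect_equal(cell$virial, oracle$virial, tolerance = 1e-9)
    expect_lt(max(abs(colSums(cell$forces))), 1e-9 * 30)
  }
})

test_that("two bonded particles at the rest length feel no force", {
  top <- make_fixture("two_particle")
  f <- compute_forces(top)
  expect_lt(max(abs(f$forces)), 1e-10)
  expect_lt(abs(f$energy), 1e-20)
})

test_that("the pairwise virial matches the analytic derivative", {
  # isolated non-bonded pair at r = 1.2, lambda = 1: w(r) = r dV/dr
  p <- model_parameters(lambda_mtx = 1)
  r <- 1.2
  top <- gelpress:::new_gel_topology(
    rbind(c(5, 5, 5), c(5 + r, 5, 5)), rep("matrix_segment", 2),
    matrix(0L, 0, 2), c(1L, 2L), 10)
  f <- compute_forces(top, p)
  dVdr <- -pair_force(r, 1, p)
  expect_equal(f$virial, -r * dVdr, tolerance = 1e-12)
  expect_equal(f$virial, r * pair_force(r, 1, p), tolerance = 1e-12)
})

test_that("energy is invariant under rigid translation modulo the box", {
  p <- model_parameters(lambda_mtx = 0.5)
  top <- random_config(25, L = 4.2, min_dist = 0.85, seed = 8)
  e0 <- compute_forces(top, p)$energy
  set.seed(3)
  for (i in 1:4) {
    shift <- runif(3, -7, 7)
    shifted <- sweep(top$coordinates, 2, shift, "+") %% top$box_length
    e1 <- compute_forces(top, p, coordinates = shifted)$energy
    expect_equal(e1, e0, tolerance = 1e-9)
  }
})

test_that("NVT thermostat holds the temperature of a WCA fluid", {
  p <- model_parameters()
  top <- wca_fluid(125, rho = 0.4, seed = 2)
  out <- run_md(top, p, "nvt", n_steps = 50000, sample_every = 50, seed = 3)
  Tbar <- mean(out$samples$T_inst)
  expect_lt(abs(Tbar - 1.0), 0.02)
})

test_that("NPT volume decreases monotonically with target pressure", {
  p <- model_parameters()
  top <- wca_fluid(100, rho = 0.3, seed = 4)
  vols <- sapply(c(0.05, 0.2, 1.0), function(P) {
    out <- run_npt(top, p, target_pressure = P, n_equil_steps = 8000,
                   n_prod_steps = 12000, sample_every = 30, seed = 11)
    mean(out$samples$V)
  })
  expect_true(all(diff(vols) < 0))
})

test_that("runs are deterministic for a fixed seed", {
  p <- model_parameters(lambda_mtx = 0.4)
  top <- wca_fluid(60, rho = 0.3, seed = 5)
  a <- run_md(top, p, "npt", n_steps = 2000, target_pressure = 0.1,
              sample_every = 100, seed = 42)
  b <- run_md(top, p, "npt", n_steps = 2000, target_pressure = 0.1,
              sample_every = 100, seed = 42)
  expect_identical(a$samples, b$samples)
  expect_identical(a$state$positions, b$state$positions)
  cl <- run_md(top, p, "langevin", n_steps = 2000, sample_every = 100,
               seed = 42)
  c2 <- run_md(top, p, "langevin", n_steps = 2000, sample_every = 100,
               seed = 42)
  expect_identical(cl$samples, c2$samples)
})

test_that("numerical blow-up raises an integration-failure error", {
  # absurd timestep on a stiff bond diverges to non-finite coordinates
  p <- model_parameters(dt = 50)
  top <- make_fixture("two_particle")
  top$coordinates[2, 1] <- top$coordinates[1, 1] + 1.4
  expect_error(run_md(top, p, "nve", n_steps = 5000, sample_every = 0),
               "integration failure")
})

test_that("deep pair overlap in force evaluation still returns finite forces", {
  p <- model_parameters()
  top <- gelpress:::new_gel_topology(
    rbind(c(5, 5, 5), c(5.3, 5, 5)), rep("matrix_segment", 2),
    matrix(0L, 0, 2), c(1L, 2L), 10)
  f <- compute_forces(top, p)
  expect_true(all(is.finite(f$forces)))
  expect_gt(f$forces[1, 1] * -1, 0)  # strongly repulsive
})
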