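test_that("smoothing coefficients satisfy both matching conditions", {
  ab <- smoothing_coefficients()
  r_min <- 2^(1 / 6); r_cut <- 3 / 2
  expect_equal(ab$alpha * r_min^2 + ab$beta, pi, tolerance = 1e-12)
  expect_equal(ab$alpha * r_cut^2 + ab$beta, 2 * pi, tolerance = 1e-12)
  # closed forms for the default radii
  expect_equal(ab$alpha, 4 * pi / (9 - 4 * 2^(1 / 3)), tolerance = 1e-14)
  expect_equal(ab$beta, 2 * pi - 9 / 4 * ab$alpha, tolerance = 1e-14)
  expect_equal(ab$alpha, 3.17307, tolerance = 1e-5)
  expect_equal(ab$beta, -0.85622, tolerance = 1e-4)

  ab2 <- smoothing_coefficients(1, sqrt(2))
  expect_equal(ab2$alpha, pi, tolerance = 1e-14)
  expect_equal(ab2$beta, 0, tolerance = 1e-13)

  # difference of the conditions for arbitrary valid radii
  set.seed(4)
  for (i in 1:10) {
    rm <- runif(1, 0.5, 2); rc <- rm + runif(1, 0.1, 2)
    ab3 <- smoothing_coefficients(rm, rc)
    expect_equal(ab3$alpha * (rc^2 - rm^2), pi, tolerance = 1e-12)
  }

  expect_error(smoothing_coefficients(1.5, 1.1), "invalid radii")
  expect_error(smoothing_coefficients(-1, 1), "invalid radii")
})

test_that("pair potential has the correct well, cutoff, and WCA limit", {
  p <- model_parameters()
  expect_equal(pair_potential(p$r_min, 1), -1, tolerance = 1e-14)
  expect_equal(pair_potential(p$r_min, 0), 0, tolerance = 1e-14)
  for (lam in c(0, 0.4, 1)) {
    expect_equal(pair_potential(p$r_cut, lam), 0, tolerance = 1e-15)
    expect_equal(pair_potential(seq(p$r_cut + 1e-9, 3, length.out = 7), lam),
                 rep(0, 7))
  }
  # well depth -lambda*eps attained at r_min
  r <- seq(0.9, 1.6, by = 1e-4)
  for (lam in c(0.25, 0.5, 1)) {
    v <- pair_potential(r, lam)
    expect_equal(min(v), -lam, tolerance = 1e-6)
    expect_equal(r[which.min(v)], p$r_min, tolerance = 2e-4)
  }
  # lambda = 0 recovers the shifted-truncated Lennard-Jones everywhere
  v0 <- pair_potential(r, 0)
  wca <- ifelse(r <= p$r_min, 4 * (r^-12 - r^-6) + 1, 0)
  expect_equal(v0, wca, tolerance = 1e-14)
  expect_error(pair_potential(0, 1), "positive")
  expect_error(pair_potential(-0.5, 1), "positive")
})

test_that("potential and force are continuous across r_min and r_cut", {
  p <- model_parameters()
  h <- 1e-9
  for (lam in c(0, 0.3, 1)) {
    for (rb in c(p$r_min, p$r_cut)) {
      expect_equal(pair_potential(rb - h, lam), pair_potential(rb + h, lam),
                   tolerance = 1e-7)
      expect_equal(pair_force(rb - h, lam), pair_force(rb + h, lam),
                   tolerance = 1e-7)
    }
  }
  expect_equal(pair_force(p$r_cut, 1), 0)
  expect_equal(pair_force(p$r_min, 1), 0, tolerance = 1e-12)
})

test_that("pair force equals minus the potential derivative", {
  # central differences away from the curvature kinks at r_min and r_cut
  p <- model_parameters()
  r <- seq(0.82, 1.58, by = 0.004)
  r <- r[abs(r - p$r_min) > 1e-3 & abs(r - p$r_cut) > 1e-3]
  h <- 1e-6
  for (lam in c(0, 0.7)) {
    fd <- -(pair_potential(r + h, lam) - pair_potential(r - h, lam)) / (2 * h)
    expect_equal(pair_force(r, lam), fd, tolerance = 1e-6)
  }
})

test_that("harmonic bond has the literal k (r - l0)^2 form", {
  p <- model_parameters()
  expect_equal(bond_potential(0.99), 0)
  expect_equal(bond_potential(1.09), 10.0, tolerance = 1e-12)
  expect_equal(bond_force(p$bond_l0), 0)
  # no 1/2 prefactor: curvature is 2k
  h <- 1e-5
  expect_equal((bond_potential(p$bond_l0 + h) + bond_potential(p$bond_l0 - h)) / h^2,
               2 * p$spring_k, tolerance = 1e-4)
})

test_that("parameter validation rejects unphysical values", {
  expect_error(model_parameters(lambda_emb = 1.2), "lambda")
  expect_error(model_parameters(lambda_mtx = -0.1), "lambda")
  expect_error(model_parameters(r_cut = 1.0), "r_cut")
  expect_error(model_parameters(dt = 0), "dt")
})

test_that("potential table export matches the closed forms", {
  f <- tempfile(fileext = ".csv")
  tab <- potential_table(0.5, file = f)
  expect_true(file.exists(f))
  back <- read.csv(f)
  expect_equal(names(back), c("r", "V", "F"))
  expect_equal(back$V, pair_potential(back$r, 0.5), tolerance = 1e-10)
  expect_equal(back$F, pair_force(back$r, 0.5), tolerance = 1e-10)
})
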