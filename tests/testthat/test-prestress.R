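# fabricate a swelling_curve without running MD
fake_curve <- function(kind, P, inv_phi, mspec = NULL, espec = NULL,
                       mean_V = NA) {
  pts <- data.frame(target_P = P, inv_phi = inv_phi, phi = 1 / inv_phi,
                    mean_V = if (all(is.na(mean_V))) 100 * inv_phi else mean_V,
                    mean_P = P, stderr_P = 0.01 * P, n_samples = 100L,
                    ok = TRUE)
  pts <- pts[order(pts$target_P), ]
  structure(list(system_kind = kind, points = pts, matrix_spec = mspec,
                 embedded_spec = espec, params = model_parameters(),
                 master_seed = 1, n_particles = 100),
            class = "swelling_curve")
}

test_that("prestress of identical curves is identically zero", {
  x <- seq(2, 8, length.out = 9)
  a <- fake_curve("composite", P = 1 / x, inv_phi = x)
  b <- fake_curve("particles", P = 1 / x, inv_phi = x)
  res <- compute_prestress(a, b)
  expect_equal(res$grid$P_el, rep(0, nrow(res$grid)), tolerance = 1e-12)
})

test_that("prestress subtracts closed-form curves pointwise", {
  # Pi_emb = 2/x, Pi_com = 1/x on x = 1/phi: P_el = 1/x everywhere
  x <- seq(2, 10, length.out = 17)
  com <- fake_curve("composite", P = 1 / x, inv_phi = x)
  emb <- fake_curve("particles", P = 2 / x, inv_phi = x)
  res <- compute_prestress(com, emb, n_grid = 40)
  expect_equal(res$grid$P_el, 1 / res$grid$inv_phi, tolerance = 5e-3)
})

test_that("equilibrium swelling is root-found when bracketed, else extrapolated", {
  # bracketed: Pi_com = x0 - x crosses zero inside the sampled range
  x <- seq(2, 8, length.out = 13)
  x0 <- 5.37
  com <- fake_curve("composite", P = x0 - x, inv_phi = x)
  emb <- fake_curve("particles", P = 20 / x, inv_phi = x)
  res <- compute_prestress(com, emb)
  expect_false(res$extrapolated)
  expect_equal(res$inv_phi_eq, x0, tolerance = 1e-6)
  expect_equal(res$P_el_eq, 20 / x0, tolerance = 1e-2)

  # not bracketed: linear curve extrapolates exactly to its root
  x2 <- seq(2, 5, length.out = 6)
  com2 <- fake_curve("composite", P = 0.4 * (6.5 - x2), inv_phi = x2)
  emb2 <- fake_curve("particles", P = 8 / x2, inv_phi = x2)
  res2 <- compute_prestress(com2, emb2)
  expect_true(res2$extrapolated)
  expect_equal(res2$inv_phi_eq, 6.5, tolerance = 1e-9)
})

test_that("disjoint swelling ranges are rejected with both ranges named", {
  a <- fake_curve("composite", P = c(0.3, 0.2, 0.1), inv_phi = c(2, 3, 4))
  b <- fake_curve("particles", P = c(0.3, 0.2, 0.1), inv_phi = c(6, 7, 9))
  expect_error(compute_prestress(a, b), "no 1/phi overlap.*\\[2, 4\\].*\\[6, 9\\]")
})

test_that("swelling ratios are 1 at zero loading and validated for mismatch", {
  ms <- matrix_spec(3, 2)
  bare <- fake_curve("bare_gel", P = 0.01, inv_phi = 5, mspec = ms,
                     mean_V = 1000)
  c0 <- fake_curve("composite", P = 0.01, inv_phi = 5, mspec = ms,
                   mean_V = 1000)
  c1 <- fake_curve("composite", P = 0.01, inv_phi = 4.5, mspec = ms,
                   espec = embedded_spec(19), mean_V = 1300)
  out <- swelling_ratios(list(c0, c1), bare)
  expect_equal(out$v_ratio[1], 1)
  expect_equal(out$phi_ratio[1], 1)
  expect_equal(out$v_ratio[2], 1.3)
  expect_equal(out$composition, c(0, 19 * 13 / 243))

  other <- fake_curve("bare_gel", P = 0.01, inv_phi = 5,
                      mspec = matrix_spec(3, 4), mean_V = 900)
  expect_error(swelling_ratios(list(c1), other), "matrix specs")
  pwrong <- fake_curve("composite", P = 0.02, inv_phi = 5, mspec = ms,
                       mean_V = 1000)
  expect_error(swelling_ratios(list(pwrong), bare), "different pressures")
})

test_that("derived seeds are deterministic, distinct, and 32-bit safe", {
  s <- sapply(0:200, function(k) derive_seed(7, k))
  expect_identical(s, sapply(0:200, function(k) derive_seed(7, k)))
  expect_lt(max(s), 2^31)
  expect_gt(min(s), 0)
  expect_gt(length(unique(s)), 195)
  expect_false(derive_seed(7, 1) == derive_seed(8, 1))
})

test_that("a miniature bare-gel sweep compresses under rising pressure", {
  sw <- pressure_sweep("bare_gel", matrix_spec(2, 1),
                       pressures = c(0.05, 0.5),
                       n_equil_tau = 40, n_prod_tau = 60,
                       sample_every = 40, master_seed = 3)
  expect_s3_class(sw, "swelling_curve")
  expect_identical(nrow(sw$points), 2L)
  expect_true(all(sw$points$ok))
  expect_true(all(diff(sw$points$inv_phi) < 0))  # higher P, less swollen
  expect_true(all(sw$points$inv_phi > 1))
  f <- tempfile(fileext = ".csv")
  write_curve_csv(sw, f)
  back <- read.csv(f)
  expect_identical(nrow(back), 2L)
  expect_identical(back$system_kind[1], "bare_gel")
})
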