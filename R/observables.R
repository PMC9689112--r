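#' Volume fraction of a sampled system
#'
#' The bead volume fraction is `phi = (n_emb + n_mtx) * v_sphere / <v>` where
#' `v_sphere = (pi/6) sigma^3` is the volume of one bead and `<v>` the
#' production-average box volume.
#'
#' @param samples production sample data.frame from [run_md()] (column `V`),
#'   or a numeric vector of volumes.
#' @param n_particles total number of beads (or a `gel_topology`).
#' @return dimensionless volume fraction.
#' @export
volume_fraction <- function(samples, n_particles) {
  v <- if (is.data.frame(samples)) samples$V else samples
  if (length(v) == 0) stop("empty sample stream")
  if (inherits(n_particles, "gel_topology"))
    n_particles <- nrow(n_particles$coordinates)
  n_particles * (pi / 6) / mean(v)
}

#' Block-averaged mean pressure
#'
#' Mean and standard error of the instantaneous virial pressure, with the
#' standard error estimated from block averages (10 blocks by default) to
#' absorb serial correlation.
#'
#' @param samples sample data.frame (column `P_inst`) or numeric vector.
#' @param n_blocks number of blocks.
#' @return list with `mean`, `stderr`, `n`.
#' @export
mean_pressure <- function(samples, n_blocks = 10) {
  p <- if (is.data.frame(samples)) samples$P_inst else samples
  n <- length(p)
  if (n < n_blocks) stop("too few samples for block averaging")
  block <- rep(seq_len(n_blocks), each = ceiling(n / n_blocks))[seq_len(n)]
  bm <- tapply(p, block, mean)
  se <- stats::sd(bm) / sqrt(length(bm))
  list(mean = mean(p), stderr = as.numeric(se), n = n)
}

#' Bulk modulus from a pressure-volume isotherm
#'
#' Estimates the isothermal compressibility `kappa_T = -(1/V) dV/dP` by
#' centered finite differences on an isotherm of `(P, <V>)` points (one-sided
#' at the endpoints) and reports the bulk modulus `beta_T = 1 / kappa_T`.
#' Points where the isotherm is locally non-monotone (volume increasing with
#' pressure) are flagged.
#'
#' @param P strictly increasing external pressures.
#' @param V corresponding mean volumes.
#' @return data.frame with columns `P`, `V`, `kappa_T`, `beta_T`, `flagged`,
#'   and attribute `estimator = "finite_difference"`.
#' @export
bulk_modulus <- function(P, V) {
  if (length(P) < 3) stop("need at least 3 pressure points")
  if (is.unsorted(P, strictly = TRUE)) stop("P must be strictly increasing")
  n <- length(P)
  dVdP <- numeric(n)
  dVdP[1] <- (V[2] - V[1]) / (P[2] - P[1])
  dVdP[n] <- (V[n] - V[n - 1]) / (P[n] - P[n - 1])
  if (n > 2)
    for (i in 2:(n - 1))
      dVdP[i] <- (V[i + 1] - V[i - 1]) / (P[i + 1] - P[i - 1])
  kappa <- -dVdP / V
  out <- data.frame(P = P, V = V, kappa_T = kappa,
                    beta_T = ifelse(kappa > 0, 1 / kappa, Inf),
                    flagged = kappa <= 0)
  attr(out, "estimator") <- "finite_difference"
  out
}

#' Bulk modulus from NPT volume fluctuations
#'
#' Fluctuation estimator `kappa_T = var(V) / (kT <V>)` from a single NPT
#' sample stream; cross-validates the finite-difference isotherm estimator.
#'
#' @param samples sample data.frame (column `V`).
#' @param kT temperature.
#' @return list with `kappa_T`, `beta_T`.
#' @export
bulk_modulus_fluctuation <- function(samples, kT = 1.0) {
  v <- samples$V
  kappa <- stats::var(v) / (kT * mean(v))
  list(kappa_T = kappa, beta_T = 1 / kappa)
}

#' Fit a size-scaling exponent from chain sizes
#'
#' Least-squares slope of `log(Rg)` versus `log(N)`.
#'
#' @param N chain lengths.
#' @param Rg corresponding mean radii of gyration (same length).
#' @return list with `nu`, `stderr`, and the `lm` fit.
#' @export
fit_scaling_exponent <- function(N, Rg) {
  if (length(N) < 3) stop("need at least 3 chain lengths")
  fit <- stats::lm(log(Rg) ~ log(N))
  se <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[2]))
  list(nu = unname(stats::coef(fit)[2]), stderr = se, fit = fit)
}

#' Build an isolated linear chain topology
#'
#' A single N-bead chain in a box large enough that periodic images never
#' interact; used for solvent-quality (theta-point) calibration.
#'
#' @param N beads.
#' @param l0 initial bond spacing.
#' @return a `gel_topology` (all beads labelled matrix segments).
#' @export
single_chain_topology <- function(N, l0 = 0.99) {
  L <- max(4 * N * l0, 20)
  coords <- cbind(L / 2 + (seq_len(N) - (N + 1) / 2) * l0, L / 2, L / 2)
  bonds <- cbind(seq_len(N - 1), 2:N)
  new_gel_topology(coords, rep("matrix_segment", N), bonds,
                   rep(1L, N), L)
}

#' Chain-size scaling exponent at a given solvent quality
#'
#' Simulates isolated linear chains of several lengths with the non-bonded
#' attraction strength `lambda_` (applied to all pairs), samples the radius
#' of gyration after equilibration with a Langevin thermostat, and fits the
#' scaling exponent `nu` of `Rg ~ N^nu`.  At the theta point (`lambda =
#' 0.646` for this potential) `nu = 1/2`; in the athermal limit (`lambda =
#' 0`) small chains give an effective `nu ~ 0.59`.
#'
#' @param lambda_ solvent-quality parameter in `[0, 1]`.
#' @param chain_lengths at least 3 chain lengths.
#' @param seeds one or more seeds; runs are averaged per chain length.
#' @param n_equil_tau,n_prod_tau equilibration / production lengths in tau.
#' @param params base [model_parameters()] (lambda fields overridden).
#' @return list with `nu`, `stderr`, `Rg` (per-length means), `fit`.
#' @export
chain_scaling_exponent <- function(lambda_, chain_lengths = c(10, 20, 40),
                                   seeds = 1:3,
                                   n_equil_tau = 400, n_prod_tau = 1500,
                                   params = model_parameters()) {
  if (length(chain_lengths) < 3) stop("need at least 3 chain lengths")
  params <- as_model_parameters(params)
  params$lambda_mtx <- lambda_
  ne <- round(n_equil_tau / params$dt)
  np <- round(n_prod_tau / params$dt)
  rg <- sapply(chain_lengths, function(N) {
    top <- single_chain_topology(N)
    mean(sapply(seeds, function(s) {
      eq <- run_md(top, params, "langevin", n_steps = ne, sample_every = 0,
                   seed = s)
      pr <- run_md(top, params, "langevin", n_steps = np, sample_every = 200,
                   seed = s + 1000L, state = eq$state, record_rg = TRUE)
      mean(sqrt(pr$samples$Rg2))
    }))
  })
  res <- fit_scaling_exponent(chain_lengths, rg)
  res$Rg <- stats::setNames(rg, chain_lengths)
  res
}
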