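#' Evaluate forces, energy, and virial on a configuration
#'
#' Computes the exact gradient of the total potential (non-bonded pairs
#' within `r_cut`, bonded pairs excluded from the non-bonded term, plus all
#' harmonic bonds with minimum-image bond vectors) and the internal virial
#' `W = sum_ij r_ij . f_ij`.  Uses a linked-cell list when the box holds at
#' least three cells per direction and falls back to the direct double sum
#' otherwise; `direct = TRUE` forces the O(N^2) path.
#'
#' @param topology a `gel_topology`.
#' @param params a [model_parameters()].
#' @param coordinates optional replacement coordinates (defaults to the
#'   topology's).
#' @param direct force the direct all-pairs evaluation.
#' @return list with `forces` (N x 3), `energy`, `virial`.
#' @export
compute_forces <- function(topology, params = model_parameters(),
                           coordinates = NULL, direct = FALSE) {
  params <- as_model_parameters(params)
  pos <- if (is.null(coordinates)) topology$coordinates else coordinates
  .forces_cpp(pos, topology$box_length, topology$bonds,
              species_class(topology), unclass(params), direct)
}

#' Seeded Maxwell-Boltzmann initial velocities
#'
#' Draws velocities at temperature `kT` (mass 1) and removes the net momentum.
#'
#' @param n number of particles.
#' @param kT temperature.
#' @param seed RNG seed.
#' @return n x 3 matrix.
#' @export
init_velocities <- function(n, kT = 1.0, seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rnorm(3 * n, sd = sqrt(kT)), n, 3)
  if (n > 1) v <- sweep(v, 2, colMeans(v))
  v
}

md_state <- function(positions, velocities, box_length, step = 0L) {
  s <- list(positions = positions, velocities = velocities,
            box_length = box_length, step = step)
  class(s) <- "md_state"
  s
}

#' Run molecular dynamics
#'
#' Integrates the system with velocity-Verlet at timestep `dt` (in tau).
#' Ensembles: `"nve"`; `"nvt"` (Nose-Hoover chain of length 3, relaxation
#' time `thermo_damp`); `"npt"` (additionally an isotropic
#' Martyna-Tobias-Klein barostat with its own Nose-Hoover chain, relaxation
#' `baro_damp`); `"langevin"` (BAOAB, friction `gamma`; preferred for small
#' isolated molecules where a Nose-Hoover chain is not ergodic).  Per-sample
#' scalars (`step`, `V`, `T_inst`, `W`, `U`, `P_inst`, optionally `Rg2`) are
#' recorded every `sample_every` steps; the instantaneous pressure is the 3D
#' virial form `P = (2K + W) / (3V)` with `W = sum r_ij . f_ij`.
#'
#' @param topology a `gel_topology`.
#' @param params a [model_parameters()].
#' @param ensemble one of `"nve"`, `"nvt"`, `"npt"`, `"langevin"`.
#' @param n_steps number of timesteps.
#' @param target_pressure barostat set point (NPT only), epsilon/sigma^3.
#' @param sample_every sampling stride in steps (0 = no samples).
#' @param seed seed for initial velocities and any stochastic dynamics.
#' @param state optional `md_state` to continue from (positions, velocities,
#'   box); otherwise velocities are drawn fresh.
#' @param gamma Langevin friction, 1/tau.
#' @param ideal disable all interactions (ideal gas; for engine validation).
#' @param record_rg record the squared radius of gyration each sample
#'   (single-molecule runs).
#' @return list with `state` (an `md_state`) and `samples` (data.frame).
#' @export
run_md <- function(topology, params = model_parameters(),
                   ensemble = c("npt", "nvt", "nve", "langevin"),
                   n_steps = 10000, target_pressure = 0,
                   sample_every = 100, seed = 1, state = NULL,
                   gamma = 1.0, ideal = FALSE, record_rg = FALSE) {
  params <- as_model_parameters(params)
  ensemble <- match.arg(ensemble)
  ens_code <- match(ensemble, c("nve", "nvt", "npt", "langevin")) - 1L
  if (ensemble == "npt" && target_pressure < 0)
    stop("target_pressure must be non-negative")
  n <- n_particles(topology)
  if (is.null(state)) {
    pos <- topology$coordinates
    vel <- init_velocities(n, params$kT, seed)
    box <- topology$box_length
  } else {
    pos <- state$positions; vel <- state$velocities; box <- state$box_length
  }
  out <- .md_run_cpp(pos, vel, box, topology$bonds, species_class(topology),
                     unclass(params), ens_code, target_pressure,
                     as.integer(n_steps), as.integer(sample_every),
                     params$thermo_damp, params$baro_damp, gamma,
                     as.integer(seed), ideal, record_rg)
  list(state = md_state(out$positions, out$velocities, out$box_length,
                        step = n_steps),
       samples = out$samples)
}

#' Equilibrate and sample at constant pressure
#'
#' Convenience wrapper around [run_md()]: an NPT equilibration leg whose
#' samples are discarded followed by a production leg whose samples are
#' returned.
#'
#' @inheritParams run_md
#' @param n_equil_steps equilibration steps (discarded).
#' @param n_prod_steps production steps (sampled).
#' @return list with `state` and production `samples`.
#' @export
run_npt <- function(topology, params = model_parameters(),
                    target_pressure = 0.01,
                    n_equil_steps = 50000, n_prod_steps = 100000,
                    sample_every = 100, seed = 1, ideal = FALSE) {
  eq <- run_md(topology, params, "npt", n_steps = n_equil_steps,
               target_pressure = target_pressure, sample_every = 0,
               seed = seed, ideal = ideal)
  pr <- run_md(topology, params, "npt", n_steps = n_prod_steps,
               target_pressure = target_pressure,
               sample_every = sample_every, seed = seed + 1L,
               state = eq$state, ideal = ideal)
  pr
}
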