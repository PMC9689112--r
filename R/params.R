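#' Cosine-smoothing coefficients of the non-bonded potential
#'
#' The attractive tail of the non-bonded potential is smoothed with a term
#' proportional to `cos(alpha * r^2 + beta)`.  The coefficients are fixed by
#' two matching conditions: `alpha * r_min^2 + beta = pi` (so the tail joins
#' the square well continuously at the WCA minimum with zero force) and
#' `alpha * r_cut^2 + beta = 2*pi` (so both the potential and its derivative
#' vanish at the cutoff).  For the default radii `r_min = 2^(1/6)` and
#' `r_cut = 3/2` this yields the closed forms
#' `alpha = 4*pi / (9 - 4 * 2^(1/3))` and `beta = 2*pi - (9/4) * alpha`.
#'
#' @param r_min inner matching radius (the WCA minimum), sigma units.
#' @param r_cut outer cutoff radius, sigma units; must exceed `r_min`.
#' @return named list with components `alpha` (1/sigma^2) and `beta`
#'   (dimensionless).
#' @examples
#' smoothing_coefficients()            # defaults: alpha ~ 3.1731, beta ~ -0.8562
#' smoothing_coefficients(1, sqrt(2))  # alpha = pi, beta = 0
#' @export
smoothing_coefficients <- function(r_min = 2^(1 / 6), r_cut = 3 / 2) {
  if (!is.finite(r_min) || !is.finite(r_cut) || r_min <= 0 || r_cut <= r_min)
    stop("invalid radii: need r_cut > r_min > 0")
  alpha <- pi / (r_cut^2 - r_min^2)
  beta <- pi - alpha * r_min^2
  list(alpha = alpha, beta = beta)
}

#' Model parameters of the bead-spring composite-gel model
#'
#' Collects every constant of the model in reduced units (`epsilon = sigma =
#' m = 1`; time unit `tau = sigma * sqrt(m / epsilon)`).  The solvent-quality
#' parameters `lambda_*` in `[0, 1]` scale the depth of the attractive well of
#' the non-bonded potential per species pair: `lambda_mtx` for matrix-matrix,
#' `lambda_emb` for embedded-embedded, and `lambda_cr` for cross pairs.
#' `lambda = 0` is an athermal good solvent (pure WCA repulsion), `lambda = 1`
#' a poor solvent; the theta point for linear chains is at `lambda = 0.646`.
#' Bonds are stiff harmonic springs `V = spring_k * (r - bond_l0)^2` (note:
#' no 1/2 prefactor).
#'
#' @param epsilon,sigma,mass energy, length, and mass units (keep at 1).
#' @param kT thermal energy in epsilon units.
#' @param lambda_mtx,lambda_emb,lambda_cr attraction strengths in `[0, 1]`.
#' @param spring_k bond spring constant, epsilon/sigma^2.
#' @param bond_l0 equilibrium bond length, sigma.
#' @param r_min WCA minimum `2^(1/6) * sigma`.
#' @param r_cut smoothing cutoff, sigma.
#' @param dt integration timestep in tau.
#' @param thermo_damp thermostat relaxation time, tau (default `100 * dt`).
#' @param baro_damp barostat relaxation time, tau (default `1000 * dt`; raise
#'   to about `4000 * dt` for target pressures near 0.001 to avoid slow
#'   volume oscillations).
#' @return object of class `model_parameters`: a validated named list that
#'   additionally carries the matched smoothing coefficients `alpha`, `beta`.
#' @export
model_parameters <- function(epsilon = 1, sigma = 1, mass = 1, kT = 1.0,
                             lambda_mtx = 0, lambda_emb = 0, lambda_cr = 0,
                             spring_k = 1000, bond_l0 = 0.99,
                             r_min = 2^(1 / 6), r_cut = 3 / 2,
                             dt = 0.005,
                             thermo_damp = 100 * dt, baro_damp = 1000 * dt) {
  for (lam in c(lambda_mtx, lambda_emb, lambda_cr))
    if (!is.finite(lam) || lam < 0 || lam > 1)
      stop("lambda parameters must lie in [0, 1]")
  if (r_cut <= r_min) stop("r_cut must exceed r_min")
  if (dt <= 0) stop("dt must be positive")
  ab <- smoothing_coefficients(r_min, r_cut)
  p <- list(epsilon = epsilon, sigma = sigma, mass = mass, kT = kT,
            lambda_mtx = lambda_mtx, lambda_emb = lambda_emb,
            lambda_cr = lambda_cr,
            spring_k = spring_k, bond_l0 = bond_l0,
            r_min = r_min, r_cut = r_cut,
            alpha = ab$alpha, beta = ab$beta,
            dt = dt, thermo_damp = thermo_damp, baro_damp = baro_damp)
  class(p) <- "model_parameters"
  p
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Bead-spring model parameters (reduced units)\n")
  cat(sprintf("  kT = %g   dt = %g tau   thermo_damp = %g   baro_damp = %g\n",
              x$kT, x$dt, x$thermo_damp, x$baro_damp))
  cat(sprintf("  lambda: mtx = %g  emb = %g  cross = %g\n",
              x$lambda_mtx, x$lambda_emb, x$lambda_cr))
  cat(sprintf("  bonds: k = %g eps/sigma^2, l0 = %g sigma\n",
              x$spring_k, x$bond_l0))
  cat(sprintf("  non-bonded: r_min = %.6f, r_cut = %g, alpha = %.6f, beta = %.6f\n",
              x$r_min, x$r_cut, x$alpha, x$beta))
  invisible(x)
}

as_model_parameters <- function(p) {
  if (inherits(p, "model_parameters")) return(p)
  if (is.list(p)) return(do.call(model_parameters, p))
  stop("cannot interpret 'params'; use model_parameters()")
}
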