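#' Flory-Huggins mixing pressure
#'
#' `Pi_mix(phi) = -A * [ln(1 - phi) + phi + chi0 phi^2 + chi1 phi^3]` where
#' `A` is a single fitted pressure scale (`mix_prefactor`; in molar units it
#' corresponds to `R T / V1` with `V1` the solvent partial molar volume, not
#' separately identifiable in reduced simulation units) and `chi0`, `chi1`
#' are interaction parameters tied to the second and third virial
#' coefficients.  For small `phi` the leading behavior is
#' `A * (1/2 - chi0) * phi^2`, so `chi0 = 1/2` is the theta condition.
#'
#' @param phi polymer volume fraction in `(0, 1)` (0 allowed, giving 0).
#' @param chi0,chi1 interaction parameters.
#' @param mix_prefactor positive pressure scale `A`.
#' @return osmotic mixing pressure.
#' @export
pi_mix <- function(phi, chi0, chi1 = 0, mix_prefactor = 1) {
  if (any(phi >= 1) || any(phi < 0)) stop("phi must lie in [0, 1)")
  if (mix_prefactor <= 0) stop("mix_prefactor must be positive")
  -mix_prefactor * (log(1 - phi) + phi + chi0 * phi^2 + chi1 * phi^3)
}

#' Elastic pressure of the network
#'
#' `Pi_el(phi) = K1 phi^(1/3) + K2 phi^(4/3)`; with `K1 < 0` and `K2 > 0`
#' the network resists swelling at high dilution and resists compression at
#' high concentration.
#'
#' @param phi polymer volume fraction, positive.
#' @param K1,K2 elastic coefficients.
#' @return elastic osmotic pressure.
#' @export
pi_el <- function(phi, K1, K2) {
  if (any(phi < 0)) stop("phi must be non-negative")
  K1 * phi^(1 / 3) + K2 * phi^(4 / 3)
}

#' Osmotic virial expansion for the particle solution
#'
#' `Pi_emb = (rho / Mw_emb) * (1 + B2 rho + B3 rho^2)` in reduced units
#' (`kT = 1`): the dilute limit is the ideal osmotic law `Pi_emb / rho ->
#' 1 / Mw_emb` with `rho` the segment number density and `Mw_emb` the
#' particle molecular mass.
#'
#' @param rho segment number density, 1/sigma^3.
#' @param Mw_emb particle molecular mass (segments per particle).
#' @param B2,B3 second and third osmotic virial coefficients.
#' @return osmotic pressure.
#' @export
pi_particles_virial <- function(rho, Mw_emb, B2 = 0, B3 = 0) {
  if (any(rho < 0)) stop("rho must be non-negative")
  (rho / Mw_emb) * (1 + B2 * rho + B3 * rho^2)
}

#' Composite osmotic pressure of the continuum model
#'
#' `Pi_com(phi) = Pi_mix + Pi_el`.
#'
#' @inheritParams pi_mix
#' @inheritParams pi_el
#' @return osmotic pressure.
#' @export
pi_com <- function(phi, chi0, chi1, K1, K2, mix_prefactor = 1) {
  pi_mix(phi, chi0, chi1, mix_prefactor) + pi_el(phi, K1, K2)
}

#' Fit the continuum swelling-pressure model to a curve
#'
#' Bounded nonlinear least squares of `Pi_com(phi) = Pi_mix + Pi_el` to a
#' swelling-pressure data set, weighted by `1 / stderr^2` when point errors
#' are available.  The fit is multi-started (at least 8 seeded starting
#' points spread over the parameter box) and the best converged fit is
#' returned, which makes the result independent of the input point order.
#'
#' @param data a `swelling_curve`, or a data.frame with columns `phi`, `Pi`
#'   and optionally `stderr`.
#' @param fix named list of parameters to hold fixed (any of `chi0`, `chi1`,
#'   `K1`, `K2`, `mix_prefactor`; `mix_prefactor` is fixed at 1 by default
#'   since in reduced units it is degenerate with the chi parameters).
#' @param lower,upper named bounds for the free parameters.
#' @param n_starts number of multi-start points.
#' @param seed seed for the start-point design.
#' @return object of class `continuum_fit`: list with `params` (full named
#'   vector), `stderr` (for free parameters), `residuals`, `phi_root` (the
#'   fitted `Pi_com = 0` crossing in `phi`, NA when not bracketed),
#'   `identifiable` flag, and the underlying `nls` object.
#' @export
fit_composite <- function(data, fix = list(mix_prefactor = 1),
                          lower = c(chi0 = 0, chi1 = -1, K1 = -10, K2 = 0,
                                    mix_prefactor = 1e-6),
                          upper = c(chi0 = 2, chi1 = 1, K1 = 0, K2 = 10,
                                    mix_prefactor = 100),
                          n_starts = 8, seed = 1) {
  if (inherits(data, "swelling_curve")) {
    p <- curve_points(data)
    data <- data.frame(phi = p$phi, Pi = p$target_P, stderr = p$stderr_P)
  }
  if (nrow(data) < 5) stop("need at least 5 points to fit")
  if (max(data$phi) / min(data$phi) < 2)
    warning("phi range spans less than a factor of 2; fit may be ill-conditioned")
  w <- if (!is.null(data$stderr) && all(is.finite(data$stderr)) &&
           all(data$stderr > 0)) 1 / data$stderr^2 else rep(1, nrow(data))

  all_names <- c("chi0", "chi1", "K1", "K2", "mix_prefactor")
  fixed <- unlist(fix)
  free <- setdiff(all_names, names(fixed))
  if (length(free) == 0) stop("no free parameters")
  lo <- lower[free]; up <- upper[free]

  model_fun <- function(theta) {
    pars <- c(theta, fixed)[all_names]
    pi_com(data$phi, pars["chi0"], pars["chi1"], pars["K1"], pars["K2"],
           pars["mix_prefactor"])
  }

  set.seed(seed)
  starts <- replicate(n_starts, stats::runif(length(free), lo, up),
                      simplify = FALSE)
  starts <- lapply(starts, stats::setNames, free)

  resid_fun <- function(theta) sqrt(w) * (data$Pi - model_fun(theta))

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lo, upper = up, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("all fit starts failed")

  theta <- stats::setNames(best$fit$par, free)
  pars <- c(theta, fixed)[all_names]
  dof <- max(1, nrow(data) - length(free))
  s2 <- best$rss / dof
  se <- tryCatch(sqrt(diag(solve(best$fit$hessian)) * 2 * s2),
                 error = function(e) rep(NA_real_, length(free)))
  names(se) <- free
  identifiable <- all(is.finite(se))

  f0 <- function(phi) pi_com(phi, pars["chi0"], pars["chi1"], pars["K1"],
                             pars["K2"], pars["mix_prefactor"])
  rng <- range(data$phi)
  phi_root <- tryCatch({
    lo_ <- max(1e-6, rng[1] / 4)
    if (f0(lo_) * f0(rng[2]) < 0) stats::uniroot(f0, c(lo_, rng[2]))$root
    else NA_real_
  }, error = function(e) NA_real_)

  res <- list(params = pars, stderr = se,
              residuals = data$Pi - model_fun(theta),
              phi_root = phi_root, identifiable = identifiable,
              fit = best$fit, data = data)
  if (!identifiable)
    warning("fit has flat directions; parameter errors not identifiable")
  class(res) <- "continuum_fit"
  res
}

#' @export
print.continuum_fit <- function(x, ...) {
  cat("Continuum swelling-pressure fit (Pi_mix + Pi_el):\n")
  print(round(x$params, 5))
  cat(sprintf("  RMS residual = %.4g; Pi_com = 0 at phi = %s\n",
              sqrt(mean(x$residuals^2)),
              ifelse(is.na(x$phi_root), "NA (not bracketed)",
                     sprintf("%.4f", x$phi_root))))
  invisible(x)
}

#' Read a swelling-pressure curve from CSV
#'
#' Expects columns `phi`, `Pi`, and optionally `stderr`; the format used for
#' experimental swelling-pressure data.
#'
#' @param file CSV path.
#' @return data.frame ready for [fit_composite()].
#' @export
read_pressure_curve <- function(file) {
  df <- utils::read.csv(file)
  if (!all(c("phi", "Pi") %in% names(df)))
    stop("CSV must contain columns 'phi' and 'Pi'")
  df
}
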