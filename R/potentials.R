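#' Non-bonded pair potential
#'
#' Total non-bonded segment-segment interaction: a Weeks-Chandler-Andersen
#' core (Lennard-Jones cut and shifted at its minimum `r_min = 2^(1/6)`), a
#' square well of depth `lambda * epsilon` on `(0, r_min]`, and a cosine
#' smoothing tail `(1/2) * lambda * epsilon * (cos(alpha r^2 + beta) - 1)` on
#' `(r_min, r_cut]` that carries the potential continuously to zero with zero
#' slope at the cutoff.  The well depth at `r_min` is exactly
#' `-lambda * epsilon`.
#'
#' @param r separation distance(s), sigma units; must be positive.
#' @param lambda_ attraction strength in `[0, 1]`.
#' @param params a [model_parameters()] object (its own `lambda_*` fields are
#'   ignored here; the pair's `lambda_` is passed explicitly).
#' @return potential energy in epsilon units (vectorized over `r`).
#' @seealso [pair_force()], [bond_potential()], [potential_table()]
#' @export
pair_potential <- function(r, lambda_, params = model_parameters()) {
  params <- as_model_parameters(params)
  if (any(!is.finite(r)) || any(r <= 0)) stop("r must be positive")
  eps <- params$epsilon
  v <- numeric(length(r))
  core <- r <= params$r_min
  mid <- r > params$r_min & r <= params$r_cut
  if (any(core)) {
    sr6 <- (params$sigma / r[core])^6
    v[core] <- 4 * eps * (sr6^2 - sr6) + eps - lambda_ * eps
  }
  if (any(mid)) {
    v[mid] <- 0.5 * lambda_ * eps *
      (cos(params$alpha * r[mid]^2 + params$beta) - 1)
  }
  v
}

#' Non-bonded pair force
#'
#' Magnitude of the radial force `-dV/dr` for the non-bonded potential;
#' positive values are repulsive.  The square well is flat on its interior so
#' it contributes no force; the force is continuous at `r_min` (the WCA force
#' vanishes at its minimum and `sin(alpha r_min^2 + beta) = sin(pi) = 0`) and
#' vanishes identically for `r >= r_cut`.
#'
#' @inheritParams pair_potential
#' @return force magnitude in epsilon/sigma units (vectorized over `r`).
#' @export
pair_force <- function(r, lambda_, params = model_parameters()) {
  params <- as_model_parameters(params)
  if (any(!is.finite(r)) || any(r <= 0)) stop("r must be positive")
  eps <- params$epsilon
  f <- numeric(length(r))
  core <- r <= params$r_min
  mid <- r > params$r_min & r < params$r_cut
  if (any(core)) {
    rc <- r[core]
    sr6 <- (params$sigma / rc)^6
    f[core] <- (48 * eps * sr6^2 - 24 * eps * sr6) / rc
  }
  if (any(mid)) {
    rm <- r[mid]
    f[mid] <- lambda_ * eps * params$alpha * rm *
      sin(params$alpha * rm^2 + params$beta)
  }
  f
}

#' Harmonic bond potential and force
#'
#' Bonded neighbors interact through a stiff harmonic spring
#' `V_H(r) = k (r - l0)^2` with `k = 1000 eps/sigma^2` and `l0 = 0.99 sigma`
#' by default.  Note the literal form without a 1/2 prefactor.  Bonded pairs
#' are excluded from the non-bonded potential.
#'
#' @param r separation distance(s), sigma units; non-negative.
#' @param params a [model_parameters()] object supplying `spring_k`, `bond_l0`.
#' @return `bond_potential`: energy in epsilon units; `bond_force`: force
#'   magnitude `-dV/dr` (positive = repulsive), epsilon/sigma units.
#' @export
bond_potential <- function(r, params = model_parameters()) {
  params <- as_model_parameters(params)
  if (any(!is.finite(r)) || any(r < 0)) stop("r must be non-negative")
  params$spring_k * (r - params$bond_l0)^2
}

#' @rdname bond_potential
#' @export
bond_force <- function(r, params = model_parameters()) {
  params <- as_model_parameters(params)
  if (any(!is.finite(r)) || any(r < 0)) stop("r must be non-negative")
  -2 * params$spring_k * (r - params$bond_l0)
}

#' Tabulate the pair potential and force
#'
#' Evaluates `V(r)` and `F(r)` on a grid for plotting or inspection and
#' optionally writes the table as CSV.
#'
#' @param lambda_ attraction strength.
#' @param params a [model_parameters()] object.
#' @param r grid of separations (default 0.8 to `r_cut` + 0.1).
#' @param file optional CSV path.
#' @return data.frame with columns `r`, `V`, `F` (invisibly if written).
#' @export
potential_table <- function(lambda_, params = model_parameters(),
                            r = seq(0.8, params$r_cut + 0.1, by = 0.001),
                            file = NULL) {
  tab <- data.frame(r = r,
                    V = pair_potential(r, lambda_, params),
                    F = pair_force(r, lambda_, params))
  if (!is.null(file)) {
    utils::write.csv(tab, file, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
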