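#' Derive a per-run seed from a master seed
#'
#' Deterministic 32-bit linear-congruential mix of a master seed and a stream
#' index, so every (system, pressure) cell of an experiment gets its own
#' reproducible seed.
#'
#' @param master master seed (integer).
#' @param stream stream index (integer).
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stream) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) + 1
  for (i in seq_len(2)) s <- (48271 * s + 12345 + as.numeric(stream) * 30011) %% m
  as.integer(s + 1)
}

#' Sweep a system over external pressures
#'
#' Builds the requested system kind (composite gel, embedded-particle
#' solution, or bare gel), runs one NPT simulation per pressure, and collects
#' the swelling curve of mean inverse volume fraction against imposed
#' pressure.  Failed runs are annotated and skipped rather than aborting the
#' sweep.
#'
#' @param system_kind one of `"composite"`, `"particles"`, `"bare_gel"`.
#' @param mspec a [matrix_spec()] (ignored for `"particles"` except to set
#'   the particle count via `composition`).
#' @param espec an [embedded_spec()]; defaults to the count matching
#'   `composition` for the given matrix.
#' @param pressures vector of positive target pressures.
#' @param params a [model_parameters()] carrying the lambda values.
#' @param composition target `n_emb / n_mtx` when `espec` is NULL.
#' @param master_seed master seed; per-run seeds come from [derive_seed()].
#' @param n_equil_tau,n_prod_tau run lengths per pressure, in tau.
#' @param sample_every sampling stride in steps.
#' @param initial_phi initial volume fraction for box sizing.
#' @return object of class `swelling_curve`: data.frame `points` with columns
#'   `target_P`, `inv_phi`, `phi`, `mean_V`, `mean_P`, `stderr_P`,
#'   `n_samples`, `ok`, plus provenance fields.
#' @export
pressure_sweep <- function(system_kind = c("composite", "particles", "bare_gel"),
                           mspec, espec = NULL, pressures,
                           params = model_parameters(), composition = 1,
                           master_seed = 1,
                           n_equil_tau = 250, n_prod_tau = 500,
                           sample_every = 100, initial_phi = 0.05) {
  system_kind <- match.arg(system_kind)
  if (any(pressures <= 0)) stop("pressures must be positive")
  params <- as_model_parameters(params)
  if (is.null(espec) && system_kind != "bare_gel")
    espec <- embedded_spec(embedded_count_for_composition(mspec, composition))

  topo <- switch(system_kind,
    composite = insert_embedded(build_matrix(mspec, initial_phi, params),
                                espec, seed = derive_seed(master_seed, 0)),
    bare_gel = build_matrix(mspec, initial_phi, params),
    particles = insert_embedded(empty_topology(espec$n_emb, initial_phi),
                                espec, seed = derive_seed(master_seed, 0)))
  n <- n_particles(topo)
  ne <- round(n_equil_tau / params$dt)
  np <- round(n_prod_tau / params$dt)

  rows <- lapply(seq_along(pressures), function(i) {
    P <- pressures[i]
    seed <- derive_seed(master_seed, i)
    res <- tryCatch({
      out <- run_npt(topo, params, target_pressure = P,
                     n_equil_steps = ne, n_prod_steps = np,
                     sample_every = sample_every, seed = seed)
      phi <- volume_fraction(out$samples, n)
      mp <- mean_pressure(out$samples)
      data.frame(target_P = P, inv_phi = 1 / phi, phi = phi,
                 mean_V = mean(out$samples$V), mean_P = mp$mean,
                 stderr_P = mp$stderr, n_samples = mp$n, ok = TRUE)
    }, error = function(e) {
      warning(sprintf("run at P = %g failed: %s", P, conditionMessage(e)))
      data.frame(target_P = P, inv_phi = NA, phi = NA, mean_V = NA,
                 mean_P = NA, stderr_P = NA, n_samples = 0L, ok = FALSE)
    })
    res
  })
  pts <- do.call(rbind, rows)
  pts <- pts[order(pts$target_P), ]
  curve <- list(system_kind = system_kind, points = pts,
                matrix_spec = if (system_kind != "particles") mspec else NULL,
                embedded_spec = espec, params = params,
                master_seed = master_seed, n_particles = n,
                n_equil_tau = n_equil_tau, n_prod_tau = n_prod_tau)
  class(curve) <- "swelling_curve"
  curve
}

#' @export
print.swelling_curve <- function(x, ...) {
  cat(sprintf("Swelling curve (%s), %d particles, lambda_emb = %g:\n",
              x$system_kind, x$n_particles, x$params$lambda_emb))
  print(x$points[, c("target_P", "inv_phi", "mean_P", "stderr_P")],
        row.names = FALSE)
  invisible(x)
}

curve_points <- function(curve, min_points = 2) {
  p <- curve$points
  p <- p[p$ok & is.finite(p$inv_phi), , drop = FALSE]
  if (nrow(p) < min_points)
    stop(sprintf("swelling curve has fewer than %d usable points", min_points))
  p
}

# monotone interpolant Pi(x) on x = 1/phi from a swelling curve
curve_interpolant <- function(curve) {
  p <- curve_points(curve)
  ord <- order(p$inv_phi)
  stats::splinefun(p$inv_phi[ord], p$target_P[ord], method = "monoH.FC")
}

#' Prestress of a composite gel
#'
#' Interpolates the composite-gel and particle-solution swelling curves onto
#' a shared grid of inverse volume fraction (monotone piecewise-cubic
#' interpolation restricted to the overlap of the two ranges) and forms the
#' prestress `P_el = Pi_emb - Pi_com` pointwise.  The equilibrium swelling is
#' the `Pi_com = 0` crossing: root-found on the interpolant when the curve
#' brackets zero, otherwise linearly extrapolated from the two lowest-
#' pressure points (flagged).  The equilibrium prestress `P_el_eq` is the
#' particle-solution pressure at that swelling; at equilibrium `P_el_eq ~
#' Pi_emb` since `Pi_com = 0` there.
#'
#' @param composite `swelling_curve` of the composite gel.
#' @param particles `swelling_curve` of the embedded-particle solution.
#' @param n_grid grid resolution.
#' @param extend_past_equilibrium if positive, extend the grid beyond the
#'   composite's measured swelling range by up to this much in `1/phi`
#'   (never beyond the particle curve's range): the composite pressure is
#'   continued linearly from its two lowest-pressure points down to zero at
#'   the equilibrium swelling and held at zero beyond, so the prestress
#'   tracks `Pi_emb` there.  This reconstructs the region around equilibrium
#'   where the prestress peaks; the extension is marked in the grid.
#' @return object of class `prestress_result` with data.frame `grid`
#'   (columns `inv_phi`, `Pi_com`, `Pi_emb`, `P_el`, `extended`),
#'   `inv_phi_eq`, `P_el_eq`, `extrapolated`.
#' @export
compute_prestress <- function(composite, particles, n_grid = 50,
                              extend_past_equilibrium = 0) {
  pc <- curve_points(composite)
  pe <- curve_points(particles)
  lo <- max(min(pc$inv_phi), min(pe$inv_phi))
  hi_meas <- min(max(pc$inv_phi), max(pe$inv_phi))
  if (lo >= hi_meas)
    stop(sprintf(
      "no 1/phi overlap: composite [%.3g, %.3g] vs particles [%.3g, %.3g]",
      min(pc$inv_phi), max(pc$inv_phi), min(pe$inv_phi), max(pe$inv_phi)))
  fc <- curve_interpolant(composite)
  fe <- curve_interpolant(particles)

  # linear continuation of the composite curve from its two lowest-pressure
  # points (used both for the Pi_com = 0 crossing and the extension)
  ord <- order(pc$target_P)
  p2 <- pc[ord[1:2], ]
  slope <- diff(p2$target_P) / diff(p2$inv_phi)
  x_eq_lin <- p2$inv_phi[1] - p2$target_P[1] / slope

  hi <- hi_meas
  if (extend_past_equilibrium > 0)
    hi <- min(max(pe$inv_phi),
              max(hi_meas, max(pc$inv_phi) + extend_past_equilibrium))
  x <- seq(lo, hi, length.out = n_grid)
  xc_max <- max(pc$inv_phi)
  Pi_com <- ifelse(x <= xc_max, fc(pmin(x, xc_max)),
                   pmax(0, p2$target_P[1] + slope * (x - p2$inv_phi[1])))
  grid <- data.frame(inv_phi = x, Pi_com = Pi_com, Pi_emb = fe(x))
  grid$P_el <- grid$Pi_emb - grid$Pi_com
  grid$extended <- x > xc_max

  # equilibrium swelling: Pi_com = 0
  extrapolated <- FALSE
  if (min(pc$target_P) < 0 && max(pc$target_P) > 0) {
    inv_phi_eq <- stats::uniroot(fc, range(pc$inv_phi))$root
  } else {
    inv_phi_eq <- x_eq_lin
    extrapolated <- TRUE
  }
  # particle pressure at the crossing (extrapolate its own two lowest-P
  # points if the crossing lies beyond the particle curve's range)
  if (inv_phi_eq >= min(pe$inv_phi) && inv_phi_eq <= max(pe$inv_phi)) {
    P_el_eq <- fe(inv_phi_eq)
  } else {
    orde <- order(pe$target_P)
    q2 <- pe[orde[1:2], ]
    sl <- diff(q2$target_P) / diff(q2$inv_phi)
    P_el_eq <- q2$target_P[1] + sl * (inv_phi_eq - q2$inv_phi[1])
    extrapolated <- TRUE
  }
  res <- list(grid = grid, inv_phi_eq = inv_phi_eq, P_el_eq = P_el_eq,
              extrapolated = extrapolated,
              composite = composite, particles = particles)
  class(res) <- "prestress_result"
  res
}

#' @export
print.prestress_result <- function(x, ...) {
  cat(sprintf(
    "Prestress over 1/phi in [%.3f, %.3f]; equilibrium 1/phi = %.3f%s, P_el_eq = %.4g\n",
    min(x$grid$inv_phi), max(x$grid$inv_phi), x$inv_phi_eq,
    if (x$extrapolated) " (extrapolated)" else "", x$P_el_eq))
  invisible(x)
}

#' Swelling ratios of composite gels against the bare gel
#'
#' At a fixed imposed osmotic pressure, compares composite gels at several
#' compositions against the bare gel with the same matrix: `v/v0` is the mean
#' volume ratio and `phi/phi0` the volume-fraction ratio.
#'
#' @param composites list of `swelling_curve`s (single-pressure sweeps) at
#'   increasing composition.
#' @param bare the bare-gel `swelling_curve` at the same pressure and matrix.
#' @return data.frame with columns `composition`, `v_ratio`, `phi_ratio`.
#' @export
swelling_ratios <- function(composites, bare) {
  pb <- curve_points_single(bare)
  rows <- lapply(composites, function(cc) {
    if (!identical(unclass(cc$matrix_spec), unclass(bare$matrix_spec)))
      stop("matrix specs of composite and bare gel differ")
    p <- curve_points_single(cc)
    if (abs(p$target_P - pb$target_P) > 1e-12)
      stop("composite and bare gel were run at different pressures")
    comp <- if (is.null(cc$embedded_spec)) 0
            else cc$embedded_spec$n_emb / cc$matrix_spec$n_mtx
    data.frame(composition = comp,
               v_ratio = p$mean_V / pb$mean_V,
               phi_ratio = p$phi / pb$phi)
  })
  out <- do.call(rbind, rows)
  out[order(out$composition), ]
}

curve_points_single <- function(curve) {
  p <- curve_points(curve, min_points = 1)
  if (nrow(p) != 1) p <- p[1, , drop = FALSE]
  p
}

#' Write the points of a swelling curve as CSV
#'
#' @param curve a `swelling_curve`.
#' @param file output path.
#' @return the written data.frame, invisibly.
#' @export
write_curve_csv <- function(curve, file) {
  df <- cbind(system_kind = curve$system_kind, curve$points)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}

#' Plot a swelling curve
#'
#' Osmotic pressure against inverse volume fraction on a log pressure axis.
#'
#' @param x a `swelling_curve`.
#' @param add overlay on an existing plot.
#' @param ... passed to [graphics::points()].
#' @export
plot.swelling_curve <- function(x, add = FALSE, ...) {
  p <- curve_points(x, min_points = 1)
  if (!add) {
    graphics::plot(p$inv_phi, p$target_P, log = "y",
                   xlab = expression(1 / phi),
                   ylab = expression(Pi ~ (epsilon / sigma^3)),
                   type = "b", ...)
  } else {
    graphics::points(p$inv_phi, p$target_P, type = "b", ...)
  }
  invisible(x)
}

#' Plot a prestress result
#'
#' The interpolated composite and particle pressures and their difference
#' (the prestress) against inverse volume fraction, with the equilibrium
#' swelling marked.
#'
#' @param x a `prestress_result`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.prestress_result <- function(x, ...) {
  g <- x$grid
  graphics::matplot(g$inv_phi, cbind(g$Pi_com, g$Pi_emb, g$P_el),
                    type = "l", lty = c(2, 3, 1), col = c(2, 4, 1),
                    xlab = expression(1 / phi), ylab = "pressure", ...)
  graphics::abline(v = x$inv_phi_eq, col = "grey", lty = 4)
  graphics::legend("topright",
                   legend = c(expression(Pi[com]), expression(Pi[emb]),
                              expression(P[el])),
                   lty = c(2, 3, 1), col = c(2, 4, 1), bty = "n")
  invisible(x)
}
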