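# Brute-force R oracle for forces/energy/virial, built directly on the
# exported closed-form pair functions (independent of the engine's C++ path).

oracle_forces <- function(topology, params) {
  pos <- topology$coordinates %% topology$box_length
  L <- topology$box_length
  n <- nrow(pos)
  cls <- as.integer(topology$species %in% c("embedded_core", "embedded_segment"))
  lam_of <- function(ci, cj) {
    if (ci == cj) {
      if (ci == 0) params$lambda_mtx else params$lambda_emb
    } else params$lambda_cr
  }
  bonded <- matrix(FALSE, n, n)
  if (nrow(topology$bonds) > 0)
    for (b in seq_len(nrow(topology$bonds))) {
      i <- topology$bonds[b, 1]; j <- topology$bonds[b, 2]
      bonded[i, j] <- bonded[j, i] <- TRUE
    }
  F <- matrix(0, n, 3); U <- 0; W <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      d <- pos[i, ] - pos[j, ]
      d <- d - L * round(d / L)
      r <- sqrt(sum(d^2))
      if (bonded[i, j]) {
        U <- U + bond_potential(r, params)
        f <- bond_force(r, params)
      } else {
        if (r >= params$r_cut) next
        U <- U + pair_potential(r, lam_of(cls[i], cls[j]), params)
        f <- pair_force(r, lam_of(cls[i], cls[j]), params)
      }
      W <- W + f * r
      F[i, ] <- F[i, ] + f * d / r
      F[j, ] <- F[j, ] - f * d / r
    }
  list(forces = F, energy = U, virial = W)
}

# random configuration with a minimum pair distance (rejection sampling)
random_config <- function(n, L, min_dist = 0.85, seed = 1,
                          species = rep("matrix_segment", n),
                          bonds = matrix(0L, 0, 2)) {
  set.seed(seed)
  pos <- matrix(NA_real_, n, 3)
  placed <- 0
  while (placed < n) {
    cand <- runif(3, 0, L)
    ok <- TRUE
    if (placed > 0) {
      d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, cand)
      d <- d - L * round(d / L)
      ok <- min(rowSums(d^2)) >= min_dist^2
    }
    if (ok) {
      placed <- placed + 1
      pos[placed, ] <- cand
    }
  }
  gelpress:::new_gel_topology(pos, species, bonds, seq_len(n), L)
}

# small WCA fluid on a lattice start
wca_fluid <- function(n, rho, seed = 1) {
  L <- (n / rho)^(1 / 3)
  g <- ceiling(n^(1 / 3))
  pts <- (as.matrix(expand.grid(seq_len(g), seq_len(g), seq_len(g)))[seq_len(n), ]
          - 0.5) * (L / g)
  gelpress:::new_gel_topology(pts, rep("matrix_segment", n), matrix(0L, 0, 2),
                              seq_len(n), L)
}
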