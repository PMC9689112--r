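#' Specification of the cross-linked star-polymer matrix
#'
#' The polymer matrix is a periodic network of star polymers: `Nb` branch
#' points (star cores) per box direction on a simple cubic lattice, each star
#' carrying `f_mtx` arms of `M` segments, with arm tips bonded tip-to-tip to
#' the tips of neighboring stars (bonds through the periodic boundaries are
#' permitted).  The total number of matrix segments is
#' `n_mtx = Nb^3 * (f_mtx * M + 1)`.
#'
#' @param Nb branch points per direction (`Nx = Ny = Nz = Nb`), at least 2.
#' @param M segments per arm (the chain length between branch points is
#'   `2 * M`), at least 1.
#' @param f_mtx arms per star; the builder's lattice pattern requires 4.
#' @return object of class `matrix_spec` with derived field `n_mtx`.
#' @export
matrix_spec <- function(Nb, M, f_mtx = 4) {
  if (Nb < 2) stop("Nb must be at least 2")
  if (f_mtx < 3) stop("f_mtx must be at least 3")
  if (M < 1) stop("M must be at least 1")
  s <- list(Nb = as.integer(Nb), M = as.integer(M), f_mtx = as.integer(f_mtx),
            n_mtx = as.integer(Nb^3 * (f_mtx * M + 1)))
  class(s) <- "matrix_spec"
  s
}

#' Specification of the embedded star particles
#'
#' Embedded particles are small star polymers (`f_emb` arms of `M_emb`
#' segments plus a core), spherically symmetric at the default size, standing
#' in for the aggrecan-like microgel particles of the composite.  Molecular
#' mass `Mw_emb = f_emb * M_emb + 1`; total embedded segments
#' `n_emb = N_emb * Mw_emb`.
#'
#' @param N_emb number of embedded particles (0 gives a bare gel).
#' @param f_emb arms per particle.
#' @param M_emb segments per arm.
#' @return object of class `embedded_spec` with derived `Mw_emb`, `n_emb`.
#' @export
embedded_spec <- function(N_emb, f_emb = 4, M_emb = 3) {
  if (N_emb < 0) stop("N_emb must be non-negative")
  s <- list(N_emb = as.integer(N_emb), f_emb = as.integer(f_emb),
            M_emb = as.integer(M_emb),
            Mw_emb = as.integer(f_emb * M_emb + 1))
  s$n_emb <- as.integer(s$N_emb * s$Mw_emb)
  class(s) <- "embedded_spec"
  s
}

#' Number of embedded particles for a target segmental composition
#'
#' Picks `N_emb` so that `n_emb / n_mtx` is as close as possible to the target
#' composition (1 by default: equal numbers of embedded and matrix segments).
#'
#' @param mspec a [matrix_spec()].
#' @param composition target `n_emb / n_mtx`.
#' @param f_emb,M_emb embedded-particle architecture.
#' @return integer particle count.
#' @export
embedded_count_for_composition <- function(mspec, composition = 1,
                                           f_emb = 4, M_emb = 3) {
  as.integer(round(composition * mspec$n_mtx / (f_emb * M_emb + 1)))
}

species_levels <- c("matrix_core", "matrix_segment",
                    "embedded_core", "embedded_segment")

new_gel_topology <- function(coordinates, species, bonds, molecule_id,
                             box_length, matrix_spec = NULL,
                             embedded_spec = NULL) {
  stopifnot(is.matrix(coordinates), ncol(coordinates) == 3)
  bonds <- matrix(as.integer(bonds), ncol = 2,
                  dimnames = NULL)
  storage.mode(coordinates) <- "double"
  dimnames(coordinates) <- NULL
  t <- list(coordinates = coordinates,
            species = factor(species, levels = species_levels),
            bonds = bonds, molecule_id = as.integer(molecule_id),
            box_length = box_length,
            matrix_spec = matrix_spec, embedded_spec = embedded_spec)
  class(t) <- "gel_topology"
  t
}

#' @export
print.gel_topology <- function(x, ...) {
  cat(sprintf("Gel topology: %d particles, %d bonds, box L = %.4f sigma\n",
              nrow(x$coordinates), nrow(x$bonds), x$box_length))
  print(table(x$species))
  invisible(x)
}

n_particles <- function(topology) nrow(topology$coordinates)

#' Species class of each particle (0 = matrix, 1 = embedded)
#' @param topology a `gel_topology`.
#' @return integer vector.
#' @keywords internal
species_class <- function(topology) {
  as.integer(topology$species %in% c("embedded_core", "embedded_segment"))
}

#' Build the periodic star-polymer matrix
#'
#' Places `Nb^3` star cores on a cubic lattice in a periodic box sized so the
#' initial volume fraction equals `initial_phi`, and lays each bridge between
#' bonded neighbor cores as `2 * M` evenly spaced beads (an `M`-bead arm from
#' each core, joined by a tip-tip bond).  The 4-arm connection pattern is a
#' deterministic 4-regular spanning subgraph of the simple-cubic adjacency:
#' every core bridges its `+x` neighbor; cores in even-`i` lattice planes
#' bridge `+y`, cores in odd-`i` planes bridge `+z`.  Every core then uses
#' exactly 4 arm ends, and the bond graph is connected and winds all three
#' periodic directions for any `Nb >= 2`.
#'
#' @param spec a [matrix_spec()] (requires `f_mtx = 4`).
#' @param initial_phi initial bead volume fraction used to size the box (the
#'   NPT barostat relaxes it during equilibration).
#' @param params a [model_parameters()] (for the bond length).
#' @param pattern bridge-pattern function `function(Nb)` returning an integer
#'   matrix with columns `i, j, k, dx, dy, dz` (one row per bridge, lattice
#'   units); the default implements the axis-alternating pattern above.
#' @return a `gel_topology`.
#' @export
build_matrix <- function(spec, initial_phi = 0.05,
                         params = model_parameters(), pattern = NULL) {
  if (spec$f_mtx != 4)
    stop("the lattice bridge pattern is defined for f_mtx = 4")
  if (initial_phi <= 0 || initial_phi >= 1)
    stop("initial_phi must lie in (0, 1)")
  Nb <- spec$Nb; M <- spec$M
  n <- spec$n_mtx
  L <- (n * pi / 6 / initial_phi)^(1 / 3)
  a <- L / Nb
  if (a <= 0) stop("infeasible lattice spacing")
  # bridge beads are spaced a/(2M+1) apart; beads on bridges leaving the same
  # core along different axes come within sqrt(2) of that spacing.  Below
  # about 0.55 sigma the resulting WCA forces (~1e4 eps/sigma) throw beads
  # across the box in one timestep, so refuse to build such a start.
  if (a / (2 * M + 1) < 0.55)
    stop(sprintf(paste0(
      "initial_phi = %g packs bridge beads %.2f sigma apart for Nb = %d, ",
      "M = %d; reduce initial_phi below %.4g"),
      initial_phi, a / (2 * M + 1), Nb, M,
      initial_phi * (a / (2 * M + 1) / 0.55)^3))

  if (is.null(pattern)) pattern <- bridge_pattern_axis_alternating
  br <- pattern(Nb)

  ncore <- Nb^3
  core_index <- function(i, j, k) (i %% Nb) * Nb^2 + (j %% Nb) * Nb + (k %% Nb) + 1
  ijk <- as.matrix(expand.grid(k = 0:(Nb - 1), j = 0:(Nb - 1), i = 0:(Nb - 1)))
  ijk <- ijk[, c("i", "j", "k")]
  # core_index(i,j,k) ordering: i major, then j, then k
  ord <- order(ijk[, "i"], ijk[, "j"], ijk[, "k"])
  ijk <- ijk[ord, , drop = FALSE]
  cores <- ijk * a

  nbr <- nrow(br)
  stopifnot(nbr == 2 * ncore)  # 4-regular: 2 out-bridges per core
  npart <- n
  coords <- matrix(0, npart, 3)
  coords[seq_len(ncore), ] <- cores
  species <- rep("matrix_segment", npart)
  species[seq_len(ncore)] <- "matrix_core"
  molecule <- integer(npart)
  molecule[seq_len(ncore)] <- seq_len(ncore)

  bonds <- matrix(0L, nrow = ncore * spec$f_mtx * M + nbr, ncol = 2)
  bead <- ncore
  nb_bonds <- 0L
  d_bead <- a / (2 * M + 1)
  for (b in seq_len(nbr)) {
    i <- br[b, "i"]; j <- br[b, "j"]; k <- br[b, "k"]
    dvec <- c(br[b, "dx"], br[b, "dy"], br[b, "dz"])
    c1 <- core_index(i, j, k)
    c2 <- core_index(i + dvec[1], j + dvec[2], k + dvec[3])
    origin <- c(i, j, k) * a
    u <- dvec / sqrt(sum(dvec^2))
    # arm from c1: beads 1..M marching toward c2; arm from c2: beads M+1..2M
    # marching back; tip-tip bond joins bead M and bead M+1
    prev <- c1
    for (s in seq_len(M)) {
      bead <- bead + 1
      coords[bead, ] <- origin + u * (s * d_bead)
      molecule[bead] <- c1
      nb_bonds <- nb_bonds + 1L
      bonds[nb_bonds, ] <- c(prev, bead)
      prev <- bead
    }
    tip1 <- bead
    prev <- c2
    for (s in seq_len(M)) {
      bead <- bead + 1
      coords[bead, ] <- origin + u * ((2 * M + 1 - s) * d_bead)
      molecule[bead] <- c2
      nb_bonds <- nb_bonds + 1L
      bonds[nb_bonds, ] <- c(prev, bead)
      prev <- bead
    }
    nb_bonds <- nb_bonds + 1L
    bonds[nb_bonds, ] <- c(tip1, bead)  # tip-tip
  }
  stopifnot(bead == npart, nb_bonds == nrow(bonds))
  coords <- coords %% L

  new_gel_topology(coords, species, bonds, molecule, L,
                   matrix_spec = spec)
}

#' Axis-alternating 4-regular bridge pattern
#'
#' Every lattice site bridges `+x`; sites with even lattice index `i` bridge
#' `+y`, odd `i` bridge `+z`.  Each site then participates in exactly 4
#' bridges (two in x plus one out-bridge and one in-bridge in y or z), and
#' the network is connected and winds all three periodic directions for any
#' `Nb >= 2`.
#'
#' @param Nb branch points per direction.
#' @return integer matrix with columns `i, j, k, dx, dy, dz`.
#' @export
bridge_pattern_axis_alternating <- function(Nb) {
  g <- as.matrix(expand.grid(i = 0:(Nb - 1), j = 0:(Nb - 1), k = 0:(Nb - 1)))
  bx <- cbind(g, dx = 1L, dy = 0L, dz = 0L)
  even <- g[, "i"] %% 2 == 0
  by <- cbind(g[even, , drop = FALSE], dx = 0L, dy = 1L, dz = 0L)
  bz <- cbind(g[!even, , drop = FALSE], dx = 0L, dy = 0L, dz = 1L)
  rbind(bx, by, bz)
}

#' Insert embedded star particles without overlaps
#'
#' Places `N_emb` star particles (a core plus `f_emb` arms of `M_emb` beads at
#' bond-length spacing along random directions) at uniformly random positions
#' and orientations in the periodic box, rejecting any trial configuration
#' with a non-bonded minimum-image distance below the overlap threshold.
#' Deterministic for a given seed.
#'
#' @param topology a `gel_topology` (the matrix, or an empty box from
#'   [empty_topology()] for a particles-only system).
#' @param spec an [embedded_spec()].
#' @param seed RNG seed.
#' @param overlap_threshold minimum allowed non-bonded center distance
#'   (default `sigma = 1`).
#' @param max_trials insertion attempts before giving up.
#' @return a `gel_topology` including the embedded particles.
#' @export
insert_embedded <- function(topology, spec, seed = 1,
                            overlap_threshold = 1, max_trials = 1e6) {
  if (spec$N_emb == 0) {
    topology$embedded_spec <- spec
    return(topology)
  }
  L <- topology$box_length
  old_n <- n_particles(topology)
  per_star <- spec$Mw_emb
  new_coords <- matrix(0, spec$N_emb * per_star, 3)
  new_bonds <- matrix(0L, spec$N_emb * spec$f_emb * spec$M_emb, 2)
  l0 <- 0.99

  all_pts <- topology$coordinates  # grows as stars are accepted
  placed <- 0L
  trials <- 0L
  ib <- 0L
  set.seed(seed)
  while (placed < spec$N_emb) {
    trials <- trials + 1L
    if (trials > max_trials)
      stop(sprintf("packing failure: placed %d of %d embedded particles in %d trials",
                   placed, spec$N_emb, as.integer(max_trials)))
    core <- stats::runif(3, 0, L)
    dirs <- matrix(stats::rnorm(3 * spec$f_emb), spec$f_emb, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    star <- matrix(0, per_star, 3)
    star[1, ] <- core
    row <- 1L
    for (arm in seq_len(spec$f_emb))
      for (s in seq_len(spec$M_emb)) {
        row <- row + 1L
        star[row, ] <- core + dirs[arm, ] * (s * l0)
      }
    star <- star %% L
    # reject on any non-bonded overlap (against existing beads and within the
    # trial star itself, bonded neighbors excepted by distance: arm beads along
    # one arm are l0 apart which exceeds typical thresholds only if > l0)
    if (min_image_min_dist(star, all_pts, L) < overlap_threshold) next
    if (star_self_overlap(star, spec, L, overlap_threshold)) next
    placed <- placed + 1L
    off <- old_n + (placed - 1L) * per_star
    new_coords[(placed - 1L) * per_star + seq_len(per_star), ] <- star
    row <- 1L
    for (arm in seq_len(spec$f_emb)) {
      prev <- off + 1L  # star core
      for (s in seq_len(spec$M_emb)) {
        row <- row + 1L
        ib <- ib + 1L
        new_bonds[ib, ] <- c(prev, off + row)
        prev <- off + row
      }
    }
    all_pts <- rbind(all_pts, star)
  }

  species <- c(as.character(topology$species),
               rep(c("embedded_core", rep("embedded_segment", per_star - 1L)),
                   spec$N_emb))
  mol0 <- if (old_n > 0) max(topology$molecule_id) else 0L
  molecule <- c(topology$molecule_id,
                rep(mol0 + seq_len(spec$N_emb), each = per_star))
  new_gel_topology(rbind(topology$coordinates, new_coords), species,
                   rbind(topology$bonds, new_bonds), molecule, L,
                   matrix_spec = topology$matrix_spec, embedded_spec = spec)
}

# smallest minimum-image distance between any row of a and any row of b
min_image_min_dist <- function(a, b, L) {
  if (nrow(b) == 0) return(Inf)
  dmin <- Inf
  for (r in seq_len(nrow(a))) {
    d <- sweep(b, 2, a[r, ])
    d <- d - L * round(d / L)
    dmin <- min(dmin, sqrt(min(rowSums(d^2))))
  }
  dmin
}

# non-bonded overlap within a trial star (bonded neighbors along an arm and
# the core-first-bead bonds are exempt)
star_self_overlap <- function(star, spec, L, threshold) {
  n <- nrow(star)
  bonded <- matrix(FALSE, n, n)
  row <- 1L
  for (arm in seq_len(spec$f_emb)) {
    prev <- 1L
    for (s in seq_len(spec$M_emb)) {
      row <- row + 1L
      bonded[prev, row] <- bonded[row, prev] <- TRUE
      prev <- row
    }
  }
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      if (bonded[i, j]) next
      d <- star[i, ] - star[j, ]
      d <- d - L * round(d / L)
      if (sqrt(sum(d^2)) < threshold) return(TRUE)
    }
  FALSE
}

#' Empty periodic box (for particles-only systems)
#'
#' @param n_target number of beads the box should accommodate at volume
#'   fraction `phi` (used only to size the box).
#' @param phi target bead volume fraction.
#' @return a `gel_topology` with zero particles.
#' @export
empty_topology <- function(n_target, phi = 0.05) {
  L <- (n_target * pi / 6 / phi)^(1 / 3)
  new_gel_topology(matrix(0, 0, 3), character(0), matrix(0L, 0, 2),
                   integer(0), L)
}

#' Segmental composition of a topology
#'
#' Ratio of embedded-particle segments to matrix segments, counted from the
#' species labels.  A bare gel has composition 0.
#'
#' @param topology a `gel_topology`.
#' @return dimensionless ratio `n_emb / n_mtx`.
#' @export
composition <- function(topology) {
  n_emb <- sum(species_class(topology) == 1L)
  n_mtx <- sum(species_class(topology) == 0L)
  if (n_mtx == 0) stop("topology has no matrix segments")
  n_emb / n_mtx
}

#' Connectivity and periodic winding of the matrix bond graph
#'
#' Breadth-first traversal over the bond graph, assigning every particle an
#' unwrapped image-consistent coordinate; a non-tree bond whose end-to-end
#' offset is a non-zero multiple of the box length in direction d proves a
#' cycle winding the box in d.
#'
#' @param topology a `gel_topology`.
#' @param matrix_only restrict to matrix particles (default TRUE).
#' @return list with `connected` (logical) and `spans` (logical 3-vector for
#'   x, y, z).
#' @export
network_span <- function(topology, matrix_only = TRUE) {
  keep <- if (matrix_only) which(species_class(topology) == 0L)
          else seq_len(n_particles(topology))
  idx <- match(seq_len(n_particles(topology)), keep)
  b <- topology$bonds
  b <- b[!is.na(idx[b[, 1]]) & !is.na(idx[b[, 2]]), , drop = FALSE]
  b <- cbind(idx[b[, 1]], idx[b[, 2]])
  n <- length(keep)
  L <- topology$box_length
  pos <- topology$coordinates[keep, , drop = FALSE]

  adj <- vector("list", n)
  for (e in seq_len(nrow(b))) {
    adj[[b[e, 1]]] <- c(adj[[b[e, 1]]], e)
    adj[[b[e, 2]]] <- c(adj[[b[e, 2]]], e)
  }
  unwrapped <- matrix(NA_real_, n, 3)
  visited <- rep(FALSE, n)
  spans <- c(FALSE, FALSE, FALSE)
  queue <- integer(n)
  unwrapped[1, ] <- pos[1, ]
  visited[1] <- TRUE
  queue[1] <- 1L; head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (e in adj[[v]]) {
      w <- if (b[e, 1] == v) b[e, 2] else b[e, 1]
      dv <- pos[w, ] - pos[v, ]
      dv <- dv - L * round(dv / L)
      if (!visited[w]) {
        visited[w] <- TRUE
        unwrapped[w, ] <- unwrapped[v, ] + dv
        tail <- tail + 1L
        queue[tail] <- w
      } else {
        off <- round((unwrapped[v, ] + dv - unwrapped[w, ]) / L)
        spans <- spans | (off != 0)
      }
    }
  }
  list(connected = all(visited), spans = spans)
}
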