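test_that("particle and bond counts follow the closed formulas on a grid", {
  for (Nb in c(2, 3, 4)) {
    for (M in c(1, 2, 4, 8)) {
      spec <- matrix_spec(Nb, M)
      # long arms need a dilute start for a non-overlapping construction
      top <- build_matrix(spec, initial_phi = if (M == 8) 0.01 else 0.05)
      n_mtx <- Nb^3 * (4 * M + 1)
      expect_identical(nrow(top$coordinates), as.integer(n_mtx))
      expect_identical(spec$n_mtx, as.integer(n_mtx))
      # intra-star bonds Nb^3*f*M; tip-tip bonds Nb^3*f/2
      expect_identical(nrow(top$bonds), as.integer(Nb^3 * 4 * M + Nb^3 * 2))
      mol <- top$molecule_id
      cross <- mol[top$bonds[, 1]] != mol[top$bonds[, 2]]
      expect_identical(sum(cross), as.integer(Nb^3 * 4 / 2))
    }
  }
})

test_that("every star uses exactly four arm ends and tips pair uniquely", {
  top <- build_matrix(matrix_spec(3, 2))
  ncore <- 27
  deg <- tabulate(c(top$bonds), nbins = nrow(top$coordinates))
  expect_true(all(deg[seq_len(ncore)] == 4))   # 4 arms leave every core
  expect_true(all(deg[-seq_len(ncore)] == 2))  # every segment is mid-chain
  # each tip participates in exactly one inter-star (cross-molecule) bond
  mol <- top$molecule_id
  cross <- top$bonds[mol[top$bonds[, 1]] != mol[top$bonds[, 2]], , drop = FALSE]
  tips <- c(cross)
  expect_identical(anyDuplicated(tips), 0L)
  expect_identical(length(tips), 2L * as.integer(27 * 4 / 2))
})

test_that("matrix bond graph is connected and winds all periodic directions", {
  for (Nb in c(2, 3)) {
    top <- build_matrix(matrix_spec(Nb, 2))
    sp <- network_span(top)
    expect_true(sp$connected)
    expect_true(all(sp$spans))
  }
})

test_that("no non-bonded pair is closer than the overlap threshold at build", {
  top <- build_matrix(matrix_spec(2, 2))
  n <- nrow(top$coordinates)
  L <- top$box_length
  bonded <- matrix(FALSE, n, n)
  for (b in seq_len(nrow(top$bonds)))
    bonded[top$bonds[b, 1], top$bonds[b, 2]] <-
      bonded[top$bonds[b, 2], top$bonds[b, 1]] <- TRUE
  dmin <- Inf
  for (i in seq_len(n - 1)) {
    d <- sweep(top$coordinates[(i + 1):n, , drop = FALSE], 2,
               top$coordinates[i, ])
    d <- d - L * round(d / L)
    r <- sqrt(rowSums(d^2))
    r[bonded[i, (i + 1):n]] <- Inf
    dmin <- min(dmin, r)
  }
  expect_gte(dmin, 1.0)
})

test_that("embedded insertion is deterministic, counted, and overlap-free", {
  ms <- matrix_spec(3, 2)
  base <- build_matrix(ms)
  es0 <- embedded_spec(0)
  expect_identical(insert_embedded(base, es0)$coordinates, base$coordinates)

  # composition target 1 for Nb=3, M=2: round(243 / 13) = 19 particles
  Ne <- embedded_count_for_composition(ms, 1)
  expect_identical(Ne, 19L)
  es <- embedded_spec(Ne)
  expect_identical(es$n_emb, as.integer(19 * 13))
  top <- insert_embedded(base, es, seed = 5)
  expect_identical(nrow(top$coordinates), as.integer(243 + 19 * 13))
  expect_identical(nrow(top$bonds),
                   nrow(base$bonds) + as.integer(19 * 4 * 3))
  expect_equal(composition(top), 19 * 13 / 243, tolerance = 1e-12)

  top2 <- insert_embedded(base, es, seed = 5)
  expect_identical(top$coordinates, top2$coordinates)
  top3 <- insert_embedded(base, es, seed = 6)
  expect_false(identical(top$coordinates, top3$coordinates))

  # composition is linear in the number of embedded particles
  half <- insert_embedded(base, embedded_spec(10), seed = 5)
  expect_equal(composition(half), 10 * 13 / 243, tolerance = 1e-12)

  # minimum distance between the inserted star beads and everything else
  new_idx <- 244:nrow(top$coordinates)
  d <- gelpress:::min_image_min_dist(top$coordinates[new_idx[1:26], ],
                                     top$coordinates[1:243, ],
                                     top$box_length)
  expect_gte(d, 1.0)
})

test_that("insertion into an impossibly small box reports packing failure", {
  tiny <- empty_topology(5, phi = 0.05)
  tiny$box_length <- 2.5
  expect_error(
    insert_embedded(tiny, embedded_spec(8), seed = 1, max_trials = 200),
    "packing failure.*placed")
})

test_that("bare gel composition is zero and requires a matrix", {
  top <- build_matrix(matrix_spec(2, 1))
  expect_identical(composition(top), 0)
  sol <- insert_embedded(empty_topology(26, 0.02), embedded_spec(2), seed = 2)
  expect_error(composition(sol), "no matrix")
})

test_that("topology serialization round-trips exactly", {
  ms <- matrix_spec(2, 2)
  top <- insert_embedded(build_matrix(ms), embedded_spec(3), seed = 9)
  f1 <- tempfile(fileext = ".data")
  write_topology_lammps(top, f1)
  back <- read_topology_lammps(f1)
  expect_equal(back$coordinates, top$coordinates, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(as.character(back$species), as.character(top$species))
  expect_identical(back$bonds, top$bonds, ignore_attr = TRUE)
  expect_equal(back$box_length, top$box_length, tolerance = 1e-9)

  f2 <- tempfile(fileext = ".xyz")
  write_topology_xyz(top, f2)
  lines <- readLines(f2)
  expect_identical(as.integer(lines[1]), nrow(top$coordinates))
  expect_match(lines[2], "Lattice=")

  f3 <- tempfile(fileext = ".json")
  write_topology_json(top, f3)
  meta <- jsonlite::read_json(f3)
  expect_identical(meta$n_particles, nrow(top$coordinates))
  expect_identical(meta$matrix_spec$Nb, 2L)
})
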