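#' Write a topology as a LAMMPS-style data file
#'
#' Atoms in `full` style (id, molecule, type, charge = 0, x, y, z) with the
#' four species as atom types in the order matrix_core, matrix_segment,
#' embedded_core, embedded_segment, plus a Bonds section (single bond type).
#' Coordinates are stored wrapped into `[0, L)`.
#'
#' @param topology a `gel_topology`.
#' @param file output path.
#' @export
write_topology_lammps <- function(topology, file) {
  n <- n_particles(topology)
  nb <- nrow(topology$bonds)
  L <- topology$box_length
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("composite gel topology", "",
               sprintf("%d atoms", n), sprintf("%d bonds", nb),
               "4 atom types", "1 bond types", "",
               sprintf("0.0 %.10f xlo xhi", L),
               sprintf("0.0 %.10f ylo yhi", L),
               sprintf("0.0 %.10f zlo zhi", L), "",
               "Atoms # full", ""), con)
  type <- as.integer(topology$species)
  writeLines(sprintf("%d %d %d 0.0 %.10f %.10f %.10f",
                     seq_len(n), topology$molecule_id, type,
                     topology$coordinates[, 1], topology$coordinates[, 2],
                     topology$coordinates[, 3]), con)
  if (nb > 0) {
    writeLines(c("", "Bonds", ""), con)
    writeLines(sprintf("%d 1 %d %d", seq_len(nb),
                       topology$bonds[, 1], topology$bonds[, 2]), con)
  }
  invisible(file)
}

#' Read a topology written by [write_topology_lammps()]
#'
#' @param file path to the data file.
#' @return a `gel_topology`.
#' @export
read_topology_lammps <- function(file) {
  lines <- readLines(file)
  n <- as.integer(sub(" atoms", "", grep(" atoms$", lines, value = TRUE)[1]))
  nb <- as.integer(sub(" bonds", "", grep(" bonds$", lines, value = TRUE)[1]))
  L <- as.numeric(strsplit(grep("xlo xhi", lines, value = TRUE)[1], " ")[[1]][2])
  ia <- grep("^Atoms", lines)[1] + 2
  at <- utils::read.table(text = lines[ia:(ia + n - 1)])
  ord <- order(at$V1)
  at <- at[ord, ]
  bonds <- matrix(0L, 0, 2)
  if (nb > 0) {
    ib <- grep("^Bonds", lines)[1] + 2
    bt <- utils::read.table(text = lines[ib:(ib + nb - 1)])
    bonds <- as.matrix(bt[, 3:4])
    dimnames(bonds) <- NULL
    storage.mode(bonds) <- "integer"
  }
  new_gel_topology(as.matrix(at[, 5:7]), species_levels[at$V3],
                   bonds, at$V2, L)
}

#' Write a topology as extended XYZ
#'
#' One frame with a `Lattice` header (cubic box) and columns
#' species x y z.
#'
#' @param topology a `gel_topology`.
#' @param file output path.
#' @export
write_topology_xyz <- function(topology, file) {
  n <- n_particles(topology)
  L <- topology$box_length
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%d", n), con)
  writeLines(sprintf(
    'Lattice="%.10f 0 0 0 %.10f 0 0 0 %.10f" Properties=species:S:1:pos:R:3',
    L, L, L), con)
  writeLines(sprintf("%s %.10f %.10f %.10f", as.character(topology$species),
                     topology$coordinates[, 1], topology$coordinates[, 2],
                     topology$coordinates[, 3]), con)
  invisible(file)
}

#' Write the topology's spec provenance as a JSON sidecar
#'
#' @param topology a `gel_topology`.
#' @param file output path.
#' @export
write_topology_json <- function(topology, file) {
  meta <- list(
    n_particles = n_particles(topology),
    n_bonds = nrow(topology$bonds),
    box_length = topology$box_length,
    species_counts = as.list(table(topology$species)),
    matrix_spec = if (!is.null(topology$matrix_spec))
      unclass(topology$matrix_spec) else NULL,
    embedded_spec = if (!is.null(topology$embedded_spec))
      unclass(topology$embedded_spec) else NULL)
  jsonlite::write_json(meta, file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(file)
}
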