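config_schema <- list(
  model = c("epsilon", "sigma", "mass", "kT", "lambda_mtx", "lambda_emb",
            "lambda_cr", "spring_k", "bond_l0", "r_min", "r_cut", "dt",
            "thermo_damp", "baro_damp"),
  matrix = c("Nb", "M", "f_mtx"),
  embedded = c("N_emb", "f_emb", "M_emb", "composition"),
  run = c("n_equil_tau", "n_prod_tau", "sample_every", "initial_phi"),
  top = c("model", "matrix", "embedded", "run", "system_kinds", "pressures",
          "master_seed", "output_dir"))

#' Load and validate an experiment configuration
#'
#' Reads a YAML experiment description, rejects unknown keys, applies the
#' model defaults (`f_mtx = 4`, `f_emb = 4`, `M_emb = 3`, `kT = 1`, `dt =
#' 0.005`, ...), and returns a normalized configuration.  The minimal valid
#' config specifies only `matrix: {Nb: ..., M: ...}`.
#'
#' @param path YAML file path.
#' @return object of class `experiment_config`: list with `params`
#'   ([model_parameters()]), `matrix` ([matrix_spec()]), `embedded`
#'   ([embedded_spec()] or NULL), `system_kinds`, `pressures`,
#'   `master_seed`, `run`, `output_dir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop(sprintf("unknown config key%s in %s: %s",
                   if (length(bad) > 1) "s" else "", where,
                   paste(bad, collapse = ", ")))
  }
  check_keys(raw, config_schema$top, "top level")
  for (blk in c("model", "matrix", "embedded", "run"))
    if (!is.null(raw[[blk]]))
      check_keys(raw[[blk]], config_schema[[blk]], blk)

  if (is.null(raw$matrix$Nb) || is.null(raw$matrix$M))
    stop("config must specify matrix: Nb and M")

  params <- do.call(model_parameters, if (is.null(raw$model)) list()
                                      else raw$model)
  mspec <- matrix_spec(raw$matrix$Nb, raw$matrix$M,
                       f_mtx = raw$matrix$f_mtx %||% 4)
  espec <- NULL
  if (!is.null(raw$embedded)) {
    e <- raw$embedded
    N_emb <- if (!is.null(e$N_emb)) e$N_emb
             else embedded_count_for_composition(
                    mspec, e$composition %||% 1,
                    f_emb = e$f_emb %||% 4, M_emb = e$M_emb %||% 3)
    espec <- embedded_spec(N_emb, f_emb = e$f_emb %||% 4,
                           M_emb = e$M_emb %||% 3)
  }
  run <- list(n_equil_tau = raw$run$n_equil_tau %||% 250,
              n_prod_tau = raw$run$n_prod_tau %||% 500,
              sample_every = raw$run$sample_every %||% 100,
              initial_phi = raw$run$initial_phi %||% 0.05)
  cfg <- list(params = params, matrix = mspec, embedded = espec,
              system_kinds = raw$system_kinds %||% "composite",
              pressures = raw$pressures %||% c(0.01, 0.05, 0.2),
              master_seed = raw$master_seed %||% 1,
              run = run, output_dir = raw$output_dir %||% ".")
  class(cfg) <- "experiment_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an experiment configuration back to YAML
#'
#' Writes the normalized (defaults-applied) configuration; loading the result
#' reproduces the same configuration, so every output directory can carry its
#' effective config as provenance.
#'
#' @param cfg an `experiment_config`.
#' @param path output YAML path.
#' @export
write_config <- function(cfg, path) {
  raw <- list(
    model = unclass(cfg$params)[config_schema$model],
    matrix = unclass(cfg$matrix)[c("Nb", "M", "f_mtx")],
    run = cfg$run,
    system_kinds = cfg$system_kinds,
    pressures = cfg$pressures,
    master_seed = cfg$master_seed,
    output_dir = cfg$output_dir)
  if (!is.null(cfg$embedded))
    raw$embedded <- unclass(cfg$embedded)[c("N_emb", "f_emb", "M_emb")]
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

#' Deterministic miniature test systems
#'
#' Small exactly-countable systems used in tests and demonstrations:
#' `two_particle` (a bonded pair at the equilibrium bond length),
#' `tiny_gel` (the smallest matrix, `Nb = 2`, `M = 1`: 40 particles),
#' `single_chain` (an isolated 10-bead chain), and `ideal_gas` (500
#' unbonded particles at random positions).
#'
#' @param kind fixture name.
#' @param seed RNG seed where randomness is involved.
#' @return a `gel_topology`.
#' @export
make_fixture <- function(kind = c("two_particle", "tiny_gel", "single_chain",
                                  "ideal_gas"), seed = 1) {
  kind <- match.arg(kind)
  switch(kind,
    two_particle = {
      L <- 10
      new_gel_topology(rbind(c(4.5, 5, 5), c(4.5 + 0.99, 5, 5)),
                       rep("matrix_segment", 2), cbind(1L, 2L),
                       c(1L, 1L), L)
    },
    tiny_gel = build_matrix(matrix_spec(Nb = 2, M = 1)),
    single_chain = single_chain_topology(10),
    ideal_gas = {
      set.seed(seed)
      n <- 500
      L <- (n / 0.5)^(1 / 3) * 1.0  # rho = 0.5 at construction
      new_gel_topology(matrix(stats::runif(3 * n, 0, L), n, 3),
                       rep("matrix_segment", n), matrix(0L, 0, 2),
                       seq_len(n), L)
    })
}
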