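#' Run configuration
#'
#' Bundles every tunable of the pipeline. Defaults reproduce the method's
#' standard settings: identity thresholds 85 down to 10 by 5 (16
#' conditions), neighbor thresholds 5.0 to 9.0 Angstrom by 0.5, at least
#' 10 sequences per candidate, separation degree at most 3, 10,000
#' permutation replicates at a 5\% upper tail, and a 9 Angstrom
#' functional-region radius.
#'
#' @param X_grid,D_grid,min_sequences,max_separation,n_perm,alpha_fraction
#'   See [select_homologs()] and [lmic_mc_test()].
#' @param seed Integer seed used for every stochastic step.
#' @param shell_spacing,shell_clash,shell_margin Solvent-shell grid
#'   parameters (Angstrom).
#' @param jitter Tessellation degeneracy-breaking jitter (Angstrom).
#' @param aligner Aligner command (string, used via [mafft_aligner()]) or
#'   `"identity"` for pre-aligned/indel-free input.
#' @param universe Evaluation universe: `"surface"` (scored surface
#'   residues) or `"all"`.
#' @param radius Functional-region radius (Angstrom).
#' @param min_identity Query/structure identity floor for mapping.
#' @return A `run_config` list.
#' @export
run_config <- function(X_grid = seq(85, 10, by = -5),
                       D_grid = seq(5, 9, by = 0.5),
                       min_sequences = 10, max_separation = 3,
                       n_perm = 10000, alpha_fraction = 0.05, seed = 1L,
                       shell_spacing = 3, shell_clash = 2.5,
                       shell_margin = 8, jitter = 1e-4,
                       aligner = "mafft", universe = "surface", radius = 9,
                       min_identity = 0.95) {
  cfg <- list(
    X_grid = as.numeric(X_grid), D_grid = as.numeric(D_grid),
    min_sequences = as.integer(min_sequences),
    max_separation = as.integer(max_separation),
    n_perm = as.integer(n_perm), alpha_fraction = as.numeric(alpha_fraction),
    seed = as.integer(seed), shell_spacing = as.numeric(shell_spacing),
    shell_clash = as.numeric(shell_clash),
    shell_margin = as.numeric(shell_margin), jitter = as.numeric(jitter),
    aligner = aligner, universe = match.arg(universe, c("surface", "all")),
    radius = as.numeric(radius), min_identity = as.numeric(min_identity)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as JSON
#'
#' The write/read round trip is the identity.
#'
#' @param cfg A [run_config()].
#' @param path JSON file path.
#' @return `write_run_config()` the path invisibly; `read_run_config()` a
#'   `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

config_aligner <- function(cfg) {
  if (identical(cfg$aligner, "identity")) identity_aligner()
  else mafft_aligner(cfg$aligner)
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small deterministic fingerprint (djb2) for log lines
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}
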