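#' Run the sequence-selection stage end to end
#'
#' Reads a structure chain and a query-plus-hits sequence bundle, builds
#' the surface contact graph, sweeps the (X, D) grid and adopts the
#' maximum-DSPAC homolog set. Artifacts written to `out_dir`: the DSPAC
#' grid (`dspac_grid.tsv`), the adopted-set FASTA (`adopted.fasta`), the
#' Moran scatter of the adopted cell (`moran_scatter.tsv`) and a summary
#' JSON (`selection.json`).
#'
#' @param pdb Path to (or text of) the PDB file.
#' @param chain Chain id.
#' @param query_fasta,hits_fasta FASTA paths (query: single sequence).
#' @param config A [run_config()].
#' @param out_dir Output directory (created); `NULL` skips artifacts.
#' @param master_aln Optional precomputed master alignment.
#' @return The `dspac_selection`, invisibly carrying `graph` and `config`
#'   as attributes.
#' @export
run_select <- function(pdb, chain, query_fasta, hits_fasta, config = run_config(),
                       out_dir = NULL, master_aln = NULL) {
  query <- read_fasta_tbl(query_fasta)[1, , drop = FALSE]
  hits <- read_fasta_tbl(hits_fasta)
  hits <- filter_hits(query$seq, hits)
  seqs <- dplyr::bind_rows(query, hits)
  graph <- build_graph(pdb, chain, config)
  sel <- select_homologs(
    seqs, query$id, graph, aligner = config_aligner(config),
    X_grid = config$X_grid, D_grid = config$D_grid,
    min_sequences = config$min_sequences,
    max_separation = config$max_separation, master_aln = master_aln,
    min_identity = config$min_identity)
  attr(sel, "graph") <- graph
  attr(sel, "config") <- config
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(sel$grid, file.path(out_dir, "dspac_grid.tsv"))
    mem <- seqs[seqs$id %in% sel$adopted$members, , drop = FALSE]
    writeLines(paste0(">", mem$id, "\n", mem$seq),
               file.path(out_dir, "adopted.fasta"))
    readr::write_tsv(sel$adopted$scores, file.path(out_dir, "scores.tsv"))
    fit <- dspac(sel$adopted$scores, graph, sel$adopted$D,
                 config$max_separation)
    readr::write_tsv(fit$scatter, file.path(out_dir, "moran_scatter.tsv"))
    summary <- list(
      adopted_X = sel$adopted$X, adopted_D = sel$adopted$D,
      dspac = sel$adopted$dspac, n_points = sel$adopted$n_points,
      p_value = sel$adopted$p_value,
      n_members = length(sel$adopted$members),
      members = sel$adopted$members,
      config_hash = config_hash(config), seed = config$seed)
    jsonlite::write_json(summary, file.path(out_dir, "selection.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_artifact(out_dir, "selection.json", config)
  }
  invisible(sel)
}

#' Run the cluster-detection stage end to end
#'
#' From a structure chain and an aligned FASTA containing the query,
#' computes the conservation profile, runs the LMIC Monte Carlo test at
#' the given neighbor threshold and predicts the functional residues; when
#' a catalytic TSV is supplied the prediction is scored against the
#' 9-Angstrom functional region. Artifacts: `prediction.tsv` (per-residue
#' statistics and flags) and, with truth, `metrics.json`.
#'
#' @inheritParams run_select
#' @param msa Aligned FASTA path (query row first or named `query`).
#' @param D Neighboring residue threshold (Angstrom).
#' @param catalytic Optional catalytic TSV path.
#' @param query_id Query row id (default: first row).
#' @return A list: `mc` (the `lmic_mc` tibble), `predicted` tibble,
#'   `metrics` (or `NULL`), `graph`.
#' @export
run_predict <- function(pdb, chain, msa, D, config = run_config(),
                        catalytic = NULL, out_dir = NULL, query_id = NULL) {
  aln <- read_alignment(msa, query_id = query_id)
  graph <- build_graph(pdb, chain, config)
  prof <- conservation_profile(aln)
  scores <- map_conservation(prof, aln, graph, config$min_identity)
  ctx <- nbr_context(graph)
  mc <- lmic_mc_test(scores, graph, D, config$max_separation,
                     n_perm = config$n_perm,
                     alpha_fraction = config$alpha_fraction,
                     seed = config$seed, ctx = ctx)
  predicted <- predict_regions(mc, graph, D, config$max_separation)
  metrics <- NULL
  if (!is.null(catalytic)) {
    truth <- functional_region(read_catalytic(catalytic), graph,
                               config$radius)
    universe <- if (config$universe == "surface") mc$node_id
                else graph$nodes$node_id
    metrics <- prediction_metrics(intersect(predicted$node_id, universe),
                                  truth, universe)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- dplyr::mutate(
      mc,
      predicted = .data$node_id %in% .env$predicted$node_id,
      provenance = .env$predicted$provenance[
        match(.data$node_id, .env$predicted$node_id)])
    readr::write_tsv(tab, file.path(out_dir, "prediction.tsv"))
    if (!is.null(metrics))
      jsonlite::write_json(as.list(metrics),
                           file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_artifact(out_dir, "prediction.tsv", config)
  }
  list(mc = mc, predicted = predicted, metrics = metrics, graph = graph)
}

build_graph <- function(pdb, chain, config) {
  nodes <- read_structure(pdb, chain)
  shell <- solvent_shell(nodes, config$shell_spacing, config$shell_clash,
                         config$shell_margin)
  contact_graph(nodes, shell, jitter = config$jitter)
}

read_fasta_tbl <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  tibble::tibble(id = sub("\\s.*$", "", names(ss)),
                 seq = toupper(as.character(ss)))
}

log_artifact <- function(out_dir, file, config) {
  line <- sprintf("[%s] wrote %s config=%s seed=%d",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), file,
                  config_hash(config), config$seed)
  cat(line, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
  invisible(line)
}
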