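# Small fixture builders used across test files.

pdb_atom_line <- function(serial, atom, res, chain, resno, x, y, z,
                          record = "ATOM", alt = " ", icode = " ") {
  sprintf("%-6s%5d %s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, sprintf("%-4s", substr(paste0(" ", atom), 1, 4)),
          alt, res, chain, resno, icode, x, y, z, 1, 0,
          substr(atom, 1, 1))
}

# a 3-residue chain (GLY, ALA, TRP) with N/CA/CB records where applicable
three_res_pdb <- function(extra_lines = character()) {
  l <- c(
    pdb_atom_line(1, "N",  "GLY", "A", 1, 0.0, 0.0, 0.0),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 1.0, 0.0, 0.0),
    pdb_atom_line(3, "N",  "ALA", "A", 2, 4.0, 0.0, 0.0),
    pdb_atom_line(4, "CA", "ALA", "A", 2, 5.0, 0.0, 0.0),
    pdb_atom_line(5, "CB", "ALA", "A", 2, 5.5, 1.2, 0.0),
    pdb_atom_line(6, "N",  "TRP", "A", 3, 8.0, 0.0, 0.0),
    pdb_atom_line(7, "CA", "TRP", "A", 3, 9.0, 0.0, 0.0),
    pdb_atom_line(8, "CB", "TRP", "A", 3, 9.5, 1.2, 0.0),
    extra_lines,
    "END")
  paste(l, collapse = "\n")
}

# contact graph with explicit nodes/edges, every node surface
manual_graph <- function(coords, edges_idx, ids = NULL) {
  co <- as.matrix(coords)
  n <- nrow(co)
  if (is.null(ids)) ids <- paste0("A", seq_len(n))
  g <- list(
    nodes = tibble::tibble(
      node_id = ids, chain = "A", resnum = seq_len(n), icode = "",
      aa = "ALA", x = co[, 1], y = co[, 2], z = co[, 3],
      rep_atom = "CB", cb_fallback = FALSE, label = "surface"),
    edges = tibble::tibble(from = ids[edges_idx[, 1]],
                           to = ids[edges_idx[, 2]])
  )
  class(g) <- "contact_graph"
  g
}

# linear path graph along the x axis at 1 A spacing
path_graph <- function(n) {
  co <- cbind(seq_len(n) - 1, 0, 0)
  manual_graph(co, cbind(seq_len(n - 1), 2:n))
}

scores_tbl <- function(graph, cons) {
  tibble::tibble(node_id = graph$nodes$node_id, site = seq_along(cons),
                 cons = cons)
}

aln_from_strings <- function(seqs, ids = NULL, query = NULL) {
  if (is.null(ids)) {
    ids <- if (length(seqs) == 1L) "query"
           else c("query", paste0("s", 2:length(seqs)))
  }
  new_alignment(tibble::tibble(id = ids, seq = seqs),
                query_id = if (is.null(query)) ids[1] else query)
}

# random geometric graph on a cube, all-surface, used for null calibration
rgg_graph <- function(n, side = 30, cutoff = 6, seed = 1) {
  co <- dspacr:::withr_seed(seed, matrix(stats::runif(3 * n, 0, side), ncol = 3))
  geometric_graph(co, cutoff)
}
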