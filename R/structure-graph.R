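#' Read the residue nodes of one protein chain
#'
#' Parses the ATOM records of a PDB file (via [bio3d::read.pdb()]) and
#' returns one node per residue, located at its representative atom: the
#' C-beta, except for glycine where the C-alpha is used. HETATM records
#' (waters, ligands) are ignored, only the first MODEL is read, and for
#' alternate locations the first-listed one is kept. A non-glycine residue
#' missing its C-beta falls back to the C-alpha (recorded in `cb_fallback`);
#' residues with neither atom are dropped with a warning.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB-format lines
#'   (anything containing a newline, or of length > 1, is treated as text).
#' @param chain Chain identifier to extract.
#' @return A tibble with one row per residue: `node_id`, `chain`, `resnum`,
#'   `icode`, `aa` (3-letter code), `x`, `y`, `z`, `rep_atom` ("CB" or
#'   "CA") and `cb_fallback`.
#' @examples
#' pdb <- toy_structure("sphere", n = 30, patch_size = 4, seed = 1)$pdb_text
#' read_structure(pdb, chain = "A")
#' @export
read_structure <- function(pdb, chain) {
  stopifnot(is.character(pdb), length(chain) == 1L)
  if (length(pdb) > 1L || grepl("\n", pdb[1], fixed = TRUE)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), path)
  } else {
    path <- pdb
  }
  pdbobj <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdbobj$atom
  at <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain not found: ", chain)
  # first-listed altloc wins
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  key <- paste(at$resno, at$insert, at$elety)
  at <- at[!duplicated(key), , drop = FALSE]

  rid <- paste(at$resno, at$insert, sep = "|")
  nodes <- purrr::map_dfr(split(at, factor(rid, levels = unique(rid))),
    function(res) {
      cb <- res[res$elety == "CB", , drop = FALSE]
      ca <- res[res$elety == "CA", , drop = FALSE]
      aa <- res$resid[1]
      use_cb <- nrow(cb) == 1L && !identical(aa, "GLY")
      fallback <- FALSE
      if (use_cb) {
        atom <- cb
      } else if (nrow(ca) >= 1L) {
        atom <- ca[1, , drop = FALSE]
        fallback <- !identical(aa, "GLY")
      } else {
        return(NULL)
      }
      tibble::tibble(
        chain = atom$chain, resnum = res$resno[1], icode = res$insert[1],
        aa = aa, x = atom$x, y = atom$y, z = atom$z,
        rep_atom = if (use_cb) "CB" else "CA", cb_fallback = fallback
      )
    })
  n_res <- length(unique(rid))
  if (nrow(nodes) < n_res) {
    warning(n_res - nrow(nodes),
            " residue(s) dropped: no CA or CB atom present")
  }
  if (nrow(nodes) == 0L) stop("empty chain: no residue with a usable atom")
  nodes <- tibble::as_tibble(nodes)
  nodes$node_id <- paste0(nodes$chain, nodes$resnum, nodes$icode)
  dplyr::select(nodes, "node_id", dplyr::everything())
}

#' Build a deterministic solvent shell around a structure
#'
#' Stand-in for the scattered-water step of a protein Voronoi tessellation:
#' points of a regular cubic grid filling the node bounding box expanded by
#' `margin`, with points closer than `clash` to any residue node removed.
#' A residue whose Voronoi cell touches one of these points is a surface
#' residue.
#'
#' @param nodes Residue node tibble from [read_structure()].
#' @param spacing Grid spacing in Angstrom.
#' @param clash Minimum allowed distance from a grid point to any node.
#' @param margin Bounding-box expansion in Angstrom.
#' @return A tibble of shell points (`x`, `y`, `z`) with the parameters
#'   stored as attributes.
#' @export
solvent_shell <- function(nodes, spacing = 3, clash = 2.5, margin = 8) {
  if (nrow(nodes) == 0L) stop("empty structure")
  stopifnot(spacing > 0, clash > 0, margin > 0)
  co <- as.matrix(nodes[, c("x", "y", "z")])
  lo <- apply(co, 2, min) - margin
  hi <- apply(co, 2, max) + margin
  # cell-centered grid: point count scales as spacing^-3
  grid <- expand.grid(
    x = seq(lo[1] + spacing / 2, hi[1], by = spacing),
    y = seq(lo[2] + spacing / 2, hi[2], by = spacing),
    z = seq(lo[3] + spacing / 2, hi[3], by = spacing)
  )
  gm <- as.matrix(grid)
  # min distance to any node, blockwise to bound memory
  keep <- vapply(seq_len(nrow(gm)), function(i) {
    d2 <- (co[, 1] - gm[i, 1])^2 + (co[, 2] - gm[i, 2])^2 +
      (co[, 3] - gm[i, 3])^2
    min(d2) >= clash^2
  }, logical(1))
  out <- tibble::as_tibble(grid[keep, , drop = FALSE])
  attr(out, "spacing") <- spacing
  attr(out, "clash") <- clash
  attr(out, "margin") <- margin
  out
}

#' Residue contact graph from a Voronoi tessellation
#'
#' Tessellates the joint point set (residue representative atoms, solvent
#' shell, optionally points of another chain) and defines two residues as
#' contacting when their Voronoi cells share a facet, i.e. when the pair is
#' an edge of the Delaunay tetrahedralization. A residue adjacent to at
#' least one shell point is labeled `surface`; adjacent to a point of the
#' other chain, `interface`; otherwise `inner`. A fixed-seed jitter breaks
#' the exact degeneracies of grid-based shells.
#'
#' @param nodes Residue node tibble from [read_structure()].
#' @param shell Solvent shell from [solvent_shell()]; built with defaults
#'   when `NULL`.
#' @param other_points Optional matrix/tibble of x, y, z points belonging to
#'   another molecule.
#' @param jitter Amplitude (Angstrom) of the degeneracy-breaking jitter.
#' @param jitter_seed Seed of the jitter (does not disturb the caller's RNG).
#' @return A `contact_graph`: list with `nodes` (node tibble plus `label`)
#'   and `edges` (tibble of `from`, `to` node ids, both orientations
#'   implied, stored once with `from < to`).
#' @export
contact_graph <- function(nodes, shell = NULL, other_points = NULL,
                          jitter = 1e-4, jitter_seed = 1L) {
  if (is.null(shell)) shell <- solvent_shell(nodes)
  co <- as.matrix(nodes[, c("x", "y", "z")])
  sh <- as.matrix(shell[, c("x", "y", "z")])
  op <- if (!is.null(other_points)) {
    m <- as.matrix(as.data.frame(other_points))
    colnames(m) <- NULL
    m[, 1:3, drop = FALSE]
  } else {
    matrix(numeric(0), ncol = 3)
  }
  if (nrow(op) > 0L && nrow(sh) > 0L) {
    # the other molecule displaces solvent too
    clash <- attr(shell, "clash") %||% 2.5
    keep <- vapply(seq_len(nrow(sh)), function(i) {
      min((op[, 1] - sh[i, 1])^2 + (op[, 2] - sh[i, 2])^2 +
            (op[, 3] - sh[i, 3])^2) >= clash^2
    }, logical(1))
    sh <- sh[keep, , drop = FALSE]
  }
  pts <- rbind(co, sh, op)
  if (nrow(pts) < 5L) stop("tessellation failed: fewer than 5 points")
  cls <- rep(c(0L, 1L, 2L), c(nrow(co), nrow(sh), nrow(op)))
  jit <- withr_seed(jitter_seed, {
    matrix(stats::runif(length(pts), -jitter, jitter), nrow = nrow(pts))
  })
  edges <- .delaunay_edges_cpp(pts + jit)

  n_res <- nrow(co)
  a <- edges[, 1]; b <- edges[, 2]
  res_edge <- a <= n_res & b <= n_res
  touches_shell <- tabulate(c(a[cls[b] == 1L], b[cls[a] == 1L]),
                            nbins = n_res) > 0
  touches_other <- tabulate(c(a[cls[b] == 2L], b[cls[a] == 2L]),
                            nbins = n_res) > 0
  label <- ifelse(touches_shell, "surface",
                  ifelse(touches_other, "interface", "inner"))

  nodes$label <- label
  g <- list(
    nodes = nodes,
    edges = tibble::tibble(from = nodes$node_id[a[res_edge]],
                           to = nodes$node_id[b[res_edge]])
  )
  class(g) <- "contact_graph"
  attr(g, "jitter") <- jitter
  attr(g, "jitter_seed") <- jitter_seed
  g
}

#' Build a contact graph directly from coordinates and an edge rule
#'
#' Tessellation-free constructor used for simulation studies: every node is
#' labeled `surface` and two nodes are connected when their Euclidean
#' distance is at most `cutoff`. Useful to study the spatial statistics on
#' random geometric graphs without a structure file.
#'
#' @param coords Matrix or tibble of x, y, z coordinates (one row per node).
#' @param cutoff Connection distance in Angstrom.
#' @param ids Optional node ids (default `n1 ... nN`).
#' @return A `contact_graph`.
#' @export
geometric_graph <- function(coords, cutoff, ids = NULL) {
  co <- as.matrix(as.data.frame(coords))[, 1:3, drop = FALSE]
  n <- nrow(co)
  if (is.null(ids)) ids <- paste0("n", seq_len(n))
  d <- as.matrix(stats::dist(co))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  g <- list(
    nodes = tibble::tibble(node_id = ids, chain = "A", resnum = seq_len(n),
                           icode = "", aa = "ALA", x = co[, 1], y = co[, 2],
                           z = co[, 3], rep_atom = "CB", cb_fallback = FALSE,
                           label = "surface"),
    edges = tibble::tibble(from = ids[idx[, 1]], to = ids[idx[, 2]])
  )
  class(g) <- "contact_graph"
  g
}

#' @export
print.contact_graph <- function(x, ...) {
  cat("<contact_graph> ", nrow(x$nodes), " residues, ",
      nrow(x$edges), " contacts; ",
      sum(x$nodes$label == "surface"), " surface / ",
      sum(x$nodes$label == "inner"), " inner / ",
      sum(x$nodes$label == "interface"), " interface\n", sep = "")
  invisible(x)
}

#' @export
tidy.contact_graph <- function(x, ...) x$nodes

#' Neighborhood of a surface residue
#'
#' The neighbors of surface residue `i` are the other surface residues that
#' are both within `D` Angstrom of its representative atom and within
#' `max_separation` steps on the surface-induced contact graph — the path
#' bound removes residues close in space but distant along the molecular
#' surface.
#'
#' @param graph A `contact_graph`.
#' @param node_id Focal surface residue id.
#' @param D Distance threshold in Angstrom.
#' @param max_separation Maximum separation degree (path length).
#' @return Character vector of neighbor node ids.
#' @export
graph_neighborhood <- function(graph, node_id, D, max_separation = 3) {
  ctx <- nbr_context(graph)
  if (!node_id %in% ctx$ids) stop("non-surface focal residue: ", node_id)
  nb <- neighbor_sets(ctx, D, max_separation)
  nb[[match(node_id, ctx$ids)]]
}

# Precompute, for the surface-induced subgraph, the Euclidean distance and
# separation-degree matrices. Cached on the graph environment-free way:
# recomputed per call site; selection/statistics compute it once and reuse.
nbr_context <- function(graph) {
  surf <- graph$nodes[graph$nodes$label == "surface", , drop = FALSE]
  ids <- surf$node_id
  co <- as.matrix(surf[, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(co))
  e <- graph$edges
  keep <- e$from %in% ids & e$to %in% ids
  ig <- igraph::graph_from_data_frame(e[keep, , drop = FALSE],
                                      directed = FALSE,
                                      vertices = data.frame(name = ids))
  sep <- igraph::distances(ig)
  sep <- sep[ids, ids, drop = FALSE]
  list(ids = ids, dmat = dmat, sep = sep)
}

# Adjacency lists under a (D, max_separation) rule, as id character vectors.
neighbor_sets <- function(ctx, D, max_separation = 3) {
  ok <- ctx$dmat <= D & ctx$sep <= max_separation
  diag(ok) <- FALSE
  lapply(seq_along(ctx$ids), function(i) ctx$ids[ok[i, ]])
}

#' Write / read a contact graph as plain TSV tables
#'
#' @param graph A `contact_graph`.
#' @param dir Output directory; writes `nodes.tsv` and `edges.tsv`.
#' @return `write_contact_graph()` returns the directory invisibly;
#'   `read_contact_graph()` returns a `contact_graph`.
#' @export
write_contact_graph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(graph$nodes, file.path(dir, "nodes.tsv"))
  readr::write_tsv(graph$edges, file.path(dir, "edges.tsv"))
  invisible(dir)
}

#' @rdname write_contact_graph
#' @export
read_contact_graph <- function(dir) {
  g <- list(
    nodes = readr::read_tsv(file.path(dir, "nodes.tsv"),
                            col_types = readr::cols(
                              icode = readr::col_character())),
    edges = readr::read_tsv(file.path(dir, "edges.tsv"),
                            col_types = readr::cols())
  )
  g$nodes$icode[is.na(g$nodes$icode)] <- ""
  class(g) <- "contact_graph"
  g
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
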