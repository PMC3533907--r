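#' Predicted functional residues from significant LMIC residues
#'
#' Each significant residue seeds a predicted region consisting of itself
#' and its neighborhood under the same (D, separation) rule used by the
#' statistics; the prediction is the union over seeds, with provenance
#' recording whether a residue entered as a seed or as a neighbor.
#'
#' @param mc `lmic_mc` result from [lmic_mc_test()].
#' @param graph `contact_graph`.
#' @param D Neighboring residue threshold in Angstrom.
#' @param max_separation Separation degree bound.
#' @return A tibble `node_id`, `provenance` ("seed" or "neighbor").
#' @export
predict_regions <- function(mc, graph, D, max_separation = 3) {
  ctx <- nbr_context(graph)
  sig <- mc$node_id[mc$significant]
  if (length(sig) == 0L)
    return(tibble::tibble(node_id = character(), provenance = character()))
  nb <- neighbor_sets(ctx, D, max_separation)
  nbrs <- unique(unlist(nb[match(sig, ctx$ids)]))
  # restrict neighbors to scored residues so predictions live in the
  # evaluation universe
  nbrs <- intersect(nbrs, mc$node_id)
  tibble::tibble(
    node_id = c(sig, setdiff(nbrs, sig)),
    provenance = c(rep("seed", length(sig)),
                   rep("neighbor", length(setdiff(nbrs, sig))))
  )
}

#' Read a catalytic-residue list
#'
#' Plain TSV with columns `chain`, `resnum` and optional `icode`.
#'
#' @param path TSV file path.
#' @return Character vector of node ids (`chain` `resnum` `icode` pasted).
#' @export
read_catalytic <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chain = readr::col_character(), resnum = readr::col_integer(),
    .default = readr::col_character()))
  icode <- if ("icode" %in% names(tab)) tab$icode else ""
  icode[is.na(icode)] <- ""
  paste0(tab$chain, tab$resnum, icode)
}

#' Functional region derived from catalytic residues
#'
#' The truth definition used for evaluation: the catalytic residues plus
#' every residue whose representative atom lies within `radius` Angstrom of
#' the geometric center of the catalytic residues.
#'
#' @param catalytic Character vector of catalytic node ids.
#' @param graph `contact_graph`.
#' @param radius Sphere radius in Angstrom (default 9).
#' @return A list: `catalytic`, `region` (node id set), `center`, `radius`.
#' @export
functional_region <- function(catalytic, graph, radius = 9) {
  if (length(catalytic) == 0L) stop("no catalytic residues")
  nodes <- graph$nodes
  miss <- setdiff(catalytic, nodes$node_id)
  if (length(miss) > 0L)
    stop("catalytic residue not in structure: ", paste(miss, collapse = ", "))
  co <- as.matrix(nodes[, c("x", "y", "z")])
  center <- colMeans(co[match(catalytic, nodes$node_id), , drop = FALSE])
  d <- sqrt(rowSums(sweep(co, 2, center)^2))
  region <- union(catalytic, nodes$node_id[d <= radius])
  list(catalytic = catalytic, region = region, center = center,
       radius = radius)
}

#' Confusion-matrix metrics of a functional-region prediction
#'
#' Counts over the evaluation universe with positives = actual region
#' intersected with the universe. Sensitivity = TP/(TP+FN), specificity =
#' TP/(TP+FP) (precision), selectivity = TN/(TN+FP), F = harmonic mean of
#' sensitivity and specificity. Any 0/0 ratio is reported as 0, except
#' selectivity with TN+FP = 0, reported as 1.
#'
#' @param predicted Character vector of predicted node ids (must lie in
#'   `universe`).
#' @param actual Functional region from [functional_region()] (or a plain
#'   id vector).
#' @param universe Character vector of node ids to count over (typically
#'   the scored surface residues).
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `selectivity`, `f_score`.
#' @export
prediction_metrics <- function(predicted, actual, universe) {
  if (is.list(actual)) actual <- actual$region
  if (length(setdiff(predicted, universe)) > 0L)
    stop("prediction outside universe")
  pos <- intersect(actual, universe)
  tp <- length(intersect(predicted, pos))
  fp <- length(setdiff(predicted, pos))
  fn <- length(setdiff(pos, predicted))
  tn <- length(universe) - tp - fp - fn
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tp + fp > 0) tp / (tp + fp) else 0
  sel <- if (tn + fp > 0) tn / (tn + fp) else 1
  f <- if (sens + spec > 0) 2 * sens * spec / (sens + spec) else 0
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn, sensitivity = sens,
                 specificity = spec, selectivity = sel, f_score = f)
}
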