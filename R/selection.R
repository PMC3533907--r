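#' Length-filter BLAST hits against the query
#'
#' Keeps the hits whose length lies between 80\% and 150\% of the query
#' length (boundaries inclusive), preserving the input order.
#'
#' @param query Query sequence (single string) or a one-row tibble with a
#'   `seq` column.
#' @param hits Tibble with columns `id`, `seq`.
#' @return The filtered hits tibble.
#' @export
filter_hits <- function(query, hits) {
  qlen <- nchar(if (is.character(query)) query else query$seq)
  stopifnot(qlen > 0)
  len <- nchar(hits$seq)
  hits[len >= 0.8 * qlen & len <= 1.5 * qlen, , drop = FALSE]
}

#' Percent identity of an alignment row to the query
#'
#' Computed on the pairwise projection of the master alignment:
#' `100 * matches / columns where at least one of the pair is non-gap`.
#'
#' @param aln Alignment tibble.
#' @param seq_id Row to compare against the query row.
#' @return Percent identity in \[0, 100\].
#' @export
percent_identity <- function(aln, seq_id) {
  m <- aln_matrix(aln)
  q <- m[query_of(aln), ]
  s <- m[seq_id, ]
  comparable <- q != "-" | s != "-"
  if (!any(comparable)) stop("no overlap between query and ", seq_id)
  100 * sum(q == s & q != "-" & comparable) / sum(comparable)
}

#' Nested candidate homolog sets over the identity-threshold grid
#'
#' One candidate per threshold `X`: the hits with percent identity to the
#' query at least `X`, plus the query itself. Candidates are nested (a
#' smaller threshold contains every larger-threshold set) and a candidate
#' is eligible when it holds at least `min_sequences` members including the
#' query.
#'
#' @param master_aln Master alignment of query plus all retained hits.
#' @param X_grid Identity thresholds in percent (default 85 down to 10 by
#'   5, i.e. 16 conditions).
#' @param min_sequences Eligibility floor (default 10; exactly 10 is
#'   eligible).
#' @return A tibble `X`, `members` (list column of ids, query included),
#'   `n_members`, `eligible`, with per-hit identities in attribute
#'   `identities`.
#' @export
candidate_sets <- function(master_aln, X_grid = seq(85, 10, by = -5),
                           min_sequences = 10) {
  qid <- query_of(master_aln)
  hit_ids <- setdiff(master_aln$id, qid)
  pid <- vapply(hit_ids, function(id) percent_identity(master_aln, id),
                numeric(1))
  out <- tibble::tibble(
    X = X_grid,
    members = lapply(X_grid, function(x) c(qid, hit_ids[pid >= x]))
  )
  out$n_members <- lengths(out$members)
  out$eligible <- out$n_members >= min_sequences
  attr(out, "identities") <- tibble::tibble(id = hit_ids, identity = pid)
  out
}

#' Aligner hooks
#'
#' An aligner is a function taking a tibble of sequences (`id`, `seq`,
#' ungapped) and a query id, returning an alignment tibble.
#' `mafft_aligner()` shells out to an external `mafft` binary;
#' `identity_aligner()` returns the sequences as-is and requires them to
#' share one length (exact for simulated indel-free families).
#'
#' @param command Aligner executable.
#' @param args Extra command-line arguments.
#' @return A function `(seqs, query_id) -> alignment tibble`.
#' @export
mafft_aligner <- function(command = "mafft", args = c("--auto", "--quiet")) {
  force(command); force(args)
  function(seqs, query_id) {
    fin <- tempfile(fileext = ".fasta")
    fout <- tempfile(fileext = ".fasta")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    writeLines(paste0(">", seqs$id, "\n", seqs$seq), fin)
    status <- system2(command, c(args, shQuote(fin)), stdout = fout)
    if (!identical(status, 0L)) stop("aligner failed: ", command)
    read_alignment(fout, query_id = query_id)
  }
}

#' @rdname mafft_aligner
#' @export
identity_aligner <- function() {
  function(seqs, query_id) {
    if (length(unique(nchar(seqs$seq))) != 1L)
      stop("identity aligner requires equal-length sequences")
    new_alignment(seqs, query_id)
  }
}

#' Adopt the homolog set and neighbor threshold maximizing DSPAC
#'
#' For every eligible candidate set the members are (re)aligned with the
#' injected aligner, the conservation profile is computed and mapped onto
#' the structure, and DSPAC is evaluated at every neighbor threshold `D`.
#' The `(X, D)` cell with maximal DSPAC over eligible, non-degenerate cells
#' is adopted; ties break toward larger `X`, then smaller `D`.
#'
#' @param seqs Tibble of ungapped sequences (`id`, `seq`) containing the
#'   query and all retained hits.
#' @param query_id Id of the query sequence.
#' @param graph `contact_graph` of the target chain.
#' @param aligner Aligner hook; see [mafft_aligner()].
#' @param X_grid,min_sequences Passed to [candidate_sets()].
#' @param D_grid Neighbor thresholds in Angstrom (default 5.0 to 9.0 by
#'   0.5).
#' @param max_separation Separation degree bound.
#' @param master_aln Optional precomputed master alignment (skips the
#'   initial alignment of all sequences).
#' @param min_identity Identity floor for structure mapping.
#' @return A `dspac_selection`: list with `grid` (X, D, dspac, slope,
#'   n_points, p_value, eligible, degenerate), `candidates`, `adopted`
#'   (list: X, D, dspac, members, alignment, scores) or `NULL` rows when no
#'   candidate is eligible.
#' @export
select_homologs <- function(seqs, query_id, graph,
                            aligner = mafft_aligner(),
                            X_grid = seq(85, 10, by = -5),
                            D_grid = seq(5, 9, by = 0.5),
                            min_sequences = 10, max_separation = 3,
                            master_aln = NULL, min_identity = 0.95) {
  stopifnot(query_id %in% seqs$id)
  master_aln <- master_aln %||% aligner(seqs, query_id)
  cands <- candidate_sets(master_aln, X_grid, min_sequences)
  if (!any(cands$eligible))
    stop("no candidate with >= ", min_sequences, " sequences")
  ctx <- nbr_context(graph)

  per_cand <- vector("list", nrow(cands))
  grid <- list()
  for (ci in seq_len(nrow(cands))) {
    if (!cands$eligible[ci]) {
      grid[[ci]] <- tibble::tibble(
        X = cands$X[ci], D = D_grid, dspac = NA_real_, slope = NA_real_,
        n_points = NA_integer_, p_value = NA_real_, eligible = FALSE,
        degenerate = NA)
      next
    }
    members <- cands$members[[ci]]
    sub <- seqs[seqs$id %in% members, , drop = FALSE]
    # identical membership to the previous eligible candidate: reuse
    prev <- if (ci > 1) per_cand[[ci - 1]] else NULL
    if (!is.null(prev) && setequal(prev$members, members)) {
      pc <- prev
    } else {
      aln <- aligner(sub, query_id)
      prof <- conservation_profile(aln)
      sc <- map_conservation(prof, aln, graph, min_identity)
      pc <- list(members = members, aln = aln, scores = sc)
    }
    per_cand[[ci]] <- pc
    fits <- lapply(D_grid, function(D)
      glance(dspac(pc$scores, graph, D, max_separation, ctx = ctx)))
    grid[[ci]] <- dplyr::bind_rows(fits) |>
      dplyr::mutate(X = cands$X[ci], eligible = TRUE) |>
      dplyr::select("X", "D", "dspac", "slope", "n_points", "p_value",
                    "eligible", "degenerate")
  }
  grid <- dplyr::bind_rows(grid)

  pool <- grid[grid$eligible & !is.na(grid$dspac), , drop = FALSE]
  if (nrow(pool) == 0L) stop("all eligible candidates are degenerate")
  best <- pool[order(-pool$dspac, -pool$X, pool$D), , drop = FALSE][1, ]
  ci <- match(best$X, cands$X)
  adopted <- list(
    X = best$X, D = best$D, dspac = best$dspac, n_points = best$n_points,
    p_value = best$p_value, members = per_cand[[ci]]$members,
    alignment = per_cand[[ci]]$aln, scores = per_cand[[ci]]$scores
  )
  res <- list(grid = grid, candidates = cands, adopted = adopted)
  class(res) <- "dspac_selection"
  res
}

#' @export
print.dspac_selection <- function(x, ...) {
  cat("<dspac_selection> adopted X = ", x$adopted$X, "%, D = ",
      x$adopted$D, " A, DSPAC = ", format(x$adopted$dspac, digits = 4),
      ", ", length(x$adopted$members), " sequences\n", sep = "")
  invisible(x)
}

#' @export
tidy.dspac_selection <- function(x, ...) x$grid

#' @export
glance.dspac_selection <- function(x, ...) {
  tibble::tibble(adopted_X = x$adopted$X, adopted_D = x$adopted$D,
                 dspac = x$adopted$dspac, n_points = x$adopted$n_points,
                 p_value = x$adopted$p_value,
                 n_members = length(x$adopted$members))
}
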