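#' Read an aligned FASTA file into an alignment tibble
#'
#' @param path Aligned FASTA file (gap character `-`).
#' @param query_id Identifier of the query row (defaults to the first
#'   sequence).
#' @return A tibble with columns `id` and `seq` (upper-case, gapped), with
#'   the query id stored in attribute `query_id`.
#' @export
read_alignment <- function(path, query_id = NULL) {
  ss <- Biostrings::readAAStringSet(path)
  aln <- tibble::tibble(id = names(ss), seq = toupper(as.character(ss)))
  new_alignment(aln, query_id %||% aln$id[1])
}

#' Construct an alignment tibble from sequences
#'
#' @param aln A data frame with columns `id` and `seq` (equal-length,
#'   gapped, upper-case amino-acid strings).
#' @param query_id Identifier of the query row.
#' @return The alignment tibble with attribute `query_id`.
#' @export
new_alignment <- function(aln, query_id) {
  aln <- tibble::as_tibble(aln[, c("id", "seq")])
  aln$seq <- toupper(aln$seq)
  if (length(unique(nchar(aln$seq))) != 1L)
    stop("alignment rows have unequal lengths")
  if (!query_id %in% aln$id) stop("query_id not among alignment rows")
  attr(aln, "query_id") <- query_id
  aln
}

query_of <- function(aln) attr(aln, "query_id")

# alignment as a character matrix (rows = sequences), nonstandard -> '-'
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(m) <- aln$id
  m[!m %in% AA20] <- "-"
  m
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

#' The normalized BLOSUM62 substitution table
#'
#' Loads BLOSUM62 (from Biostrings) restricted to the 20 standard residues
#' and records its maximum and minimum, used to min-max normalize pair
#' scores into \[0, 1\].
#'
#' @return A list with the integer `matrix`, `max_m` and `min_m`.
#' @export
substitution_table <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA20, AA20]
  list(matrix = m, max_m = max(m), min_m = min(m))
}

#' Normalized substitution score of a residue pair
#'
#' `(m(a, b) - min(m)) / (max(m) - min(m))` when both letters are standard
#' residues; 0 when either is a gap or a nonstandard letter. Vectorized
#' over `a` and `b`.
#'
#' @param a,b Single-letter residue codes (or `-`).
#' @param table Substitution table from [substitution_table()].
#' @return Numeric in \[0, 1\].
#' @export
mut_score <- function(a, b, table = substitution_table()) {
  out <- numeric(length(a))
  ok <- a %in% AA20 & b %in% AA20
  if (any(ok)) {
    out[ok] <- (table$matrix[cbind(a[ok], b[ok])] - table$min_m) /
      (table$max_m - table$min_m)
  }
  out
}

#' Position-based (Henikoff-Henikoff) sequence weights
#'
#' At each column a sequence contributes `1 / (r * s)` where `r` is the
#' number of distinct residue types in the column and `s` the count of the
#' sequence's own type; gap cells contribute nothing and gaps do not count
#' as a residue type. Per-sequence totals are normalized to sum to one.
#'
#' @param aln Alignment tibble.
#' @return A tibble with columns `id` and `weight` (summing to 1).
#' @export
henikoff_weights <- function(aln) {
  m <- aln_matrix(aln)
  if (nrow(m) < 2L) stop("need >=2 sequences")
  raw <- numeric(nrow(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    res <- col != "-"
    if (!any(res)) next
    tab <- table(col[res])
    r <- length(tab)
    contrib <- numeric(length(col))
    contrib[res] <- 1 / (r * as.numeric(tab[col[res]]))
    raw <- raw + contrib
  }
  if (all(raw == 0)) raw <- rep(1, nrow(m))
  tibble::tibble(id = aln$id, weight = raw / sum(raw))
}

#' Per-site conservation profile of an alignment
#'
#' The conservation of column `i` is the weighted average of normalized
#' substitution scores over all unordered sequence pairs,
#' `Cons(i) = sum_{j<k} W_j W_k Mut(s_j(i), s_k(i)) / sum_{j<k} W_j W_k`,
#' so fully gapped columns score 0 and values always lie in \[0, 1\].
#'
#' @param aln Alignment tibble.
#' @param weights Sequence weights from [henikoff_weights()] (computed when
#'   `NULL`).
#' @param table Substitution table.
#' @return A tibble with columns `site` (1-based alignment column) and
#'   `cons`, carrying the weights in attribute `weights`.
#' @export
conservation_profile <- function(aln, weights = NULL,
                                 table = substitution_table()) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need >=2 sequences")
  if (is.null(weights)) weights <- henikoff_weights(aln)
  w <- weights$weight[match(aln$id, weights$id)]
  pairs <- utils::combn(n, 2)
  ww <- w[pairs[1, ]] * w[pairs[2, ]]
  denom <- sum(ww)
  cons <- vapply(seq_len(ncol(m)), function(i) {
    sum(ww * mut_score(m[pairs[1, ], i], m[pairs[2, ], i], table)) / denom
  }, numeric(1))
  out <- tibble::tibble(site = seq_len(ncol(m)), cons = cons)
  attr(out, "weights") <- weights
  out
}

#' Map a conservation profile onto the surface residues of a structure
#'
#' Aligns the ungapped query row of the alignment to the structure's
#' residue sequence (exact match when possible, global pairwise alignment
#' fallback via Biostrings otherwise) and assigns each surface residue the
#' conservation of its matching query column. Residues without a match are
#' reported in attribute `unmapped` and excluded from spatial statistics.
#'
#' @param profile Profile from [conservation_profile()].
#' @param aln Alignment tibble (for the query row).
#' @param graph `contact_graph` of the chain.
#' @param min_identity Identity floor (fraction) below which the query is
#'   rejected as not matching the structure.
#' @return A tibble of scored surface residues: `node_id`, `site`, `cons`.
#' @export
map_conservation <- function(profile, aln, graph, min_identity = 0.95) {
  qrow <- aln$seq[aln$id == query_of(aln)]
  if (length(qrow) != 1L) stop("query row absent from alignment")
  qchars <- strsplit(qrow, "", fixed = TRUE)[[1]]
  qpos <- which(qchars != "-")            # alignment column of each query aa
  qseq <- paste(qchars[qpos], collapse = "")

  sseq <- paste(bio3d::aa321(graph$nodes$aa), collapse = "")

  if (identical(qseq, sseq)) {
    s2q <- seq_len(nchar(sseq))
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(qseq), Biostrings::AAString(sseq),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    qi <- cumsum(qa != "-")
    si <- cumsum(sa != "-")
    both <- qa != "-" & sa != "-"
    ident <- sum(qa[both] == sa[both]) / max(1L, nchar(sseq))
    if (ident < min_identity)
      stop(sprintf("query does not match structure (identity %.2f)", ident))
    s2q <- rep(NA_integer_, nchar(sseq))
    s2q[si[both]] <- qi[both]
  }

  nodes <- graph$nodes
  site <- rep(NA_integer_, nrow(nodes))
  mapped <- !is.na(s2q)
  site[which(mapped)] <- qpos[s2q[mapped]]
  scored <- tibble::tibble(node_id = nodes$node_id, site = site,
                           label = nodes$label) |>
    dplyr::filter(.data$label == "surface", !is.na(.data$site)) |>
    dplyr::left_join(profile, by = "site") |>
    dplyr::select("node_id", "site", "cons")
  unmapped <- setdiff(nodes$node_id[nodes$label == "surface"],
                      scored$node_id)
  attr(scored, "unmapped") <- unmapped
  scored
}

`%||%` <- function(a, b) if (is.null(a)) b else a
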