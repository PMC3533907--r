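#' Deterministic toy protein structures
#'
#' Generates small synthetic single-chain structures for end-to-end tests
#' and simulations:
#' * `"sphere"` — a hollow Fibonacci-lattice sphere whose nodes are all
#'   classified surface by the tessellation pipeline (solvent fills both
#'   sides of the shell);
#' * `"onion"` — a dense outer Fibonacci sphere enclosing a compact
#'   icosahedral core; the 12 core nodes (plus center) classify inner;
#' * `"slab"` — a two-layer cubic lattice patch.
#'
#' Each node carries a uniformly drawn amino acid (the root sequence of
#' [simulate_family()]), a contiguous surface cap of `patch_size` nodes is
#' marked as the planted functional patch, and the structure serializes to
#' a minimal PDB (one representative atom per residue) that round-trips
#' through [read_structure()].
#'
#' @param geometry One of `"sphere"`, `"onion"`, `"slab"`.
#' @param n Total node count (>= 20).
#' @param patch_size Planted patch size (< n/4).
#' @param seed Integer seed; everything is deterministic given the
#'   arguments.
#' @param spacing Target nearest-neighbor spacing in Angstrom (sphere);
#'   the default 3.8 matches the closest C-beta packing distances seen in
#'   folded proteins and keeps nearest-neighbor contacts immune to solvent
#'   intrusion (half-spacing below the 2.5 Angstrom clash distance).
#' @return A `toy_structure`: list with `nodes` tibble (as
#'   [read_structure()] plus `in_patch`), `patch` (node ids), `pdb_text`,
#'   `geometry`, `seed`.
#' @export
toy_structure <- function(geometry = c("sphere", "onion", "slab"), n,
                          patch_size, seed, spacing = 3.8) {
  geometry <- match.arg(geometry)
  stopifnot(n >= 20, patch_size < n / 4)
  co <- switch(geometry,
    sphere = fibonacci_sphere(n, radius = sqrt(n * spacing^2 / (4 * pi))),
    onion = {
      n_in <- 12L
      inner <- icosahedron(2.2)
      outer <- fibonacci_sphere(n - n_in, radius = 6.5)
      rbind(outer, inner)
    },
    slab = {
      nx <- ceiling(sqrt(n / 2))
      g <- expand.grid(x = seq_len(nx), y = seq_len(ceiling(n / 2 / nx)),
                       z = 1:2)
      as.matrix(g[seq_len(n), ]) * spacing
    })
  aa <- withr_seed(seed, sample(AA20, n, replace = TRUE))
  # patch: contiguous cap nearest to a seeded random direction (first-layer
  # nodes only, so the cap sits on the outer surface)
  outer_idx <- switch(geometry,
    sphere = seq_len(n),
    onion = seq_len(n - 12L),
    slab = which(co[, 3] == max(co[, 3])))
  dir <- withr_seed(seed + 1L, {
    v <- stats::rnorm(3); v / sqrt(sum(v^2))
  })
  anchor <- switch(geometry,
    sphere = dir * sqrt(n * spacing^2 / (4 * pi)),
    onion = dir * 6.5,
    slab = co[outer_idx[1], ] + c(0.1, 0.1, 0))
  d_anchor <- sqrt(colSums((t(co[outer_idx, , drop = FALSE]) - anchor)^2))
  patch_idx <- outer_idx[order(d_anchor)[seq_len(patch_size)]]

  aa3 <- bio3d::aa123(aa)
  nodes <- tibble::tibble(
    node_id = paste0("A", seq_len(n)), chain = "A", resnum = seq_len(n),
    icode = "", aa = aa3, x = round(co[, 1], 3), y = round(co[, 2], 3),
    z = round(co[, 3], 3),
    rep_atom = ifelse(aa3 == "GLY", "CA", "CB"), cb_fallback = FALSE,
    in_patch = seq_len(n) %in% patch_idx
  )
  out <- list(nodes = nodes, patch = nodes$node_id[patch_idx],
              pdb_text = nodes_to_pdb(nodes), geometry = geometry,
              seed = seed)
  class(out) <- "toy_structure"
  out
}

fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

icosahedron <- function(radius) {
  g <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, g), c(0, -1, g), c(0, 1, -g), c(0, -1, -g),
    c(1, g, 0), c(-1, g, 0), c(1, -g, 0), c(-1, -g, 0),
    c(g, 0, 1), c(-g, 0, 1), c(g, 0, -1), c(-g, 0, -1))
  v * radius / sqrt(1 + g^2)
}

# minimal single-atom-per-residue PDB serialization
nodes_to_pdb <- function(nodes) {
  atom <- ifelse(nodes$rep_atom == "CA", " CA ", " CB ")
  elem <- "C"
  lines <- sprintf(
    "ATOM  %5d %s %3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(nodes)), atom, nodes$aa, nodes$chain, nodes$resnum,
    ifelse(nodes$icode == "", " ", nodes$icode),
    nodes$x, nodes$y, nodes$z, 1, 0, elem)
  paste(c(lines, "END"), collapse = "\n")
}

#' @export
print.toy_structure <- function(x, ...) {
  cat("<toy_structure> ", x$geometry, ", ", nrow(x$nodes), " residues, ",
      length(x$patch), "-residue patch (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Simulate a homolog family with a conserved surface patch
#'
#' Realizes the scenario driving DSPAC-based sequence selection: an
#' in-group of homologs that conserve the planted functional patch while
#' diverging elsewhere, and an out-group whose original patch has
#' diverged and whose conserved patch has relocated to the antipodal
#' surface cap (a family whose function moved). Sequences are indel-free,
#' so the identity alignment is exact.
#'
#' Each sequence starts from the structure's root sequence and accumulates
#' BLOSUM62-conditional substitutions at permitted positions until its
#' realized identity reaches its target (recorded; mutations may revert, so
#' identity is counted, not assumed). In-group sequences never touch patch
#' columns; out-group sequences carry a shared out-group consensus
#' (divergent from the root) at the relocated patch, hold it fixed, and are
#' free to mutate the original patch.
#'
#' @param structure A [toy_structure()].
#' @param identity_targets Target percent identities of the in-group
#'   (default 15 values spread 85 down to 45).
#' @param outgroup_split Identity below which sequences belong to the
#'   out-group (default 40).
#' @param n_outgroup Number of out-group sequences (default 5, identity
#'   targets clustered tightly in (`outgroup_split` - 9,
#'   `outgroup_split` - 5): a coherent diverged subfamily).
#' @param seed Integer seed.
#' @return A list: `seqs` tibble (`id`, `seq`, `target`, `realized`,
#'   `group`) including the query row (`id = "query"`), `relocated_patch`
#'   node ids, `seed`.
#' @export
simulate_family <- function(structure,
                            identity_targets = seq(85, 45, length.out = 15),
                            outgroup_split = 40, n_outgroup = 5, seed = 1L) {
  stopifnot(all(identity_targets >= 10), all(identity_targets <= 95),
            all(identity_targets >= outgroup_split))
  nodes <- structure$nodes
  n <- nrow(nodes)
  root <- bio3d::aa321(nodes$aa)
  patch_pos <- which(nodes$node_id %in% structure$patch)

  # antipodal cap: nodes nearest to the reflection of the patch center
  co <- as.matrix(nodes[, c("x", "y", "z")])
  pc <- colMeans(co[patch_pos, , drop = FALSE])
  d_anti <- sqrt(colSums((t(co) + pc)^2))
  reloc_pos <- order(d_anti)[seq_along(patch_pos)]
  if (length(intersect(reloc_pos, patch_pos)) > 0L)
    stop("identity target unreachable: relocated patch overlaps the patch")

  # the out-group is a coherent functionally diverged subfamily: its
  # identities to the query cluster tightly just below the split, so the
  # whole subfamily enters the candidate sets as a block
  out_targets <- if (n_outgroup > 0)
    seq(outgroup_split - 5, outgroup_split - 9, length.out = n_outgroup)
  else numeric()
  tab <- substitution_table()
  # substitution proposal: BLOSUM62-conditional, zero mass on identity
  prop <- exp(tab$matrix / 2)
  diag(prop) <- 0
  prop <- prop / rowSums(prop)

  # the out-group conserves its own residues at the relocated site, not the
  # root's: a shared consensus, forced to differ from the root there
  reloc_consensus <- withr_seed(seed * 2003L, {
    vapply(root[reloc_pos], function(a)
      sample(setdiff(AA20, a), 1L), character(1))
  })

  mutate_to <- function(target, protected, rng_stream, start = root) {
    free <- setdiff(seq_len(n), protected)
    if (100 * length(protected) / n > target + 5)
      stop("identity target unreachable: protected patch too large")
    s <- start
    withr_seed(rng_stream, {
      guard <- 0L
      while (100 * sum(s == root) / n > target && guard < 50L * n) {
        pos <- sample(free, 1L)
        s[pos] <- sample(AA20, 1L, prob = prop[s[pos], ])
        guard <- guard + 1L
      }
    })
    s
  }

  specs <- rbind(
    data.frame(target = identity_targets, group = "ingroup"),
    data.frame(target = out_targets,
               group = rep("outgroup", length(out_targets))))
  seqs <- purrr::map_dfr(seq_len(nrow(specs)), function(k) {
    ingroup <- specs$group[k] == "ingroup"
    protected <- if (ingroup) patch_pos else reloc_pos
    start <- root
    if (!ingroup) start[reloc_pos] <- reloc_consensus
    s <- mutate_to(specs$target[k], protected, seed * 1009L + k, start)
    tibble::tibble(
      id = sprintf("%s_%02d", specs$group[k], k),
      seq = paste(s, collapse = ""),
      target = specs$target[k],
      realized = 100 * sum(s == root) / n,
      group = specs$group[k])
  })
  seqs <- dplyr::bind_rows(
    tibble::tibble(id = "query", seq = paste(root, collapse = ""),
                   target = 100, realized = 100, group = "query"),
    seqs)
  list(seqs = seqs, relocated_patch = nodes$node_id[reloc_pos], seed = seed)
}

#' Write a simulated fixture bundle to disk
#'
#' Emits the minimal PDB, the family FASTA (query first), the trivial
#' aligned FASTA (sequences are indel-free) and a pseudo-catalytic TSV
#' listing the planted patch residues, so the full pipeline can run from
#' files.
#'
#' @param structure A [toy_structure()].
#' @param family A [simulate_family()] result.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_fixture_bundle <- function(structure, family, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(structure$pdb_text, file.path(dir, "structure.pdb"))
  fa <- paste0(">", family$seqs$id, "\n", family$seqs$seq)
  writeLines(fa[family$seqs$id == "query"], file.path(dir, "query.fasta"))
  writeLines(fa[family$seqs$id != "query"], file.path(dir, "hits.fasta"))
  writeLines(fa, file.path(dir, "aligned.fasta"))
  patch <- structure$nodes[structure$nodes$in_patch, , drop = FALSE]
  readr::write_tsv(
    tibble::tibble(chain = patch$chain, resnum = patch$resnum,
                   icode = patch$icode),
    file.path(dir, "catalytic.tsv"))
  invisible(dir)
}
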