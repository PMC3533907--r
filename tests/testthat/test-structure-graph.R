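test_that("representative atoms follow the CB rule with CA for glycine", {
  nodes <- read_structure(three_res_pdb(), "A")
  expect_equal(nrow(nodes), 3)
  expect_equal(nodes$rep_atom, c("CA", "CB", "CB"))
  expect_equal(nodes$aa, c("GLY", "ALA", "TRP"))
  # GLY sits at its CA, ALA at its CB
  expect_equal(unlist(nodes[1, c("x", "y", "z")], use.names = FALSE),
               c(1, 0, 0))
  expect_equal(unlist(nodes[2, c("x", "y", "z")], use.names = FALSE),
               c(5.5, 1.2, 0))
})

test_that("HETATM records (waters, ligands) are ignored", {
  het <- c(
    pdb_atom_line(90, "O", "HOH", "A", 101, 2, 2, 2, record = "HETATM"),
    pdb_atom_line(91, "O", "HOH", "A", 102, 3, 3, 3, record = "HETATM"))
  nodes <- read_structure(three_res_pdb(het), "A")
  expect_equal(nrow(nodes), 3)
  expect_false(any(grepl("HOH", nodes$aa)))
})

test_that("missing CB falls back to CA and is recorded", {
  lines <- c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "VAL", "A", 2, 4, 0, 0),
    pdb_atom_line(3, "CB", "VAL", "A", 2, 4.5, 1.2, 0),
    "END")
  nodes <- read_structure(paste(lines, collapse = "\n"), "A")
  expect_equal(nodes$rep_atom, c("CA", "CB"))
  expect_equal(nodes$cb_fallback, c(TRUE, FALSE))
})

test_that("absent chains and unusable residues raise errors", {
  expect_error(read_structure(three_res_pdb(), "B"), "chain not found")
  only_n <- paste(c(pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0), "END"),
                  collapse = "\n")
  expect_error(suppressWarnings(read_structure(only_n, "A")), "empty chain")
})

test_that("first-listed altloc is kept", {
  lines <- c(
    pdb_atom_line(1, "CA", "SER", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", "SER", "A", 1, 0.5, 1.2, 0, alt = "A"),
    pdb_atom_line(3, "CB", "SER", "A", 1, 0.9, 1.5, 0, alt = "B"),
    "END")
  nodes <- read_structure(paste(lines, collapse = "\n"), "A")
  expect_equal(nrow(nodes), 1)
  expect_equal(nodes$x, 0.5)
})

test_that("solvent shell fills the expanded box and respects the clash", {
  node <- tibble::tibble(node_id = "A1", chain = "A", resnum = 1,
                         icode = "", aa = "ALA", x = 0, y = 0, z = 0,
                         rep_atom = "CB", cb_fallback = FALSE)
  sh <- solvent_shell(node, spacing = 3, clash = 2.5, margin = 6)
  d <- sqrt(sh$x^2 + sh$y^2 + sh$z^2)
  expect_true(all(d >= 2.5))
  expect_true(all(abs(sh$x) <= 6 & abs(sh$y) <= 6 & abs(sh$z) <= 6))
  # halving the spacing multiplies the retained count by ~8
  sh2 <- solvent_shell(node, spacing = 1.5, clash = 2.5, margin = 6)
  ratio <- nrow(sh2) / nrow(sh)
  expect_gt(ratio, 6)
  expect_lt(ratio, 10)
  expect_error(solvent_shell(node[0, ], 3, 2.5, 6), "empty structure")
  expect_error(solvent_shell(node, 3, 2.5, 0))
})

test_that("tessellation adjacency matches the brute-force Voronoi oracle", {
  for (seed in 1:3) {
    co <- dspacr:::withr_seed(seed,
                              matrix(stats::runif(3 * 14, 0, 12), ncol = 3))
    edges <- dspacr:::.delaunay_edges_cpp(co)
    adj <- matrix(FALSE, 14, 14)
    adj[edges] <- TRUE
    adj <- adj | t(adj)
    expect_identical(adj, oracle_voronoi_neighbors(co),
                     label = paste("seed", seed))
  }
})

test_that("two residues inside a shell are surface and mutually adjacent", {
  nodes <- tibble::tibble(
    node_id = c("A1", "A2"), chain = "A", resnum = 1:2, icode = "",
    aa = "ALA", x = c(-1.25, 1.25), y = 0, z = 0, rep_atom = "CB",
    cb_fallback = FALSE)
  g <- contact_graph(nodes)
  expect_equal(g$nodes$label, c("surface", "surface"))
  expect_equal(nrow(g$edges), 1)
})

test_that("a caged center node is classified inner", {
  cage <- dspacr:::icosahedron(5)
  nodes <- tibble::tibble(
    node_id = paste0("A", 1:13), chain = "A", resnum = 1:13, icode = "",
    aa = "ALA", x = c(0, cage[, 1]), y = c(0, cage[, 2]),
    z = c(0, cage[, 3]), rep_atom = "CB", cb_fallback = FALSE)
  # shell restricted to the outside of the cage, per the construction
  sh <- solvent_shell(nodes, spacing = 2, clash = 2.5, margin = 6)
  sh <- sh[sqrt(sh$x^2 + sh$y^2 + sh$z^2) > 6.5, , drop = FALSE]
  g <- contact_graph(nodes, sh)
  expect_equal(g$nodes$label[1], "inner")
  expect_true(all(g$nodes$label[-1] == "surface"))
  expect_true(min(sqrt(sh$x^2 + sh$y^2 + sh$z^2)) > 5)
})

test_that("interface residues are recognized from other-chain points", {
  # a caged node that touches an other-chain point but no solvent:
  # solvent exposure takes precedence, so the center must be shielded
  cage <- dspacr:::icosahedron(5)
  nodes <- tibble::tibble(
    node_id = paste0("A", 1:13), chain = "A", resnum = 1:13, icode = "",
    aa = "ALA", x = c(0, cage[, 1]), y = c(0, cage[, 2]),
    z = c(0, cage[, 3]), rep_atom = "CB", cb_fallback = FALSE)
  sh <- solvent_shell(nodes, spacing = 2, clash = 2.5, margin = 6)
  sh <- sh[sqrt(sh$x^2 + sh$y^2 + sh$z^2) > 6.5, , drop = FALSE]
  other <- cbind(x = 2.6, y = 0, z = 0)
  g <- contact_graph(nodes, sh, other_points = other)
  expect_equal(g$nodes$label[1], "interface")
  expect_true(all(g$nodes$label[-1] == "surface"))
})

test_that("edge set is symmetric and free of self loops", {
  ts <- toy_structure("sphere", n = 40, patch_size = 5, seed = 2)
  g <- contact_graph(read_structure(ts$pdb_text, "A"))
  expect_false(any(g$edges$from == g$edges$to))
  key <- paste(pmin(g$edges$from, g$edges$to),
               pmax(g$edges$from, g$edges$to))
  expect_false(any(duplicated(key)))
})

test_that("neighborhood applies both the distance and separation rules", {
  g <- path_graph(6)
  # D = 2.5 from node 1: nodes 2, 3 qualify; node 4 is 3 steps but 3 A away
  expect_setequal(graph_neighborhood(g, "A1", D = 2.5), c("A2", "A3"))
  # D below the minimum spacing: empty everywhere
  expect_length(graph_neighborhood(g, "A3", D = 0.5), 0)
  # focal residue must be surface
  g2 <- g; g2$nodes$label[1] <- "inner"
  expect_error(graph_neighborhood(g2, "A1", D = 2), "non-surface")
})

test_that("neighborhood agrees with exhaustive search and is symmetric", {
  ts <- toy_structure("sphere", n = 60, patch_size = 6, seed = 5)
  g <- contact_graph(read_structure(ts$pdb_text, "A"))
  ctx <- dspacr:::nbr_context(g)
  nb <- dspacr:::neighbor_sets(ctx, 7, 3)
  co <- as.matrix(g$nodes[match(ctx$ids, g$nodes$node_id),
                          c("x", "y", "z")])
  eidx <- cbind(match(g$edges$from, ctx$ids), match(g$edges$to, ctx$ids))
  eidx <- eidx[stats::complete.cases(eidx), , drop = FALSE]
  ora <- oracle_neighbors(co, eidx, 7, 3)
  for (i in seq_along(nb)) {
    expect_setequal(nb[[i]], ctx$ids[ora[[i]]])
  }
  for (i in seq_along(nb)) for (j in nb[[i]]) {
    expect_true(ctx$ids[i] %in% nb[[match(j, ctx$ids)]])
  }
})

test_that("graph TSV round trip preserves nodes and edges", {
  ts <- toy_structure("sphere", n = 30, patch_size = 4, seed = 9)
  g <- contact_graph(read_structure(ts$pdb_text, "A"))
  dir <- withr::local_tempdir()
  write_contact_graph(g, dir)
  g2 <- read_contact_graph(dir)
  expect_equal(as.data.frame(g2$nodes), as.data.frame(g$nodes))
  expect_equal(as.data.frame(g2$edges), as.data.frame(g$edges))
})
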