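test_that("neighbor averages follow the centered-mean definition", {
  g <- path_graph(5)
  # constant conservation: every neighbor average is zero
  sc <- scores_tbl(g, rep(0.4, 5))
  ms <- moran_scatter(sc, g, D = 10)
  expect_true(all(abs(ms$a) < 1e-12))
  # explicit enumeration on the 5-node path with scores (0,0,1,0,0)
  y <- c(0, 0, 1, 0, 0)
  sc2 <- scores_tbl(g, y)
  ms2 <- moran_scatter(sc2, g, D = 10)
  co <- cbind(0:4, 0, 0)
  nb <- oracle_neighbors(co, cbind(1:4, 2:5), 10, 3)
  ybar <- mean(y)
  a_exp <- vapply(seq_len(5), function(i) mean(y[nb[[i]]] - ybar),
                  numeric(1))
  expect_equal(ms2$a[match(g$nodes$node_id, ms2$node_id)], a_exp,
               tolerance = 1e-12)
  # centered +1/-1 neighbors cancel
  g3 <- path_graph(3)
  y3 <- c(1, 0.5, 0) # node 2 has neighbors at +0.5 and -0.5 around the mean
  ms3 <- moran_scatter(scores_tbl(g3, y3), g3, D = 10)
  expect_equal(ms3$a[ms3$node_id == "A2"], 0, tolerance = 1e-12)
})

test_that("scatter x-axis is standardized over included residues", {
  ts <- toy_structure("sphere", n = 50, patch_size = 5, seed = 8)
  g <- contact_graph(read_structure(ts$pdb_text, "A"))
  sc <- scores_tbl(g, dspacr:::withr_seed(1, stats::runif(50)))
  ms <- moran_scatter(sc, g, D = 6)
  expect_equal(mean(ms$x), 0, tolerance = 1e-9)
  expect_equal(stats::sd(ms$x), 1, tolerance = 1e-6)
})

test_that("segregated high/low blocks give dspac 1, checkerboard negative", {
  # two distant blocks, each internally connected, no cross edges
  co <- rbind(cbind(1:4, 0, 0), cbind(100 + 1:4, 0, 0))
  edges <- rbind(cbind(1:3, 2:4), cbind(5:7, 6:8))
  g <- manual_graph(co, edges)
  y <- c(rep(0.9, 4), rep(0.1, 4))
  fit <- dspac(scores_tbl(g, y), g, D = 5)
  expect_equal(fit$dspac, 1, tolerance = 1e-9)
  # alternating ring: every neighbor average opposes the value
  n <- 10
  th <- 2 * pi * (0:(n - 1)) / n
  ring <- cbind(10 * cos(th), 10 * sin(th), 0)
  redge <- cbind(1:n, c(2:n, 1))
  gr <- manual_graph(ring, redge)
  yr <- rep(c(0.9, 0.1), n / 2)
  fitr <- dspac(scores_tbl(gr, yr), gr, D = 10)
  expect_lt(fitr$dspac, 0)
})

test_that("dspac equals direct Pearson correlation of the scatter", {
  ts <- toy_structure("sphere", n = 80, patch_size = 8, seed = 2)
  g <- contact_graph(read_structure(ts$pdb_text, "A"))
  sc <- scores_tbl(g, dspacr:::withr_seed(3, stats::runif(80)))
  fit <- dspac(sc, g, D = 7)
  ms <- fit$scatter
  expect_equal(fit$dspac, stats::cor(ms$x, ms$a), tolerance = 1e-12)
  # affine rescaling of the conservation leaves dspac unchanged
  sc2 <- sc
  sc2$cons <- 3.7 * sc2$cons + 0.21
  fit2 <- dspac(sc2, g, D = 7)
  expect_equal(fit2$dspac, fit$dspac, tolerance = 1e-9)
})

test_that("dspac stays small under spatially independent attributes", {
  hits <- 0
  for (r in 1:200) {
    g <- rgg_graph(100, side = 20, cutoff = 6, seed = 100 + r)
    sc <- scores_tbl(g, dspacr:::withr_seed(1200 + r, stats::runif(100)))
    fit <- dspac(sc, g, D = 6)
    if (!is.na(fit$dspac) && abs(fit$dspac) < 0.3) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("degenerate scatters are reported, not silently scored", {
  g <- path_graph(4)
  fit <- dspac(scores_tbl(g, rep(0.5, 4)), g, D = 10)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$dspac))
})

test_that("the no-correlation test behaves like a two-sided t-test", {
  expect_equal(dspac_test(0, 30), 1)
  # monotone decreasing in |r| at fixed n
  p <- vapply(c(0.1, 0.3, 0.5, 0.741, 0.9), dspac_test, numeric(1), n = 100)
  expect_true(all(diff(p) < 0))
  expect_lt(dspac_test(0.741, 100), 0.05)
  expect_gt(dspac_test(0.741, 100), 0)
  expect_equal(dspac_test(1, 10), .Machine$double.xmin)
  # cross-check against cor.test on a concrete sample
  x <- dspacr:::withr_seed(1, stats::rnorm(40))
  y <- dspacr:::withr_seed(2, x + stats::rnorm(40))
  expect_equal(dspac_test(stats::cor(x, y), 40),
               stats::cor.test(x, y)$p.value, tolerance = 1e-12)
})

test_that("lmic matches the direct local Moran evaluation", {
  # sign structure around the mean
  g <- path_graph(4)
  y <- c(0.9, 0.9, 0.1, 0.1)
  lm0 <- lmic(scores_tbl(g, y), g, D = 1.5)
  expect_gt(lm0$lmic[lm0$node_id == "A1"], 0)  # high beside high
  expect_gt(lm0$lmic[lm0$node_id == "A4"], 0)  # low beside low clusters too
  y1 <- c(0.9, 0.9, 0.9, 0.1, 0.9)
  g5 <- path_graph(5)
  lm1 <- lmic(scores_tbl(g5, y1), g5, D = 1.5)
  expect_lt(lm1$lmic[lm1$node_id == "A4"], 0)  # low surrounded by highs
  # residue at the mean has lmic 0
  y2 <- c(0.2, 0.5, 0.8)
  g2 <- path_graph(3)
  lm2 <- lmic(scores_tbl(g2, y2), g2, D = 1.5)
  expect_equal(lm2$lmic[lm2$node_id == "A2"], 0, tolerance = 1e-12)
  # brute-force equality on random instances of <= 12 nodes
  for (seed in 1:5) {
    n <- 8 + seed %% 5
    co <- dspacr:::withr_seed(seed, matrix(stats::runif(3 * n, 0, 15),
                                           ncol = 3))
    g3 <- geometric_graph(co, cutoff = 8)
    y3 <- dspacr:::withr_seed(seed + 50, stats::runif(n))
    lm3 <- lmic(scores_tbl(g3, y3), g3, D = 6)
    eidx <- cbind(match(g3$edges$from, g3$nodes$node_id),
                  match(g3$edges$to, g3$nodes$node_id))
    nb <- oracle_neighbors(co, eidx, 6, 3)
    expect_equal(lm3$lmic, oracle_lmic(y3, nb), tolerance = 1e-12)
  }
})

test_that("constant conservation leaves lmic undefined", {
  g <- path_graph(4)
  expect_error(lmic(scores_tbl(g, rep(0.3, 4)), g, D = 2), "constant")
})

test_that("the Monte Carlo test is deterministic and counts replicates", {
  g <- rgg_graph(60, side = 22, cutoff = 6, seed = 31)
  sc <- scores_tbl(g, dspacr:::withr_seed(32, stats::runif(60)))
  mc1 <- lmic_mc_test(sc, g, D = 6, n_perm = 500, seed = 7)
  mc2 <- lmic_mc_test(sc, g, D = 6, n_perm = 500, seed = 7)
  expect_identical(as.data.frame(mc1), as.data.frame(mc2))
  expect_true(all(mc1$n_perm[mc1$n_nbr > 0] == 500))
  mc3 <- lmic_mc_test(sc, g, D = 6, n_perm = 500, seed = 8)
  expect_false(identical(mc1$threshold, mc3$threshold))
  expect_error(lmic_mc_test(sc, g, D = 6, n_perm = 50, seed = 1), "too few")
})

test_that("significance requires above-mean conservation", {
  ts <- toy_structure("sphere", n = 60, patch_size = 6, seed = 12)
  g <- contact_graph(read_structure(ts$pdb_text, "A"))
  sc <- scores_tbl(g, dspacr:::withr_seed(13, stats::runif(60)))
  mc <- lmic_mc_test(sc, g, D = 6, n_perm = 200, seed = 3)
  expect_true(all(mc$cons[mc$significant] > attr(mc, "cons_mean")))
  expect_true(all(mc$significant == (!is.na(mc$threshold) &
                                       mc$lmic > mc$threshold &
                                       mc$cons > attr(mc, "cons_mean"))))
})

test_that("permutation p-values are uniform under exchangeable attributes", {
  g <- rgg_graph(80, side = 25, cutoff = 6, seed = 71)
  sc <- scores_tbl(g, dspacr:::withr_seed(72, stats::runif(80)))
  mc <- lmic_mc_test(sc, g, D = 6, n_perm = 1000, seed = 9)
  p <- (mc$n_greater[mc$n_nbr > 0] + 1) / (1000 + 1)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted conserved patch is detected against a noisy background", {
  ts <- toy_structure("sphere", n = 150, patch_size = 8, seed = 4)
  g <- contact_graph(read_structure(ts$pdb_text, "A"))
  cons <- dspacr:::withr_seed(5, stats::runif(150, 0.1, 0.4))
  cons[match(ts$patch, g$nodes$node_id)] <- 0.95
  sc <- scores_tbl(g, cons)
  mc <- lmic_mc_test(sc, g, D = 6, n_perm = 1000, seed = 6)
  sig <- mc$node_id[mc$significant]
  expect_gte(length(intersect(sig, ts$patch)), 6)
  expect_lte(length(setdiff(sig, ts$patch)), 0.05 * (150 - 8))
})
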