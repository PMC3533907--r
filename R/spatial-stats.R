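#' Moran scatterplot of conservation on the protein surface
#'
#' For each scored surface residue with at least one neighbor the
#' scatterplot pairs its standardized conservation (`x`) with the average
#' centered conservation of its neighbors (`a`): `A_i = sum_{j in N(i)}
#' (y_j - ybar) / n_i`, with `ybar` the mean over all scored surface
#' residues. Residues with empty neighborhoods are excluded.
#'
#' @param scores Scored surface residues from [map_conservation()] (columns
#'   `node_id`, `cons`).
#' @param graph `contact_graph`.
#' @param D Neighboring residue threshold in Angstrom.
#' @param max_separation Separation degree bound.
#' @param ctx Precomputed neighborhood context (internal reuse).
#' @return A tibble `node_id`, `cons`, `x` (z-scored conservation), `a`
#'   (neighbor average, centered scale), `n_nbr`.
#' @export
moran_scatter <- function(scores, graph, D, max_separation = 3, ctx = NULL) {
  ctx <- ctx %||% nbr_context(graph)
  sc <- scores[match(ctx$ids, scores$node_id), , drop = FALSE]
  keep <- !is.na(sc$cons)
  ids <- ctx$ids[keep]
  y <- sc$cons[keep]
  ok <- ctx$dmat[keep, keep, drop = FALSE] <= D &
    ctx$sep[keep, keep, drop = FALSE] <= max_separation
  diag(ok) <- FALSE
  n_nbr <- unname(rowSums(ok))
  ybar <- mean(y)
  a <- as.numeric(ok %*% (y - ybar)) / pmax(n_nbr, 1)
  s <- stats::sd(y)
  x <- if (s > 0) (y - mean(y)) / s else rep(NA_real_, length(y))
  out <- tibble::tibble(node_id = ids, cons = y, x = x, a = a,
                        n_nbr = n_nbr)
  out <- out[out$n_nbr > 0L, , drop = FALSE]
  attr(out, "cons_mean") <- ybar
  out
}

#' Degree of spatial autocorrelation (DSPAC)
#'
#' The slope of the Moran scatterplot regression line, reported as the
#' Pearson correlation between a residue's standardized conservation and
#' its neighbors' average conservation (with a z-scored x-axis the two
#' coincide up to the a-axis scale; the raw OLS slope is also returned).
#' The p-value is the two-sided no-correlation t-test with `n - 2` degrees
#' of freedom.
#'
#' @inheritParams moran_scatter
#' @return A `dspac_fit` list: `dspac`, `slope`, `n_points`, `p_value`,
#'   `D`, plus the scatter tibble.
#' @export
dspac <- function(scores, graph, D, max_separation = 3, ctx = NULL) {
  sc <- moran_scatter(scores, graph, D, max_separation, ctx = ctx)
  n <- nrow(sc)
  if (n < 3L || stats::sd(sc$x) == 0 || stats::sd(sc$a) == 0) {
    fit <- list(dspac = NA_real_, slope = NA_real_, n_points = n,
                p_value = NA_real_, D = D, degenerate = TRUE, scatter = sc)
    class(fit) <- "dspac_fit"
    return(fit)
  }
  r <- stats::cor(sc$x, sc$a)
  fit <- list(
    dspac = r,
    slope = stats::cov(sc$a, sc$x) / stats::var(sc$x),
    n_points = n,
    p_value = dspac_test(r, n),
    D = D, degenerate = FALSE, scatter = sc
  )
  class(fit) <- "dspac_fit"
  fit
}

#' Two-sided no-correlation test for a DSPAC value
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to a t distribution with
#' `n - 2` degrees of freedom; `|r| = 1` returns the smallest representable
#' positive value.
#'
#' @param r Correlation (DSPAC).
#' @param n Number of scatterplot points.
#' @return Two-sided p-value.
#' @export
dspac_test <- function(r, n) {
  stopifnot(n >= 3)
  if (abs(r) >= 1) return(.Machine$double.xmin)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
}

#' @export
print.dspac_fit <- function(x, ...) {
  cat("<dspac_fit> DSPAC = ", format(x$dspac, digits = 4),
      " (n = ", x$n_points, ", D = ", x$D,
      " A, p = ", format(x$p_value, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
glance.dspac_fit <- function(x, ...) {
  tibble::tibble(dspac = x$dspac, slope = x$slope, n_points = x$n_points,
                 p_value = x$p_value, D = x$D, degenerate = x$degenerate)
}

#' @export
tidy.dspac_fit <- function(x, ...) x$scatter

#' Local Moran's I of conservation (LMIC)
#'
#' `LMIC_i = (Cons_i - Consbar) * sum_{j in N(i)} (Cons_j - Consbar) /
#' sigma^2`, where the mean and the population standard deviation are taken
#' over all scored surface residues and the binary neighbor weights follow
#' the same (D, separation) rule as the Moran scatterplot. Residues with an
#' empty neighborhood have LMIC 0.
#'
#' @inheritParams moran_scatter
#' @return A tibble `node_id`, `cons`, `n_nbr`, `lmic`, with `cons_mean`
#'   and `sigma` as attributes.
#' @export
lmic <- function(scores, graph, D, max_separation = 3, ctx = NULL) {
  ctx <- ctx %||% nbr_context(graph)
  sc <- scores[match(ctx$ids, scores$node_id), , drop = FALSE]
  keep <- !is.na(sc$cons)
  ids <- ctx$ids[keep]
  y <- sc$cons[keep]
  mu <- mean(y)
  sigma2 <- mean((y - mu)^2)           # population variance
  if (sigma2 == 0) stop("constant conservation, LMIC undefined")
  ok <- ctx$dmat[keep, keep, drop = FALSE] <= D &
    ctx$sep[keep, keep, drop = FALSE] <= max_separation
  diag(ok) <- FALSE
  val <- (y - mu) * as.numeric(ok %*% (y - mu)) / sigma2
  out <- tibble::tibble(node_id = ids, cons = y,
                        n_nbr = unname(rowSums(ok)), lmic = val)
  attr(out, "cons_mean") <- mu
  attr(out, "sigma") <- sqrt(sigma2)
  out
}

#' Monte Carlo significance test for LMIC
#'
#' For each scored surface residue `i` the coordinates and conservation of
#' `i` are held fixed while the conservation values of the remaining
#' residues are permuted (a conditional permutation, equivalent to randomly
#' exchanging the other residues' coordinates); `LMIC_i` is recomputed for
#' each of `n_perm` replicates. The threshold is the
#' `ceiling(alpha_fraction * n_perm)`-th largest permuted value — the
#' lowest score of the top 5\% at defaults — and residue `i` is significant
#' when its observed LMIC strictly exceeds the threshold and its
#' conservation exceeds the surface mean. The observed value is not pooled
#' into the reference set. No multiple-testing correction is applied across
#' residues.
#'
#' @inheritParams moran_scatter
#' @param n_perm Number of permutation replicates (>= 100).
#' @param alpha_fraction Upper tail fraction defining the threshold.
#' @param seed Integer seed; fixed seeds reproduce flags bit-identically.
#' @return A `lmic_mc` tibble: `node_id`, `cons`, `n_nbr`, `lmic`,
#'   `threshold`, `n_greater` (permuted values above the observed),
#'   `n_perm` (replicates actually generated), `significant`. Attributes:
#'   `cons_mean`, `sigma`, `seed`, `alpha_fraction`.
#' @export
lmic_mc_test <- function(scores, graph, D, max_separation = 3,
                         n_perm = 10000, alpha_fraction = 0.05,
                         seed = 1L, ctx = NULL) {
  if (n_perm < 100) stop("too few replicates (n_perm < 100)")
  ctx <- ctx %||% nbr_context(graph)
  base <- lmic(scores, graph, D, max_separation, ctx = ctx)
  mu <- attr(base, "cons_mean")
  sigma <- attr(base, "sigma")
  keep <- ctx$ids %in% base$node_id
  ok <- ctx$dmat[keep, keep, drop = FALSE] <= D &
    ctx$sep[keep, keep, drop = FALSE] <= max_separation
  diag(ok) <- FALSE
  nbrs <- lapply(seq_len(nrow(ok)), function(i) which(ok[i, ]))
  k <- ceiling(alpha_fraction * n_perm)
  perm <- withr_seed(seed, {
    .lmic_perm_cpp(base$cons, nbrs, mu, sigma^2, as.integer(n_perm),
                   as.integer(k))
  })
  out <- base
  out$lmic <- perm$lmic
  out$threshold <- perm$threshold
  out$n_greater <- perm$n_greater
  out$n_perm <- perm$n_perm
  out$significant <- !is.na(out$threshold) &
    out$lmic > out$threshold & out$cons > mu
  attr(out, "cons_mean") <- mu
  attr(out, "sigma") <- sigma
  attr(out, "seed") <- seed
  attr(out, "alpha_fraction") <- alpha_fraction
  class(out) <- c("lmic_mc", class(out))
  out
}

#' @export
glance.lmic_mc <- function(x, ...) {
  tibble::tibble(n_residues = nrow(x), n_significant = sum(x$significant),
                 cons_mean = attr(x, "cons_mean"), sigma = attr(x, "sigma"),
                 n_perm = max(x$n_perm), alpha_fraction =
                   attr(x, "alpha_fraction"), seed = attr(x, "seed"))
}
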