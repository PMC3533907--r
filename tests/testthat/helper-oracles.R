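# Independent brute-force oracles, deliberately implemented with different
# algorithms than the package internals.

# Voronoi facet-sharing test for a pair (i, j): does an open region exist
# on their bisector plane that is strictly closer to p_i than to every
# other point? Solved as a max-margin program in (s, t, eps) with
# quadprog: maximize the worst normalized slack, capped at 1.
oracle_voronoi_neighbors <- function(pts) {
  n <- nrow(pts)
  adj <- matrix(FALSE, n, n)
  scale <- max(stats::dist(pts))
  tol <- 1e-7 * scale
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pi_ <- pts[i, ]; pj <- pts[j, ]
      m <- (pi_ + pj) / 2
      w <- pj - pi_
      w <- w / sqrt(sum(w^2))
      u <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- u - sum(u * w) * w; u <- u / sqrt(sum(u^2))
      v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
             w[1] * u[2] - w[2] * u[1])
      ks <- setdiff(seq_len(n), c(i, j))
      A <- t(vapply(ks, function(k) {
        g <- pts[k, ] - pi_
        c(a = 2 * sum(g * u), b = 2 * sum(g * v),
          d = sum(pts[k, ]^2) - sum(pi_^2) - 2 * sum(g * m))
      }, numeric(3)))
      nrm <- sqrt(A[, 1]^2 + A[, 2]^2)
      flat <- nrm < 1e-10 * scale
      if (any(flat & A[, 3] <= tol)) next  # blocked irrespective of (s, t)
      A <- A[!flat, , drop = FALSE]
      nrm <- nrm[!flat]
      if (nrow(A) == 0L) {
        adj[i, j] <- adj[j, i] <- TRUE
        next
      }
      # constraints (normalized): (a/n) s + (b/n) t + eps <= d/n; eps <= 1
      Amat <- cbind(rbind(-A[, 1] / nrm, -A[, 2] / nrm, -1),
                    c(0, 0, -1))
      bvec <- c(-A[, 3] / nrm, -scale)
      sol <- tryCatch(
        quadprog::solve.QP(Dmat = diag(1e-8, 3), dvec = c(0, 0, 1),
                           Amat = Amat, bvec = bvec),
        error = function(e) NULL)
      adj[i, j] <- adj[j, i] <- !is.null(sol) && sol$solution[3] > tol
    }
  }
  adj
}

# Eq-style direct conservation: explicit double loop over sequence pairs.
oracle_conservation <- function(seq_mat, w, blosum, max_m, min_m) {
  std <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
           "S","T","W","Y","V")
  n <- nrow(seq_mat)
  vapply(seq_len(ncol(seq_mat)), function(col) {
    num <- 0; den <- 0
    for (j in seq_len(n - 1)) for (k in (j + 1):n) {
      a <- seq_mat[j, col]; b <- seq_mat[k, col]
      mt <- if (a %in% std && b %in% std)
        (blosum[a, b] - min_m) / (max_m - min_m) else 0
      num <- num + w[j] * w[k] * mt
      den <- den + w[j] * w[k]
    }
    num / den
  }, numeric(1))
}

# Direct local Moran evaluation from an explicit neighbor list.
oracle_lmic <- function(values, nbr_list) {
  mu <- mean(values)
  sigma2 <- mean((values - mu)^2)
  vapply(seq_along(values), function(i) {
    s <- sum(values[nbr_list[[i]]] - mu)
    (values[i] - mu) * s / sigma2
  }, numeric(1))
}

# Neighbor rule evaluated by exhaustive search: distance cutoff plus BFS
# path bound over an explicit edge list.
oracle_neighbors <- function(coords, edges_idx, D, max_sep) {
  n <- nrow(coords)
  adj <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(edges_idx)))
    adj[edges_idx[r, 1], edges_idx[r, 2]] <-
      adj[edges_idx[r, 2], edges_idx[r, 1]] <- TRUE
  sep <- matrix(Inf, n, n); diag(sep) <- 0
  reach <- diag(n) > 0
  cur <- reach
  for (step in seq_len(max_sep)) {
    cur <- (cur %*% adj) > 0
    sep[cur & !is.finite(sep)] <- step
  }
  lapply(seq_len(n), function(i) {
    which(vapply(seq_len(n), function(j) {
      j != i && sep[i, j] <= max_sep &&
        sqrt(sum((coords[i, ] - coords[j, ])^2)) <= D
    }, logical(1)))
  })
}
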