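# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive algorithms (Floyd-Warshall,
# exhaustive enumeration, BFS path counting) rather than the code under test.

# adjacency matrix of an igraph graph as plain 0/1
adj_matrix <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
}

# all-pairs shortest paths by Floyd-Warshall on the adjacency matrix
floyd_warshall <- function(g) {
  a <- adj_matrix(g)
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# nodal efficiencies from the Floyd-Warshall distances
efficiency_oracle <- function(g) {
  d <- floyd_warshall(g)
  n <- nrow(d)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

# largest connected component size of an induced subgraph, by DFS on the
# adjacency matrix
largest_component <- function(a, keep) {
  if (!any(keep)) return(0)
  idx <- which(keep)
  sub <- a[idx, idx, drop = FALSE]
  n <- length(idx)
  seen <- rep(FALSE, n)
  best <- 0
  for (s in seq_len(n)) {
    if (seen[s]) next
    stack <- s
    size <- 0
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      size <- size + 1
      stack <- c(stack, which(sub[v, ] & !seen))
    }
    best <- max(best, size)
  }
  best
}

# exact normalized attack robustness by enumerating every removal order
robustness_exhaustive <- function(g) {
  a <- adj_matrix(g)
  n <- nrow(a)
  perms <- perm_enumerate(n)
  total <- 0
  for (r in seq_len(nrow(perms))) {
    keep <- rep(TRUE, n)
    for (i in seq_len(n)) {
      keep[perms[r, i]] <- FALSE
      total <- total + largest_component(a, keep) / n
    }
  }
  total / (n * nrow(perms))
}

perm_enumerate <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perm_enumerate(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# betweenness centrality by explicit BFS shortest-path counting (Brandes-free)
betweenness_oracle <- function(g) {
  a <- adj_matrix(g)
  n <- nrow(a)
  d <- floyd_warshall(g)
  # count shortest paths between s and t passing through v
  npaths <- function(s, t) {
    if (!is.finite(d[s, t])) return(0)
    if (s == t) return(1)
    sum(vapply(which(a[s, ]), function(u)
      if (d[u, t] == d[s, t] - 1) npaths(u, t) else 0, numeric(1)))
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    tot <- npaths(s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (d[s, v] + d[v, t] == d[s, t]) {
        through <- npaths(s, v) * npaths(v, t)
        btw[v] <- btw[v] + through / tot
      }
    }
  }
  # undirected convention: each unordered pair counted once
  btw
}

# PERMANOVA pseudo-F via the Gower-centered Gram matrix (McArdle-Anderson),
# an algebraically different route from the within-group sums used in the
# package
permanova_f_oracle <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (d^2) %*% J
  groups <- as.character(groups)
  X <- sapply(unique(groups), function(g) as.numeric(groups == g))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  ssb <- sum(diag(H %*% G %*% H))
  sst <- sum(diag(G))
  ssw <- sst - ssb
  g <- length(unique(groups))
  (ssb / (g - 1)) / (ssw / (n - g))
}

# naive cyclic coordinate-descent lasso on standardized data
lasso_cd_oracle <- function(X, y, lambda, tol = 1e-10, max_sweeps = 1e4) {
  n <- nrow(X)
  p <- ncol(X)
  beta <- rep(0, p)
  for (s in seq_len(max_sweeps)) {
    old <- beta
    for (j in seq_len(p)) {
      r <- y - X[, -j, drop = FALSE] %*% beta[-j]
      rho <- sum(X[, j] * r) / n
      z <- sum(X[, j]^2) / n
      beta[j] <- sign(rho) * max(abs(rho) - lambda, 0) / z
    }
    if (max(abs(beta - old)) < tol) break
  }
  beta
}

# standardized-OLS path analysis oracle for single-indicator PLS-PM
ols_path_oracle <- function(data, paths) {
  X <- scale(as.matrix(data))
  p <- ncol(X)
  out <- matrix(0, p, p, dimnames = dimnames(paths))
  for (i in seq_len(p)) {
    pred <- which(paths[i, ] != 0)
    if (!length(pred)) next
    out[i, pred] <- coef(lm(X[, i] ~ X[, pred, drop = FALSE]))[-1]
  }
  out
}

# small random connected-ish graph
random_test_graph <- function(n, p_edge = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p_edge)
    if (igraph::ecount(g) >= 1) return(g)
  }
}

edge_f1 <- function(edges, true_edges) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  pe <- key(edges$from, edges$to)
  te <- key(true_edges$from, true_edges$to)
  tp <- sum(pe %in% te)
  if (length(pe) + length(te) == 0) return(NA_real_)
  2 * tp / (length(pe) + length(te))
}
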