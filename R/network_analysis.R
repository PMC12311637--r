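net_to_igraph <- function(net) {
  if (inherits(net, "cooccurrence_network")) as_igraph(net)
  else if (igraph::is_igraph(net)) net
  else stop("expected a cooccurrence_network or igraph object")
}

#' Whole-network topology metrics
#'
#' Standard descriptors of a co-occurrence network, computed on the
#' unweighted simple graph: node/edge counts, average degree 2E/N, density,
#' diameter (largest finite shortest path), average path length over
#' connected pairs, clustering coefficient (mean local transitivity),
#' modularity (Louvain, best of `louvain_restarts` seeded restarts),
#' Freeman degree centralization, and a small-world index
#' `(C / C_rand) / (L / L_rand)` against `n_null` Erdos-Renyi graphs
#' matched in N and E.
#'
#' @param net a [cooccurrence_network()] or igraph graph with >= 2 nodes.
#' @param seed integer seed (Louvain and the null graphs are stochastic).
#' @param n_null number of matched random graphs for the small-world null.
#' @param louvain_restarts Louvain restarts; the best modularity is kept.
#' @return named list of metrics.
#' @export
topology_metrics <- function(net, seed = 1L, n_null = 20,
                             louvain_restarts = 10) {
  g <- net_to_igraph(net)
  n <- igraph::vcount(g)
  if (n < 2) stop("network needs at least 2 nodes")
  e <- igraph::ecount(g)
  deg <- igraph::degree(g)

  set.seed(seed)
  modularity <- if (e > 0) {
    max(vapply(seq_len(louvain_restarts), function(i)
      igraph::modularity(igraph::cluster_louvain(g, weights = NA)),
      numeric(1)))
  } else NA_real_

  apl <- if (e > 0) igraph::mean_distance(g, weights = NA) else NA_real_
  diam <- if (e > 0) igraph::diameter(g, weights = NA) else NA_real_
  dens <- 2 * e / (n * (n - 1))
  clust <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  centralization <- if (n > 2)
    sum(max(deg) - deg) / ((n - 1) * (n - 2)) else NA_real_

  small_world <- NA_real_
  if (e > 0 && n_null > 0) {
    c_rand <- numeric(n_null)
    l_rand <- numeric(n_null)
    for (i in seq_len(n_null)) {
      gr <- igraph::sample_gnm(n, e)
      c_rand[i] <- igraph::transitivity(gr, type = "localaverage",
                                        isolates = "zero")
      l_rand[i] <- igraph::mean_distance(gr, weights = NA)
    }
    cr <- mean(c_rand)
    lr <- mean(l_rand)
    if (is.finite(cr) && cr > 0 && is.finite(lr) && lr > 0 &&
        is.finite(apl) && apl > 0)
      small_world <- (clust / cr) / (apl / lr)
  }

  list(n_nodes = n, n_edges = e, average_degree = 2 * e / n,
       density = dens, diameter = diam, average_path_length = apl,
       clustering_coefficient = clust, modularity = modularity,
       degree_centralization = centralization, small_world = small_world)
}

# threshold of the top (100 - percentile)% by nearest rank: the k-th
# largest value with k = ceiling((1 - percentile/100) * n); ties inclusive
nearest_rank_threshold <- function(values, percentile) {
  k <- max(1L, ceiling((1 - percentile / 100) * length(values)))
  sort(values, decreasing = TRUE)[k]
}

#' Keystone node detection
#'
#' Keystone taxa are nodes in the top `100 - percentile` percent of both
#' degree and betweenness centrality (default: top 20 percent of each).
#' Thresholds use the nearest-rank percentile and ties are inclusive, so a
#' regular graph where every node is equal returns all nodes.
#'
#' @param net a [cooccurrence_network()] or igraph graph with >= 5 nodes.
#' @param percentile lower percentile cutoff (default 80: top 20 percent).
#' @return character vector of keystone node ids, with attribute
#'   `centrality` (data.frame of degree and betweenness for all nodes).
#' @export
keystone_nodes <- function(net, percentile = 80) {
  g <- net_to_igraph(net)
  if (igraph::vcount(g) < 5) stop("keystone detection needs >= 5 nodes")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA)
  thr_d <- nearest_rank_threshold(deg, percentile)
  thr_b <- nearest_rank_threshold(btw, percentile)
  keep <- names(deg)[deg >= thr_d & btw >= thr_b]
  structure(keep, centrality = data.frame(id = names(deg), degree = deg,
                                          betweenness = btw,
                                          row.names = NULL))
}

#' Random-attack robustness of a network
#'
#' Nodes are removed one at a time in a uniformly random order; after the
#' i-th removal the relative size of the largest connected component,
#' `sigma_i = S_max / N`, is recorded. Averaging `sigma_i` over removal
#' steps and over `n_iterations` random orders gives the normalized
#' robustness `R = (1/N) sum_i mean(sigma_i)`; the vulnerability is
#' `V = 0.5 - R` exactly. For a complete graph R approaches 0.5 from below
#' (`(N-1)/(2N)`), the most attack-tolerant a simple graph can be under
#' this normalization.
#'
#' @param net a [cooccurrence_network()] or igraph graph with >= 2 nodes.
#' @param n_iterations random removal orders (default 10000).
#' @param seed integer seed.
#' @return object of class `robustness_curve`: list with `N`, `sigma`
#'   (per-step mean relative largest-component size, length N), `R`, `V`,
#'   `n_iterations`, `seed`.
#' @export
random_attack_robustness <- function(net, n_iterations = 10000, seed = 1L) {
  g <- net_to_igraph(net)
  n <- igraph::vcount(g)
  if (n < 2) stop("network needs at least 2 nodes")
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  storage.mode(el) <- "integer"
  set.seed(seed)
  sigma_abs <- attack_sigma_mc(n, el, as.integer(n_iterations))
  sigma <- sigma_abs / n
  r <- mean(sigma)
  structure(list(N = n, sigma = sigma, R = r, V = 0.5 - r,
                 n_iterations = n_iterations, seed = seed),
            class = "robustness_curve")
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat(sprintf("robustness_curve: N = %d, R = %.4f, V = %.4f (%d iterations)\n",
              x$N, x$R, x$V, x$n_iterations))
  invisible(x)
}

#' Nodal and global efficiency distribution
#'
#' Nodal efficiency of node i is the mean inverse shortest-path length to
#' every other node on the unweighted graph, with `1/Inf = 0` for
#' disconnected pairs; global efficiency is the mean over ordered pairs
#' (equivalently over nodal efficiencies). Used as a proxy for how
#' effectively signals propagate through the network.
#'
#' @param net a [cooccurrence_network()] or igraph graph with >= 2 nodes.
#' @return object of class `efficiency_distribution`: list with `nodal`
#'   (named, input node order), `values` (sorted ascending), `mu`,
#'   `sigma` (mean and sd of nodal efficiencies), `global`.
#' @export
efficiency_distribution <- function(net) {
  g <- net_to_igraph(net)
  n <- igraph::vcount(g)
  if (n < 2) stop("network needs at least 2 nodes")
  d <- igraph::distances(g, weights = NA)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  nodal <- rowSums(inv) / (n - 1)
  structure(list(nodal = nodal, values = sort(unname(nodal)),
                 mu = mean(nodal), sigma = sd(nodal),
                 global = mean(nodal)),
            class = "efficiency_distribution")
}

#' @export
print.efficiency_distribution <- function(x, ...) {
  cat(sprintf("efficiency_distribution: mu = %.4f, sigma = %.4f, global = %.4f\n",
              x$mu, x$sigma, x$global))
  invisible(x)
}
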