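#' Modified centered log-ratio transform
#'
#' CLR variant for sparse compositional counts: non-zero entries are
#' log-transformed and centered by the geometric mean of that row's
#' non-zero entries; zeros stay exactly zero, avoiding an arbitrary
#' pseudocount. Scale-invariant per row, so counts and relative abundances
#' give identical output.
#'
#' @param counts non-negative numeric matrix (samples x ASVs).
#' @return real matrix of the same shape; all-zero rows stay zero and are
#'   listed in attribute `empty_rows`.
#' @export
mclr_transform <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  empty <- character()
  for (i in seq_len(nrow(counts))) {
    x <- counts[i, ]
    nz <- x > 0
    if (!any(nz)) {
      empty <- c(empty, rownames(counts)[i])
      next
    }
    lx <- log(x[nz])
    out[i, nz] <- lx - mean(lx)
  }
  attr(out, "empty_rows") <- empty
  out
}

standardize_cols <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- 1  # constant columns become zero columns
  sweep(sweep(X, 2, mu), 2, s, "/")
}

lambda_max_of <- function(Xs) {
  S <- crossprod(Xs) / nrow(Xs)
  diag(S) <- 0
  max(abs(S))
}

# per-node lasso fits over a decreasing lambda path; the sparse regressions
# themselves go through glmnet. Returns, for each lambda, the p x p matrix
# B with B[j, i] = coefficient of predictor i in the regression of node j.
nb_fit_path <- function(Xs, lambda_path) {
  p <- ncol(Xs)
  nl <- length(lambda_path)
  res <- lapply(seq_len(nl), function(k) matrix(0, p, p))
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(Xs[, -j, drop = FALSE], Xs[, j],
                          family = "gaussian", alpha = 1,
                          lambda = lambda_path, standardize = FALSE,
                          intercept = FALSE, thresh = 1e-8)
    cf <- as.matrix(coef(fit, s = lambda_path, exact = FALSE))[-1, ,
                                                               drop = FALSE]
    others <- seq_len(p)[-j]
    for (k in seq_len(nl)) res[[k]][j, others] <- cf[, k]
  }
  for (k in seq_len(nl)) dimnames(res[[k]]) <- list(colnames(Xs), colnames(Xs))
  res
}

#' Neighborhood (nodewise lasso) selection at a fixed penalty
#'
#' For every node j, a lasso regression of column j on all other columns at
#' penalty `lambda`, on internally column-standardized data. The largest
#' useful penalty is `lambda_max = max |cross-covariance|` of the
#' standardized columns; any `lambda >= lambda_max` returns an all-zero
#' matrix.
#'
#' @param X numeric matrix (samples x nodes), at least 3 columns; e.g. the
#'   output of [mclr_transform()].
#' @param lambda non-negative penalty.
#' @return p x p coefficient matrix with zero diagonal; entry (j, i) is the
#'   coefficient of node i in the regression of node j.
#' @export
neighborhood_lasso <- function(X, lambda) {
  X <- as.matrix(X)
  if (ncol(X) < 3) stop("need at least 3 nodes")
  if (lambda < 0) stop("lambda must be non-negative")
  Xs <- standardize_cols(X)
  lmax <- lambda_max_of(Xs)
  if (lambda >= lmax)
    return(matrix(0, ncol(X), ncol(X),
                  dimnames = list(colnames(X), colnames(X))))
  # warm-start path from lambda_max down to the requested value
  path <- exp(seq(log(lmax), log(max(lambda, 1e-12)), length.out = 10))
  path[length(path)] <- lambda
  nb_fit_path(Xs, path)[[length(path)]]
}

#' Symmetrize a nodewise coefficient matrix into undirected edges
#'
#' An edge (i, j) exists when either regression selected the partner (OR
#' rule); its signed weight is the larger-magnitude of the two
#' coefficients. The AND rule (both must select) is available for
#' sensitivity analysis.
#'
#' @param B square coefficient matrix with zero diagonal (`B[j, i]` =
#'   coefficient of i in the regression of j).
#' @param rule `"or"` (default) or `"and"`.
#' @return data.frame with columns `from`, `to`, `weight`, `abs_weight`.
#' @export
symmetrize <- function(B, rule = c("or", "and")) {
  rule <- match.arg(rule)
  B <- as.matrix(B)
  p <- nrow(B)
  ids <- colnames(B)
  if (is.null(ids)) ids <- paste0("V", seq_len(p))
  from <- character()
  to <- character()
  w <- numeric()
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    a <- B[i, j]
    b <- B[j, i]
    keep <- if (rule == "or") (a != 0 || b != 0) else (a != 0 && b != 0)
    if (keep) {
      from <- c(from, ids[i])
      to <- c(to, ids[j])
      w <- c(w, if (abs(a) >= abs(b)) a else b)
    }
  }
  data.frame(from = from, to = to, weight = w, abs_weight = abs(w),
             stringsAsFactors = FALSE)
}

#' Construct a co-occurrence network object
#'
#' @param nodes data.frame with at least a column `id`; typically also
#'   `domain` (bacteria/pico/nano) and `taxonomy`.
#' @param edges data.frame `from`, `to`, `weight`, `abs_weight` (as from
#'   [symmetrize()]).
#' @param metadata list of inference provenance (method, lambda, seed...).
#' @return object of class `cooccurrence_network`.
#' @export
cooccurrence_network <- function(nodes, edges, metadata = list()) {
  stopifnot(is.data.frame(nodes), "id" %in% names(nodes))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  bad <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(bad)) stop("edges reference unknown nodes: ",
                        paste(head(bad), collapse = ", "))
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  structure(list(nodes = nodes, edges = edges, metadata = metadata),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network: %d nodes, %d edges (%s)\n",
              nrow(x$nodes), nrow(x$edges),
              if (!is.null(x$metadata$method)) x$metadata$method else "unknown"))
  invisible(x)
}

#' Convert a network to an igraph object
#'
#' @param net a [cooccurrence_network()].
#' @return an undirected igraph graph with node attributes and signed
#'   `weight` plus `abs_weight` edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' StARS model selection for neighborhood lasso networks
#'
#' Stability Approach to Regularization Selection: the lasso penalty is
#' chosen as the smallest lambda on a geometric path (from `lambda_max`
#' down to `lambda_max * lambda_min_ratio`) whose monotonized edge
#' instability across random subsamples stays at or below
#' `stars_threshold`. Instability at a given lambda is the mean over all
#' node pairs of `2 xi (1 - xi)`, where `xi` is the selection frequency of
#' that edge across subsamples. The final network is the OR-symmetrized
#' full-data fit at the selected lambda. Defaults follow the standard
#' parameterization for amplicon co-occurrence inference: nlambda 20,
#' minimum lambda ratio 0.005, instability threshold 0.05, 20 subsamples.
#'
#' @param X numeric matrix (samples x nodes), typically [mclr_transform()]
#'   output; at least 8 rows (20+ recommended for stable selection).
#' @param nlambda number of penalties on the path.
#' @param lambda_min_ratio smallest penalty as a fraction of `lambda_max`.
#' @param stars_threshold target instability.
#' @param n_subsamples number of random subsamples ("representatives").
#' @param subsample_ratio optional fraction of rows per subsample;
#'   default `min(10 sqrt(n), 0.8 n) / n`.
#' @param seed integer seed.
#' @param domains optional named character vector mapping node id to size
#'   fraction, stored as node attribute.
#' @param node_data optional data.frame of extra node annotation (row
#'   names = node ids).
#' @return list with `network` (a [cooccurrence_network()]) and
#'   `lambda_path` (lambdas, raw and monotonized instability, per-edge
#'   selection frequencies at the selected lambda, selected index).
#' @export
stars_select <- function(X, nlambda = 20, lambda_min_ratio = 0.005,
                         stars_threshold = 0.05, n_subsamples = 20,
                         subsample_ratio = NULL, seed = 1L,
                         domains = NULL, node_data = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 8) stop("need at least 8 samples for subsampling")
  if (p < 3) stop("need at least 3 nodes")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  if (n < 20)
    warning("fewer than 20 samples: StARS selection will be unstable")

  Xs <- standardize_cols(X)
  lmax <- lambda_max_of(Xs)
  lambda_path <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                         length.out = nlambda))
  b <- if (is.null(subsample_ratio))
    min(floor(10 * sqrt(n)), floor(0.8 * n))
  else max(3, floor(subsample_ratio * n))

  set.seed(seed)
  freq <- lapply(seq_len(nlambda), function(k) matrix(0, p, p))
  for (s in seq_len(n_subsamples)) {
    idx <- sample(n, b)
    Xsub <- standardize_cols(X[idx, , drop = FALSE])
    fits <- nb_fit_path(Xsub, lambda_path)
    for (k in seq_len(nlambda)) {
      adj <- (fits[[k]] != 0) | t(fits[[k]] != 0)
      freq[[k]] <- freq[[k]] + adj
    }
  }
  freq <- lapply(freq, function(m) m / n_subsamples)
  ut <- upper.tri(matrix(0, p, p))
  instability <- vapply(freq, function(xi)
    mean(2 * xi[ut] * (1 - xi[ut])), numeric(1))
  monotonized <- cummax(instability)

  ok <- which(monotonized <= stars_threshold)
  if (length(ok) == 0) {
    warning("no lambda met the instability threshold; using sparsest lambda")
    opt <- 1L
  } else {
    opt <- max(ok)  # smallest lambda still under the threshold
  }

  B <- nb_fit_path(Xs, lambda_path)[[opt]]
  edges <- symmetrize(B)
  nodes <- data.frame(id = colnames(X), stringsAsFactors = FALSE)
  nodes$domain <- if (!is.null(domains)) unname(domains[nodes$id]) else NA
  if (!is.null(node_data))
    nodes <- cbind(nodes, node_data[nodes$id, , drop = FALSE])
  net <- cooccurrence_network(nodes, edges, metadata = list(
    method = "neighborhood lasso (MB) + StARS",
    lambda_opt = lambda_path[opt], lambda_index = opt,
    nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
    stars_threshold = stars_threshold, n_subsamples = n_subsamples,
    subsample_size = b, seed = seed, n_samples = n))
  sel_freq <- freq[[opt]]
  dimnames(sel_freq) <- list(colnames(X), colnames(X))
  list(network = net,
       lambda_path = list(lambda = lambda_path, instability = instability,
                          monotonized = monotonized, selected = opt,
                          selection_frequency = sel_freq))
}
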