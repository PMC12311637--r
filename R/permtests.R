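perm_result <- function(statistic, p_value, n_permutations, seed,
                        extra = NULL) {
  out <- c(list(statistic = statistic, p_value = p_value,
                n_permutations = n_permutations, seed = seed), extra)
  class(out) <- "perm_test"
  out
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test: statistic = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

upper_vec <- function(d) d[upper.tri(d)]

check_square <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  d
}

# within/between sums of squares from squared inter-point distances
# (Anderson's distance-based formulation)
permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Distance-based permutational multivariate analysis of variance.
#' The pseudo-F statistic is
#' `(SS_between / (g - 1)) / (SS_within / (n - g))`, with sums of squares
#' computed from squared inter-point distances; `R2 = SS_between /
#' SS_total`. The null distribution is obtained by free permutation of the
#' group labels, and the p-value uses the add-one rule
#' `p = (1 + #permuted F >= observed F) / (1 + n_perm)`.
#'
#' @param d square symmetric distance matrix.
#' @param groups factor-like vector of group labels, one per row of `d`.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed.
#' @return a `perm_test` with elements `statistic` (pseudo-F), `R2`,
#'   `p_value`, `df`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- check_square(d)
  groups <- as.character(groups)
  n <- nrow(d)
  if (length(groups) != n) stop("one group label per sample required")
  tab <- table(groups)
  g <- length(tab)
  if (g < 2) stop("need at least two groups")
  if (any(tab < 2)) stop("every group must have at least two members")
  d2 <- d^2
  pseudo_f <- function(grp) {
    ss <- permanova_ss(d2, grp)
    (ss["between"] / (g - 1)) / (ss["within"] / (n - g))
  }
  ss <- permanova_ss(d2, groups)
  f_obs <- as.numeric((ss["between"] / (g - 1)) / (ss["within"] / (n - g)))
  r2 <- as.numeric(ss["between"] / ss["total"])
  set.seed(seed)
  f_perm <- vapply(seq_len(n_perm),
                   function(i) as.numeric(pseudo_f(sample(groups))),
                   numeric(1))
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  perm_result(f_obs, p, n_perm, seed,
              extra = list(R2 = r2, df = c(between = g - 1, within = n - g)))
}

#' Mantel test between two distance matrices
#'
#' Correlation (Spearman by default, matching rank-based environmental
#' screens; Pearson optional) between the upper triangles of two distance
#' matrices, with significance by simultaneous row/column permutation of
#' the second matrix. Add-one p-value, one-sided (positive association).
#'
#' @param d1,d2 square symmetric distance matrices with matching labels.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return a `perm_test` with `statistic` = Mantel r.
#' @export
mantel <- function(d1, d2, method = c("spearman", "pearson"),
                   n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  d1 <- check_square(d1)
  d2 <- check_square(d2)
  if (nrow(d1) != nrow(d2)) stop("matrices must have matching size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2)))
      stop("matrices must share labels")
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  v1 <- upper_vec(d1)
  r_obs <- cor(v1, upper_vec(d2), method = method)
  set.seed(seed)
  n <- nrow(d1)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample(n)
    cor(v1, upper_vec(d2[idx, idx]), method = method)
  }, numeric(1))
  p <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  perm_result(r_obs, p, n_perm, seed, extra = list(method = method))
}

partial_r <- function(r12, r13, r23) {
  denom2 <- (1 - r13^2) * (1 - r23^2)
  # a control collinear with either matrix leaves nothing to correlate
  if (denom2 < 1e-12) return(0)
  (r12 - r13 * r23) / sqrt(denom2)
}

#' Partial Mantel test
#'
#' First-order partial correlation
#' `r(12.3) = (r12 - r13 r23) / sqrt((1 - r13^2)(1 - r23^2))` between the
#' upper triangles of `d1` and `d2` controlling for `d_control`, with a
#' null distribution from permuting the labels of `d1` (recomputing `r12`
#' and `r13` each time while `r23` is fixed).
#'
#' @inheritParams mantel
#' @param d_control square symmetric distance matrix to partial out.
#' @return a `perm_test` with `statistic` = partial Mantel r.
#' @export
partial_mantel <- function(d1, d2, d_control,
                           method = c("spearman", "pearson"),
                           n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  d1 <- check_square(d1)
  d2 <- check_square(d2)
  d3 <- check_square(d_control)
  if (!all(dim(d1) == dim(d2)) || !all(dim(d1) == dim(d3)))
    stop("matrices must have matching size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !is.null(rownames(d3))) {
    d2 <- d2[rownames(d1), rownames(d1)]
    d3 <- d3[rownames(d1), rownames(d1)]
  }
  v2 <- upper_vec(d2)
  v3 <- upper_vec(d3)
  r23 <- cor(v2, v3, method = method)
  stat <- function(m1) {
    v1 <- upper_vec(m1)
    partial_r(cor(v1, v2, method = method), cor(v1, v3, method = method), r23)
  }
  r_obs <- stat(d1)
  set.seed(seed)
  n <- nrow(d1)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample(n)
    stat(d1[idx, idx])
  }, numeric(1))
  p <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  perm_result(r_obs, p, n_perm, seed, extra = list(method = method))
}

#' Spearman correlations between community features and environment
#'
#' Pairwise Spearman rank correlations between each column of an abundance
#' (or other feature) table and each environmental variable, with
#' Benjamini-Hochberg adjustment across the whole matrix.
#'
#' @param features numeric matrix/data.frame, samples in rows.
#' @param env numeric matrix/data.frame of environmental variables,
#'   samples in rows (matching order).
#' @return list with matrices `rho`, `p` and `p_adj` (BH-FDR).
#' @export
spearman_env_correlations <- function(features, env) {
  features <- as.matrix(features)
  env <- as.matrix(env)
  if (nrow(features) != nrow(env)) stop("sample sets must match")
  rho <- matrix(NA_real_, ncol(features), ncol(env),
                dimnames = list(colnames(features), colnames(env)))
  p <- rho
  for (i in seq_len(ncol(features))) for (j in seq_len(ncol(env))) {
    ct <- suppressWarnings(
      stats::cor.test(features[, i], env[, j], method = "spearman"))
    rho[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  p_adj <- matrix(p.adjust(p, method = "BH"), nrow(p), dimnames = dimnames(p))
  list(rho = rho, p = p, p_adj = p_adj)
}
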