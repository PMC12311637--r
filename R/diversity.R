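#' Per-sample alpha diversity
#'
#' Shannon entropy H = -sum p log p (natural log), Chao1 richness and
#' Pielou's evenness J = H / log(S_obs). Chao1 defaults to the
#' bias-corrected estimator `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, which is
#' defined even with no doubletons; the classic form
#' `S_obs + F1^2 / (2 F2)` is available via `chao1 = "classic"` (falling
#' back to `F1 (F1 - 1) / 2` when F2 = 0). Pielou is undefined (NA) for
#' samples with fewer than two observed ASVs.
#'
#' @param table an [asv_table()] of integer counts (Chao1 requires counts).
#' @param chao1 `"bias_corrected"` (default) or `"classic"`.
#' @return data.frame with columns `sample`, `shannon`, `chao1`, `pielou`.
#' @export
alpha_diversity <- function(table, chao1 = c("bias_corrected", "classic")) {
  stopifnot(inherits(table, "asv_table"))
  chao1 <- match.arg(chao1)
  if (table$type != "counts")
    warning("Chao1 assumes integer counts; table is in relative abundances")
  m <- table$counts
  res <- t(apply(m, 1, function(x) {
    x <- x[x > 0]
    s <- length(x)
    if (s == 0) return(c(shannon = 0, chao1 = 0, pielou = NA_real_))
    p <- x / sum(x)
    h <- -sum(p * log(p))
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    c1 <- if (chao1 == "bias_corrected") {
      s + f1 * (f1 - 1) / (2 * (f2 + 1))
    } else if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / 2
    j <- if (s > 1) h / log(s) else NA_real_
    c(shannon = h, chao1 = c1, pielou = j)
  }))
  data.frame(sample = rownames(m), res, row.names = rownames(m))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = 1 - 2 sum min(x_i, y_i) / sum (x_i + y_i)`. A pair of
#' all-zero rows has undefined dissimilarity; it is set to 0 by convention
#' and the affected samples are recorded in attribute `empty_samples`.
#'
#' @param m numeric matrix (samples x features), non-negative; e.g. counts,
#'   relative abundances or a Hellinger-transformed table.
#' @return symmetric `dist`-like square matrix with zero diagonal, entries
#'   in `[0, 1]`, labelled by row names.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("Bray-Curtis requires non-negative data")
  n <- nrow(m)
  rs <- rowSums(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- rs[i] + rs[j]
      d[i, j] <- d[j, i] <- if (tot == 0) 0 else
        1 - 2 * sum(pmin(m[i, ], m[j, ])) / tot
    }
  }
  attr(d, "empty_samples") <- rownames(m)[rs == 0]
  d
}

#' Non-metric multidimensional scaling by iterative majorization
#'
#' Minimizes Kruskal stress-1 with alternating steps: monotone (isotonic)
#' regression of configuration distances on the observed dissimilarity
#' order to obtain disparities, then a Guttman-transform update of the
#' configuration. Both steps are guaranteed not to increase stress, so the
#' per-iteration stress trace is non-increasing. The best of `n_starts`
#' initializations is returned; the first start is the classical
#' metric-MDS (principal coordinates) configuration, the rest are random.
#'
#' @param d square symmetric dissimilarity matrix.
#' @param k embedding dimension (default 2).
#' @param n_starts number of initializations (first is classical MDS).
#' @param max_iter majorization iterations per start.
#' @param tol stop when the stress decrease falls below `tol`.
#' @param seed integer seed for the random starts.
#' @return list with `points` (n x k), `stress` (Kruskal stress-1),
#'   `stress_trace` of the winning start, and `converged`.
#' @export
nmds <- function(d, k = 2, n_starts = 4, max_iter = 500, tol = 1e-6,
                 seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < k + 1) stop("need at least k + 1 points")
  labs <- rownames(d)
  up <- upper.tri(d)
  dv <- d[up]
  ord <- order(dv)

  config_dist <- function(x) as.matrix(dist(x))

  one_start <- function(x0) {
    x <- scale(x0, scale = FALSE)
    trace <- numeric()
    prev <- Inf
    best_x <- x
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dc <- config_dist(x)
      dcv <- dc[up]
      # disparities: isotonic regression of configuration distances on the
      # rank order of the dissimilarities
      fit <- isoreg(dcv[ord])
      dhat <- numeric(length(dcv))
      dhat[ord] <- fit$yf
      ss <- sum(dcv^2)
      stress <- sqrt(sum((dcv - dhat)^2) / ss)
      if (stress > prev) break  # scale drift: keep the best stress reached
      trace <- c(trace, stress)
      best_x <- x
      if (prev - stress < tol) {
        converged <- TRUE
        break
      }
      prev <- stress
      # Guttman transform with disparities dhat
      dh <- matrix(0, n, n)
      dh[up] <- dhat
      dh <- dh + t(dh)
      ratio <- ifelse(dc > 0, dh / dc, 0)
      b <- -ratio
      diag(b) <- rowSums(ratio)
      x <- (b %*% x) / n
    }
    list(points = best_x, stress = trace[length(trace)], trace = trace,
         converged = converged)
  }

  set.seed(seed)
  starts <- vector("list", n_starts)
  cm <- tryCatch(cmdscale(d, k = k), error = function(e) NULL)
  starts[[1]] <- if (!is.null(cm) && ncol(cm) == k) cm else
    matrix(rnorm(n * k), n, k)
  if (n_starts > 1)
    for (s in 2:n_starts) starts[[s]] <- matrix(rnorm(n * k), n, k)

  fits <- lapply(starts, one_start)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "stress"))]]
  pts <- best$points
  dimnames(pts) <- list(labs, paste0("NMDS", seq_len(k)))
  if (!best$converged)
    warning("NMDS did not converge; returning best configuration found")
  list(points = pts, stress = best$stress, stress_trace = best$trace,
       converged = best$converged)
}
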