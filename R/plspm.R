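#' Specify a PLS path model
#'
#' Defines the measurement (outer) model as named indicator blocks and the
#' structural (inner) model as a lower-triangular adjacency over the
#' latents. All blocks are reflective (mode A). The inner weighting scheme
#' defaults to the path scheme.
#'
#' @param blocks named list: latent name -> character vector of indicator
#'   column names (>= 1 each).
#' @param paths square numeric/logical matrix over the latents (rows and
#'   columns ordered as `names(blocks)`); `paths[i, j] != 0` means latent j
#'   predicts latent i. Must be strictly lower triangular (acyclic).
#' @param scheme inner weighting scheme: `"path"` (default), `"factor"` or
#'   `"centroid"`.
#' @param max_iter maximum outer/inner alternations.
#' @param tol convergence tolerance on the outer weights.
#' @return object of class `plspm_spec`.
#' @export
plspm_spec <- function(blocks, paths, scheme = c("path", "factor", "centroid"),
                       max_iter = 300, tol = 1e-8) {
  scheme <- match.arg(scheme)
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    stop("blocks must be a named list")
  if (any(vapply(blocks, length, integer(1)) < 1))
    stop("every latent needs at least one indicator")
  paths <- as.matrix(paths) * 1
  p <- length(blocks)
  if (!all(dim(paths) == p))
    stop("paths must be a ", p, " x ", p, " matrix over the latents")
  if (any(paths[upper.tri(paths, diag = TRUE)] != 0))
    stop("paths must be strictly lower triangular (acyclic inner model)")
  dimnames(paths) <- list(names(blocks), names(blocks))
  structure(list(blocks = blocks, paths = paths, scheme = scheme,
                 max_iter = max_iter, tol = tol), class = "plspm_spec")
}

#' Fit a PLS path model
#'
#' Lohmoeller-style alternating estimation with reflective (mode A)
#' measurement: standardized indicators are combined into latent scores by
#' outer weights; inner proxies are formed from adjacent latents under the
#' chosen scheme (path: regression weights on predecessors plus
#' correlations with successors); new outer weights are the covariances of
#' each indicator with its block's inner proxy; iterate until the maximum
#' outer-weight change falls below the tolerance. Afterwards loadings are
#' indicator-score correlations, and path coefficients come from OLS of
#' each endogenous latent score on its predecessors' scores. Latent scores
#' are standardized to unit variance, and each latent's sign is aligned so
#' that the sum of its loadings is positive.
#'
#' @param data data.frame containing every indicator column; rows with
#'   missing indicator values are dropped (with a message).
#' @param spec a [plspm_spec()].
#' @return object of class `plspm_fit` with elements `weights`, `loadings`
#'   (data.frame), `scores`, `path_coefficients` (matrix, entry (i, j) =
#'   effect of latent j on latent i), `r_squared`, `communality`, `gof`,
#'   `iterations`, `spec`, `n`.
#' @export
fit_plspm <- function(data, spec) {
  stopifnot(inherits(spec, "plspm_spec"))
  inds <- unlist(spec$blocks, use.names = FALSE)
  missing_cols <- setdiff(inds, names(data))
  if (length(missing_cols))
    stop("indicator columns missing from data: ",
         paste(missing_cols, collapse = ", "))
  X <- as.matrix(data[, inds, drop = FALSE])
  keep <- stats::complete.cases(X)
  if (!all(keep)) message(sum(!keep), " rows with missing values dropped")
  X <- X[keep, , drop = FALSE]
  n <- nrow(X)
  if (n < 10) stop("need at least 10 complete rows")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant indicator column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  X <- scale(X)

  lat <- names(spec$blocks)
  p <- length(lat)
  P <- spec$paths
  neighbors <- (P + t(P)) != 0
  block_idx <- lapply(spec$blocks, function(b) match(b, inds))

  w <- lapply(spec$blocks, function(b) rep(1, length(b)))
  scores <- function(w) {
    Y <- sapply(seq_len(p), function(l) {
      y <- X[, block_idx[[l]], drop = FALSE] %*% w[[l]]
      as.numeric(scale(y))
    })
    colnames(Y) <- lat
    Y
  }

  iter <- 0
  repeat {
    iter <- iter + 1
    Y <- scores(w)
    R <- cor(Y)
    E <- matrix(0, p, p, dimnames = list(lat, lat))
    for (i in seq_len(p)) {
      nb <- which(neighbors[i, ])
      if (length(nb) == 0) next
      if (spec$scheme == "centroid") {
        E[i, nb] <- sign(R[i, nb])
      } else if (spec$scheme == "factor") {
        E[i, nb] <- R[i, nb]
      } else {  # path scheme
        pred <- which(P[i, ] != 0)
        succ <- setdiff(nb, pred)
        if (length(pred))
          E[i, pred] <- solve(R[pred, pred, drop = FALSE],
                              R[pred, i, drop = FALSE])
        if (length(succ)) E[i, succ] <- R[i, succ]
      }
    }
    Z <- Y %*% t(E)
    w_new <- lapply(seq_len(p), function(l) {
      z <- if (all(Z[, l] == 0)) Y[, l] else Z[, l]  # isolated latent
      as.numeric(cor(X[, block_idx[[l]], drop = FALSE], z))
    })
    delta <- max(mapply(function(a, b) max(abs(abs(a) / sqrt(sum(a^2)) -
                                                 abs(b) / sqrt(sum(b^2)))),
                        w_new, w))
    w <- w_new
    if (delta < spec$tol) break
    if (iter >= spec$max_iter)
      stop("PLS-PM did not converge in ", spec$max_iter,
           " iterations (last delta = ", format(delta), ")")
  }

  Y <- scores(w)
  # sign convention: each latent correlates positively with its block
  for (l in seq_len(p)) {
    ld <- cor(X[, block_idx[[l]], drop = FALSE], Y[, l])
    if (sum(ld) < 0) {
      Y[, l] <- -Y[, l]
      w[[l]] <- -w[[l]]
    }
  }

  loadings <- do.call(rbind, lapply(seq_len(p), function(l)
    data.frame(latent = lat[l], indicator = spec$blocks[[l]],
               loading = as.numeric(cor(X[, block_idx[[l]], drop = FALSE],
                                        Y[, l])),
               stringsAsFactors = FALSE)))

  path_coef <- matrix(0, p, p, dimnames = list(lat, lat))
  r2 <- setNames(rep(NA_real_, p), lat)
  for (i in seq_len(p)) {
    pred <- which(P[i, ] != 0)
    if (length(pred) == 0) next
    fit <- lm(Y[, i] ~ Y[, pred, drop = FALSE])
    path_coef[i, pred] <- coef(fit)[-1]
    r2[i] <- summary(fit)$r.squared
  }

  communality <- setNames(loadings$loading^2, loadings$indicator)
  endo <- !is.na(r2)
  gof <- sqrt(mean(communality) * mean(r2[endo]))

  structure(list(weights = setNames(w, lat), loadings = loadings,
                 scores = Y, path_coefficients = path_coef,
                 r_squared = r2, communality = communality, gof = gof,
                 iterations = iter, spec = spec, n = n),
            class = "plspm_fit")
}

#' @export
print.plspm_fit <- function(x, ...) {
  cat(sprintf("plspm_fit: %d latents, %d indicators, n = %d, gof = %.4f\n",
              length(x$spec$blocks), nrow(x$loadings), x$n, x$gof))
  invisible(x)
}

#' Goodness-of-fit of a PLS path model
#'
#' `gof = sqrt(mean communality x mean R^2)` over reflective indicators
#' and endogenous latents respectively.
#'
#' @param fit a `plspm_fit`.
#' @return scalar in `[0, 1]`.
#' @export
gof <- function(fit) {
  stopifnot(inherits(fit, "plspm_fit"))
  fit$gof
}

#' Iteratively remove weakly loading indicators and refit
#'
#' Indicators with `|loading| < threshold` are removed and the model is
#' refit, repeating until all surviving loadings reach the threshold. If a
#' pass would leave a block empty, an error names the block.
#'
#' @param fit a fitted `plspm_fit`.
#' @param data the data used for fitting.
#' @param threshold minimum absolute loading (default 0.7).
#' @return a refit `plspm_fit` (identical spec if nothing was pruned) with
#'   attribute `pruned` listing removed indicators.
#' @export
prune_loadings <- function(fit, data, threshold = 0.7) {
  stopifnot(inherits(fit, "plspm_fit"))
  spec <- fit$spec
  removed <- character()
  repeat {
    weak <- fit$loadings$indicator[abs(fit$loadings$loading) < threshold]
    if (length(weak) == 0) break
    blocks <- lapply(spec$blocks, setdiff, y = weak)
    empty <- names(blocks)[vapply(blocks, length, integer(1)) == 0]
    if (length(empty))
      stop("pruning at threshold ", threshold,
           " would empty block(s): ", paste(empty, collapse = ", "))
    removed <- c(removed, weak)
    spec <- plspm_spec(blocks, spec$paths, scheme = spec$scheme,
                       max_iter = spec$max_iter, tol = spec$tol)
    fit <- fit_plspm(data, spec)
  }
  attr(fit, "pruned") <- removed
  fit
}

#' Bootstrap confidence intervals for a PLS path model
#'
#' Resamples rows with replacement, refits, and reports percentile
#' confidence intervals for path coefficients and loadings. A path or
#' loading is flagged significant when its interval excludes zero.
#' Replicates that fail to fit (e.g. a constant indicator in the resample)
#' are skipped and counted.
#'
#' @param data data.frame of indicators.
#' @param spec a [plspm_spec()].
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return list with `fit` (full-data fit), `paths` (data.frame `from`,
#'   `to`, `estimate`, `boot_mean`, `lower`, `upper`, `significant`),
#'   `loadings` (analogous), `n_boot`, `n_skipped`.
#' @export
bootstrap_plspm <- function(data, spec, n_boot = 1000, seed = 1L,
                            conf = 0.95) {
  fit <- fit_plspm(data, spec)
  lat <- names(spec$blocks)
  P <- spec$paths
  pairs <- which(P != 0, arr.ind = TRUE)
  n <- fit$n
  alpha <- (1 - conf) / 2

  set.seed(seed)
  path_boot <- matrix(NA_real_, n_boot, nrow(pairs))
  load_boot <- matrix(NA_real_, n_boot, nrow(fit$loadings))
  skipped <- 0
  for (b in seq_len(n_boot)) {
    idx <- sample(n, replace = TRUE)
    fb <- tryCatch(suppressMessages(fit_plspm(data[idx, , drop = FALSE], spec)),
                   error = function(e) NULL)
    if (is.null(fb)) {
      skipped <- skipped + 1
      next
    }
    path_boot[b, ] <- fb$path_coefficients[pairs]
    load_boot[b, ] <- fb$loadings$loading
  }

  ci <- function(m) t(apply(m, 2, quantile, probs = c(alpha, 1 - alpha),
                            na.rm = TRUE))
  pci <- ci(path_boot)
  paths_df <- data.frame(
    from = lat[pairs[, 2]], to = lat[pairs[, 1]],
    estimate = fit$path_coefficients[pairs],
    boot_mean = colMeans(path_boot, na.rm = TRUE),
    lower = pci[, 1], upper = pci[, 2], stringsAsFactors = FALSE)
  paths_df$significant <- paths_df$lower > 0 | paths_df$upper < 0
  lci <- ci(load_boot)
  loads_df <- cbind(fit$loadings,
                    boot_mean = colMeans(load_boot, na.rm = TRUE),
                    lower = lci[, 1], upper = lci[, 2])
  loads_df$significant <- loads_df$lower > 0 | loads_df$upper < 0
  list(fit = fit, paths = paths_df, loadings = loads_df,
       n_boot = n_boot, n_skipped = skipped, seed = seed, conf = conf)
}

#' Direct, indirect and total effects between latents
#'
#' Direct effect = path coefficient; indirect effect = sum over all
#' directed paths of length >= 2 of the products of coefficients along the
#' path; total = direct + indirect.
#'
#' @param fit a `plspm_fit`.
#' @return data.frame `from`, `to`, `direct`, `indirect`, `total` for every
#'   ordered latent pair reachable in the inner model ordering.
#' @export
effects_decomposition <- function(fit) {
  stopifnot(inherits(fit, "plspm_fit"))
  P <- fit$path_coefficients
  p <- nrow(P)
  total <- matrix(0, p, p, dimnames = dimnames(P))
  acc <- diag(p)
  for (k in seq_len(p - 1)) {
    acc <- acc %*% P
    total <- total + acc
  }
  idx <- which(lower.tri(total), arr.ind = TRUE)
  data.frame(from = colnames(P)[idx[, 2]], to = rownames(P)[idx[, 1]],
             direct = P[idx], indirect = (total - P)[idx],
             total = total[idx], stringsAsFactors = FALSE)
}
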