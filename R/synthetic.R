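#' Define a synthetic size-fractionated community scenario
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object. The generator emulates the statistical structure the downstream
#' pipeline assumes: zero-inflated overdispersed counts whose log-scale
#' dependence follows a known sparse precision matrix, seasonal
#' environmental gradients, cross-fraction ASV sharing at prescribed
#' abundance ratios, and cytometry counts coupled to the environment.
#'
#' Each fraction carries `n_eligible` "core" ASVs whose latent
#' log-abundances are jointly multivariate normal with covariance equal to
#' the inverse of `true_precision` (dimension = total core ASVs across
#' fractions), plus `n_noise` independent rare ASVs. The support of the
#' off-diagonal precision entries is the ground-truth conditional-dependence
#' edge set returned by [generate_counts()].
#'
#' @param n_seasons number of seasons (categorical sample blocks).
#' @param samples_per_season samples per season.
#' @param n_eligible integer vector (bacteria, pico, nano): core ASVs per
#'   fraction governed by the precision matrix.
#' @param n_noise independent low-abundance ASVs per fraction.
#' @param true_precision symmetric positive-definite matrix over all core
#'   ASVs; default a chain graph from [chain_precision()].
#' @param sequencing_depth mean reads per sample.
#' @param depth_dispersion negative-binomial size parameter for per-sample
#'   depth variation (larger = less variable).
#' @param zero_inflation probability in `[0, 1]` that any count is replaced
#'   by zero after sampling.
#' @param season_effect multiplier on seasonal environmental mean contrasts
#'   (0 = no seasonal signal; 1 = defaults).
#' @param composition_effect standard deviation of the per-season shift
#'   added to latent ASV means (community seasonality).
#' @param env_coupling slope of log10 cytometry abundance on standardized
#'   temperature.
#' @param cytometry_sd log10-scale noise of cytometry counts.
#' @param contamination_pairs data.frame(`pico_asv`, `nano_asv`, `ratio`)
#'   passed to [inject_cross_fraction_contamination()], or `NULL`.
#' @param seed integer seed; all generators are bit-reproducible given it.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_seasons = 4, samples_per_season = 10,
                               n_eligible = c(bacteria = 20, pico = 20, nano = 20),
                               n_noise = c(bacteria = 40, pico = 40, nano = 40),
                               true_precision = NULL,
                               sequencing_depth = 2e4,
                               depth_dispersion = 20,
                               zero_inflation = 0.1,
                               season_effect = 1,
                               composition_effect = 0.4,
                               env_coupling = 0.3,
                               cytometry_sd = 0.15,
                               contamination_pairs = NULL,
                               seed = 1L) {
  if (n_seasons < 1 || samples_per_season < 1)
    stop("sample counts must be positive")
  p_core <- sum(n_eligible)
  if (is.null(true_precision)) true_precision <- chain_precision(p_core)
  true_precision <- as.matrix(true_precision)
  if (nrow(true_precision) != p_core)
    stop("true_precision dimension must equal total core ASVs")
  if (max(abs(true_precision - t(true_precision))) > 1e-10)
    stop("true_precision must be symmetric")
  ev <- eigen(true_precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("true_precision must be positive definite")
  if (sequencing_depth <= 0) stop("sequencing_depth must be > 0")
  if (zero_inflation < 0 || zero_inflation > 1)
    stop("zero_inflation must be in [0, 1]")
  structure(list(
    n_seasons = n_seasons, samples_per_season = samples_per_season,
    n_eligible = n_eligible, n_noise = n_noise,
    true_precision = true_precision,
    sequencing_depth = sequencing_depth,
    depth_dispersion = depth_dispersion,
    zero_inflation = zero_inflation,
    season_effect = season_effect,
    composition_effect = composition_effect,
    env_coupling = env_coupling, cytometry_sd = cytometry_sd,
    contamination_pairs = contamination_pairs,
    seed = as.integer(seed)
  ), class = "synthetic_scenario")
}

#' Tridiagonal chain-graph precision matrix
#'
#' @param p dimension.
#' @param rho off-diagonal entry magnitude; positive definite for
#'   `|rho| < 0.5`.
#' @return p x p symmetric positive-definite matrix whose conditional
#'   dependence graph is the path 1-2-...-p.
#' @export
chain_precision <- function(p, rho = 0.4) {
  m <- diag(p)
  for (i in seq_len(p - 1)) m[i, i + 1] <- m[i + 1, i] <- -rho
  m
}

#' Random sparse positive-definite precision matrix
#'
#' Erdos-Renyi support with fixed edge magnitude, made positive definite by
#' diagonal loading.
#'
#' @param p dimension.
#' @param edge_prob probability that each off-diagonal pair carries an edge.
#' @param magnitude absolute value of nonzero partial covariances; sign
#'   random.
#' @param seed integer seed.
#' @return p x p symmetric positive-definite matrix.
#' @export
random_sparse_precision <- function(p, edge_prob = 2 / p, magnitude = 0.3,
                                    seed = 1L) {
  set.seed(seed)
  m <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (runif(1) < edge_prob) {
      v <- magnitude * sign(runif(1) - 0.5)
      m[i, j] <- m[j, i] <- v
    }
  }
  diag(m) <- rowSums(abs(m)) + 0.5
  m
}

season_names <- function(n) {
  base <- c("winter", "spring", "summer", "autumn")
  if (n <= 4) base[seq_len(n)] else paste0("season", seq_len(n))
}

scenario_samples <- function(scenario) {
  seasons <- rep(season_names(scenario$n_seasons),
                 each = scenario$samples_per_season)
  n <- length(seasons)
  data.frame(
    sample = sprintf("S%03d", seq_len(n)),
    season = seasons,
    layer = rep_len(c("surface", "bottom"), n),
    station = paste0("ST", rep_len(seq_len(max(1, scenario$samples_per_season %/% 2)),
                                   n)),
    stringsAsFactors = FALSE
  )
}

# season-specific environmental means for a subtropical mariculture bay;
# deviations from the annual mean scale with season_effect
env_season_means <- function(seasons, effect) {
  base <- list(
    temperature = c(winter = 16, spring = 21, summer = 28, autumn = 23),
    salinity    = c(winter = 32.5, spring = 31.5, summer = 30.5, autumn = 31.8),
    DO          = c(winter = 8.5, spring = 7.5, summer = 6.2, autumn = 7.0),
    TN          = c(winter = 0.75, spring = 0.60, summer = 0.45, autumn = 0.55),
    TP          = c(winter = 0.055, spring = 0.045, summer = 0.035, autumn = 0.050),
    chla        = c(winter = 1.5, spring = 3.5, summer = 5.0, autumn = 2.5)
  )
  lapply(base, function(v) {
    v <- v[match(seasons, names(v))]
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    m <- mean(v)
    m + effect * (v - m)
  })
}

env_noise_sd <- c(temperature = 0.8, salinity = 0.4, DO = 0.35,
                  TN = 0.06, TP = 0.006, chla = 0.6)

#' Generate a seeded environmental table
#'
#' One row per sample with season, layer and station labels plus
#' temperature (deg C), salinity (PSU), dissolved oxygen (mg/L), total
#' nitrogen and phosphorus (mg/L) and chlorophyll a (ug/L), drawn from
#' season-specific means with Gaussian noise.
#'
#' @param scenario a [synthetic_scenario()].
#' @return data.frame, one row per sample.
#' @export
generate_env_table <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed + 101L)
  meta <- scenario_samples(scenario)
  means <- env_season_means(meta$season, scenario$season_effect)
  n <- nrow(meta)
  for (v in names(means))
    meta[[v]] <- means[[v]] + rnorm(n, 0, env_noise_sd[[v]])
  rownames(meta) <- meta$sample
  meta
}

protist_trophic_pool <- function(fraction) {
  if (fraction == "pico")
    c(parasite = 0.4, heterotroph = 0.25, photoautotroph = 0.2,
      mixotroph = 0.1, symbiont = 0.05)
  else
    c(mixotroph = 0.35, photoautotroph = 0.25, heterotroph = 0.25,
      parasite = 0.1, symbiont = 0.05)
}

make_asv_data <- function(fraction, ids, n_eligible) {
  classes <- if (fraction == "bacteria") {
    c("Alphaproteobacteria", "Gammaproteobacteria", "Bacteroidia",
      "Cyanobacteriia", "Acidimicrobiia")
  } else {
    c("Syndiniales", "Dinophyceae", "Bacillariophyta", "Ciliophora",
      "Chlorophyta", "Cercozoa")
  }
  d <- data.frame(
    taxonomy = sample(classes, length(ids), replace = TRUE),
    network_eligible = seq_along(ids) <= n_eligible,
    stringsAsFactors = FALSE
  )
  if (fraction != "bacteria") {
    pool <- protist_trophic_pool(fraction)
    d$trophic_mode <- sample(names(pool), length(ids), replace = TRUE,
                             prob = pool)
  }
  rownames(d) <- ids
  d
}

#' Generate count tables for the three size fractions with known structure
#'
#' Latent log-abundances of the core ASVs are drawn from a multivariate
#' normal whose covariance is the inverse of the scenario's precision
#' matrix (logistic-normal-multinomial model: latent MVN, softmax within
#' fraction, multinomial at a negative-binomial per-sample depth, then
#' Bernoulli zero-inflation). Noise ASVs get independent latent variation
#' at lower mean abundance. The returned `true_edges` are the support of
#' the off-diagonal precision entries, for network-recovery testing.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `bacteria`, `pico`, `nano` ([asv_table()]s),
#'   `true_edges` (data.frame `from`, `to` in global ASV ids),
#'   `eligible_ids` (global ids of core ASVs) and `latent` (matrix of core
#'   latent log-abundances, for diagnostics).
#' @export
generate_counts <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed + 202L)
  meta <- scenario_samples(scenario)
  n <- nrow(meta)
  fractions <- c("bacteria", "pico", "nano")
  prefix <- c(bacteria = "B", pico = "P", nano = "N")
  n_elig <- scenario$n_eligible
  n_noise <- scenario$n_noise
  p_core <- sum(n_elig)

  sigma <- solve(scenario$true_precision)
  core_ids <- unlist(lapply(fractions, function(f) {
    if (n_elig[[f]] == 0) return(character())
    paste0(prefix[[f]], "_ASV", sprintf("%03d", seq_len(n_elig[[f]])))
  }))

  # season-specific latent mean shifts (community seasonality)
  seasons <- unique(meta$season)
  shift_core <- matrix(rnorm(length(seasons) * p_core, 0,
                             scenario$composition_effect),
                       length(seasons), p_core,
                       dimnames = list(seasons, NULL))

  mu_core <- rnorm(p_core, 2.0, 0.4)
  z_core <- MASS::mvrnorm(n, rep(0, p_core), sigma)
  z_core <- z_core + matrix(mu_core, n, p_core, byrow = TRUE) +
    shift_core[meta$season, , drop = FALSE]
  rownames(z_core) <- meta$sample
  colnames(z_core) <- core_ids

  out <- list()
  offset <- 0
  for (f in fractions) {
    pe <- n_elig[[f]]
    pn <- n_noise[[f]]
    if (pe + pn == 0) next
    ids_e <- core_ids[offset + seq_len(pe)]
    ids_n <- if (pn > 0)
      paste0(prefix[[f]], "_noise", sprintf("%03d", seq_len(pn)))
    else character()
    offset <- offset + pe

    z <- z_core[, ids_e, drop = FALSE]
    if (pn > 0) {
      mu_noise <- rnorm(pn, -4, 1.5)
      shift_noise <- matrix(rnorm(length(seasons) * pn, 0,
                                  scenario$composition_effect),
                            length(seasons), pn, dimnames = list(seasons, NULL))
      z_noise <- matrix(rnorm(n * pn, 0, 1), n, pn) +
        matrix(mu_noise, n, pn, byrow = TRUE) +
        shift_noise[meta$season, , drop = FALSE]
      z <- cbind(z, z_noise)
    }
    colnames(z) <- c(ids_e, ids_n)

    probs <- exp(z - apply(z, 1, max))
    probs <- probs / rowSums(probs)
    depth <- rnbinom(n, size = scenario$depth_dispersion,
                     mu = scenario$sequencing_depth)
    counts <- t(vapply(seq_len(n), function(i)
      rmultinom(1, depth[i], probs[i, ])[, 1], numeric(ncol(z))))
    if (scenario$zero_inflation > 0)
      counts[matrix(runif(length(counts)) < scenario$zero_inflation,
                    nrow(counts))] <- 0
    dimnames(counts) <- list(meta$sample, colnames(z))
    out[[f]] <- asv_table(counts, f, sample_data = meta,
                          asv_data = make_asv_data(f, colnames(z), pe))
  }

  prec <- scenario$true_precision
  idx <- which(upper.tri(prec) & prec != 0, arr.ind = TRUE)
  true_edges <- data.frame(from = core_ids[idx[, 1]], to = core_ids[idx[, 2]],
                           stringsAsFactors = FALSE)
  if (!is.null(scenario$contamination_pairs) &&
      !is.null(out$pico) && !is.null(out$nano)) {
    inj <- inject_cross_fraction_contamination(out$pico, out$nano,
                                               scenario$contamination_pairs)
    out$pico <- inj$pico
    out$nano <- inj$nano
  }
  list(bacteria = out$bacteria, pico = out$pico, nano = out$nano,
       true_edges = true_edges, eligible_ids = core_ids, latent = z_core)
}

#' Inject cross-fraction contamination at prescribed abundance ratios
#'
#' Emulates the filter-artifact that [resolve_shared_asvs()] must remove:
#' for each pair, the pico ASV's id is made shared with the nano fraction by
#' inserting a scaled copy of its abundance profile into the nano table so
#' that the realized mean relative-abundance ratio (nano / pico) matches the
#' prescribed target. If `nano_asv` names an existing nano column, that
#' column is replaced (the two ids are treated as the same organism);
#' otherwise a new column is added. Copying scaled counts rather than
#' resampling keeps the target ratio controllable.
#'
#' @param pico,nano [asv_table()]s of counts sharing a sample set.
#' @param pairs data.frame with columns `pico_asv`, `ratio` and optionally
#'   `nano_asv`.
#' @return list with modified `pico` and `nano` tables.
#' @export
inject_cross_fraction_contamination <- function(pico, nano, pairs) {
  stopifnot(inherits(pico, "asv_table"), inherits(nano, "asv_table"))
  if (is.null(pairs) || nrow(pairs) == 0) return(list(pico = pico, nano = nano))
  if (!setequal(rownames(pico$counts), rownames(nano$counts)))
    stop("tables must share sample set")
  for (k in seq_len(nrow(pairs))) {
    pa <- as.character(pairs$pico_asv[k])
    ratio <- pairs$ratio[k]
    if (!pa %in% colnames(pico$counts)) stop("unknown pico ASV id: ", pa)
    na_id <- if ("nano_asv" %in% names(pairs)) as.character(pairs$nano_asv[k]) else NA
    rel_p <- pico$counts[, pa] / pmax(rowSums(pico$counts), 1)
    base <- nano$counts
    if (!is.na(na_id) && na_id %in% colnames(base))
      base <- base[, setdiff(colnames(base), na_id), drop = FALSE]
    rs <- rowSums(base)
    target_rel <- pmin(ratio * rel_p[rownames(base)], 0.99)
    new_counts <- round(target_rel * rs / (1 - target_rel))
    add <- matrix(new_counts, ncol = 1, dimnames = list(rownames(base), pa))
    nano_counts <- cbind(base, add)
    ad <- nano$asv_data
    if (!is.null(ad)) {
      ad <- ad[colnames(base), , drop = FALSE]
      src <- pico$asv_data
      newrow <- if (!is.null(src) && pa %in% rownames(src) &&
                    all(names(ad) %in% names(src)))
        src[pa, names(ad), drop = FALSE]
      else ad[1, , drop = FALSE]
      rownames(newrow) <- pa
      ad <- rbind(ad, newrow)
    }
    nano <- asv_table(nano_counts, nano$fraction, nano$sample_data,
                      asv_data = ad, type = nano$type)
  }
  list(pico = pico, nano = nano)
}

#' Generate flow-cytometry / microscopy abundance counts
#'
#' Per-sample abundances (cells/mL) of heterotrophic bacteria (HB),
#' Synechococcus (Syn), photosynthetic picoeukaryotes (PPE) and
#' heterotrophic / pigmented nanoflagellates (HNF, PNF), log-normal around
#' group base abundances with a configurable log10-linear coupling to
#' standardized temperature.
#'
#' @param env data.frame from [generate_env_table()] (needs a `temperature`
#'   column when `env_coupling != 0`).
#' @param scenario a [synthetic_scenario()].
#' @return data.frame with columns `sample`, `HB`, `Syn`, `PPE`, `HNF`,
#'   `PNF`; strictly positive.
#' @export
generate_cytometry <- function(env, scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"), nrow(env) >= 1)
  set.seed(scenario$seed + 303L)
  base_log10 <- c(HB = 6, Syn = 5, PPE = 4, HNF = 3, PNF = 3)
  n <- nrow(env)
  tstd <- if (scenario$env_coupling != 0) {
    tt <- env$temperature
    if (sd(tt) > 0) (tt - mean(tt)) / sd(tt) else rep(0, n)
  } else rep(0, n)
  out <- data.frame(sample = rownames(env), stringsAsFactors = FALSE)
  for (g in names(base_log10)) {
    lg <- base_log10[[g]] + scenario$env_coupling * tstd +
      rnorm(n, 0, scenario$cytometry_sd)
    out[[g]] <- 10^lg
  }
  rownames(out) <- out$sample
  out
}

#' Generate indicator data from a known latent path model
#'
#' Ground truth for PLS path-model recovery tests. Latent scores follow the
#' standardized structural equations of an acyclic inner model
#' (`path_matrix[i, j]` = coefficient of latent j on latent i, strictly
#' lower triangular); each latent has unit variance. Indicators are
#' `loading * latent + sqrt(1 - loading^2) * noise`, so population
#' indicator-latent correlations equal the loadings.
#'
#' @param path_matrix strictly lower-triangular numeric matrix of
#'   standardized path coefficients.
#' @param loadings list (one element per latent) of loading vectors in
#'   `(0, 1]`; element length = number of indicators of that latent.
#' @param n number of rows to draw.
#' @param seed integer seed.
#' @return list with `indicators` (data.frame), `latents` (matrix of true
#'   scores) and `blocks` (named list mapping latent -> indicator columns).
#' @export
generate_latent_path_data <- function(path_matrix, loadings, n, seed = 1L) {
  path_matrix <- as.matrix(path_matrix)
  p <- nrow(path_matrix)
  if (any(path_matrix[upper.tri(path_matrix, diag = TRUE)] != 0))
    stop("path_matrix must be strictly lower triangular (acyclic inner model)")
  if (length(loadings) != p) stop("one loading vector per latent required")
  if (any(unlist(loadings) <= 0 | unlist(loadings) > 1))
    stop("loadings must be in (0, 1]")
  lat_names <- rownames(path_matrix)
  if (is.null(lat_names)) lat_names <- paste0("LV", seq_len(p))

  # implied latent covariance (unit variances) to size residuals
  S <- diag(p)
  for (i in seq_len(p)) {
    b <- path_matrix[i, seq_len(i - 1), drop = TRUE]
    if (i > 1 && any(b != 0)) {
      Sb <- S[seq_len(i - 1), seq_len(i - 1), drop = FALSE]
      v <- as.numeric(t(b) %*% Sb %*% b)
      if (v >= 1) stop("path coefficients imply variance >= 1 for latent ", i)
      S[i, seq_len(i - 1)] <- S[seq_len(i - 1), seq_len(i - 1)] %*% b
      S[seq_len(i - 1), i] <- S[i, seq_len(i - 1)]
    }
  }

  set.seed(seed)
  xi <- matrix(0, n, p)
  for (i in seq_len(p)) {
    pred <- if (i > 1) xi[, seq_len(i - 1), drop = FALSE] %*%
      path_matrix[i, seq_len(i - 1)] else 0
    v <- if (i > 1) {
      b <- path_matrix[i, seq_len(i - 1)]
      as.numeric(t(b) %*% S[seq_len(i - 1), seq_len(i - 1)] %*% b)
    } else 0
    xi[, i] <- pred + rnorm(n, 0, sqrt(max(1 - v, 0)))
  }
  colnames(xi) <- lat_names

  blocks <- list()
  ind <- list()
  for (i in seq_len(p)) {
    lam <- loadings[[i]]
    cols <- paste0(lat_names[i], "_x", seq_along(lam))
    for (k in seq_along(lam))
      ind[[cols[k]]] <- lam[k] * xi[, i] +
        sqrt(1 - lam[k]^2) * rnorm(n)
    blocks[[lat_names[i]]] <- cols
  }
  list(indicators = as.data.frame(ind), latents = xi, blocks = blocks)
}
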