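default_pipeline_config <- function() {
  list(
    seed = 1L,
    filter = list(min_prevalence_fraction = 1 / 3,
                  min_mean_relabund = 0.001,
                  require_all_seasons = TRUE,
                  required_seasons = NULL),
    diversity = list(n_perm = 999, nmds_k = 2),
    network = list(nlambda = 20, lambda_min_ratio = 0.005,
                   stars_threshold = 0.05, n_subsamples = 20,
                   seasonal = TRUE, min_season_samples = 8),
    stability = list(n_iterations = 10000, keystone_percentile = 80),
    plspm = list(n_boot = 1000, loading_threshold = 0.7, prune = TRUE)
  )
}

merge_config <- function(user) {
  cfg <- default_pipeline_config()
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && nm %in% names(cfg))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], user[[nm]])
    else cfg[[nm]] <- user[[nm]]
  }
  cfg
}

#' Run the full size-fractionated community analysis pipeline
#'
#' Orchestrates the seven analysis stages in order -- cross-fraction
#' filtering, diversity, niche breadth, network inference (whole-data
#' interdomain BPN plus the BP and BN two-domain variants and one
#' sub-network per season), network stability (topology, keystones,
#' robustness, efficiency), predator/prey biomass ratios, and the PLS path
#' model -- writing per-stage TSV/JSON/GraphML artifacts and a run manifest
#' with parameter values and file checksums. Inputs come either from a
#' synthetic scenario (`config$scenario`, passed to [synthetic_scenario()])
#' or from TSV paths in `config$inputs` (`bacteria`, `pico`, `nano` count
#' tables, `metadata`, `env`, `cytometry`).
#'
#' Every tunable defaults to the standard analysis parameterization:
#' shared-ASV ratio bounds 2 and 0.5; network ASV prevalence 1/3 and mean
#' relative abundance 0.001; StARS with nlambda 20, minimum lambda ratio
#' 0.005, threshold 0.05, 20 subsamples; 10,000 robustness iterations;
#' keystone percentile 80; 1,000 bootstraps with loading cutoff 0.7.
#'
#' @param config nested list or path to a YAML file.
#' @param outdir output directory (created if needed); defaults to
#'   `config$outdir`.
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- merge_config(config)
  if (is.null(outdir)) outdir <- cfg$outdir
  if (is.null(outdir)) stop("an output directory is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  files <- character()
  warnings_log <- character()
  note <- function(...) {
    msg <- sprintf(...)
    warnings_log <<- c(warnings_log, msg)
    message(msg)
  }
  out_file <- function(name) {
    files <<- c(files, file.path(outdir, name))
    file.path(outdir, name)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- inputs ----
  if (!is.null(cfg$scenario)) {
    scen_args <- cfg$scenario
    if (is.null(scen_args$seed)) scen_args$seed <- seed
    scenario <- stage("simulate", do.call(synthetic_scenario, scen_args))
    sim <- stage("simulate", generate_counts(scenario))
    env <- stage("simulate", generate_env_table(scenario))
    cyto <- stage("simulate", generate_cytometry(env, scenario))
    tabs <- list(bacteria = sim$bacteria, pico = sim$pico, nano = sim$nano)
    write_json_report(list(true_edges = sim$true_edges,
                           eligible_ids = sim$eligible_ids),
                      out_file("ground_truth.json"))
    for (f in names(tabs)) write_asv_table(tabs[[f]], file.path(outdir, f))
    files <- c(files, file.path(outdir, paste0(
      rep(names(tabs), each = 3), c("_counts.tsv", "_samples.tsv", "_asvs.tsv"))))
    write_tsv_matrix(env, out_file("env.tsv"))
    write_tsv_matrix(cyto, out_file("cytometry.tsv"))
  } else if (!is.null(cfg$inputs)) {
    inp <- cfg$inputs
    tabs <- stage("load", list(
      bacteria = read_asv_table(inp$bacteria, "bacteria", inp$metadata,
                                inp$taxonomy_bacteria),
      pico = read_asv_table(inp$pico, "pico", inp$metadata,
                            inp$taxonomy_pico),
      nano = read_asv_table(inp$nano, "nano", inp$metadata,
                            inp$taxonomy_nano)))
    env <- stage("load", read_tsv_matrix(inp$env, as_matrix = FALSE))
    cyto <- stage("load", read_tsv_matrix(inp$cytometry, as_matrix = FALSE))
  } else stop("config needs either a 'scenario' or an 'inputs' block")

  ## ---- stage 1: cross-fraction filter + network ASV selection ----
  res_filter <- stage("filter", {
    required <- cfg$filter$required_seasons
    if (is.null(required))
      required <- unique(tabs$bacteria$sample_data$season)
    for (f in names(tabs)) {
      seen <- unique(tabs[[f]]$sample_data$season)
      miss <- setdiff(required, seen)
      if (length(miss))
        stop("season coverage: fraction '", f, "' is missing season(s): ",
             paste(miss, collapse = ", "))
    }
    shared <- resolve_shared_asvs(tabs$pico, tabs$nano)
    tabs$pico <- shared$pico
    tabs$nano <- shared$nano
    selected <- lapply(tabs, function(tb)
      select_network_asvs(tb,
        min_prevalence_fraction = cfg$filter$min_prevalence_fraction,
        min_mean_relabund = cfg$filter$min_mean_relabund,
        require_all_seasons = cfg$filter$require_all_seasons))
    write_json_report(shared$report, out_file("shared_asv_report.json"))
    list(tables = tabs, selected = selected, report = shared$report)
  })
  tabs <- res_filter$tables
  selected <- res_filter$selected
  meta <- tabs$bacteria$sample_data

  ## ---- stage 2: diversity ----
  res_div <- stage("diversity", {
    alpha <- lapply(tabs, alpha_diversity)
    dists <- lapply(tabs, function(tb) bray_curtis(hellinger_transform(tb)))
    ords <- lapply(seq_along(dists), function(i)
      nmds(dists[[i]], k = cfg$diversity$nmds_k, seed = seed + 10L + i))
    names(ords) <- names(dists)
    perma <- lapply(dists, function(d)
      permanova(d, meta$season, n_perm = cfg$diversity$n_perm,
                seed = seed + 20L))
    env_num <- env[rownames(tabs$bacteria$counts),
                   vapply(env, is.numeric, logical(1)), drop = FALSE]
    d_env <- as.matrix(dist(scale(env_num)))
    mantel_env <- lapply(dists, function(d)
      mantel(d, d_env, n_perm = cfg$diversity$n_perm, seed = seed + 30L))
    for (f in names(alpha))
      write_tsv_matrix(alpha[[f]][, -1], out_file(paste0("alpha_", f, ".tsv")))
    write_json_report(list(
      permanova = lapply(perma, function(x)
        list(pseudo_F = x$statistic, R2 = x$R2, p = x$p_value)),
      mantel_env = lapply(mantel_env, function(x)
        list(r = x$statistic, p = x$p_value))),
      out_file("beta_diversity.json"))
    list(alpha = alpha, distances = dists, nmds = ords,
         permanova = perma, mantel_env = mantel_env, env_numeric = env_num)
  })

  ## ---- stage 3: niche breadth ----
  res_niche <- stage("niche", {
    nb <- lapply(tabs, levins_breadth)
    comm <- lapply(nb, community_level_breadth)
    for (f in names(comm))
      write_tsv_matrix(comm[[f]][, -1], out_file(paste0("niche_", f, ".tsv")))
    list(breadth = nb, community = comm)
  })

  ## ---- stage 4: network inference ----
  res_net <- stage("network", {
    clr <- lapply(selected, function(tb) mclr_transform(tb$counts))
    domains <- unlist(lapply(names(selected), function(f)
      setNames(rep(f, ncol(selected[[f]]$counts)),
               colnames(selected[[f]]$counts))))
    combos <- list(BPN = c("bacteria", "pico", "nano"),
                   BP = c("bacteria", "pico"), BN = c("bacteria", "nano"))
    nets <- list()
    for (nm in names(combos)) {
      X <- do.call(cbind, clr[combos[[nm]]])
      nets[[nm]] <- stars_select(X,
        nlambda = cfg$network$nlambda,
        lambda_min_ratio = cfg$network$lambda_min_ratio,
        stars_threshold = cfg$network$stars_threshold,
        n_subsamples = cfg$network$n_subsamples,
        seed = seed + 40L, domains = domains)
    }
    if (isTRUE(cfg$network$seasonal)) {
      Xall <- do.call(cbind, clr)
      for (s in unique(meta$season)) {
        rows <- which(meta$season == s)
        if (length(rows) < cfg$network$min_season_samples) {
          note("seasonal network '%s' skipped: only %d samples", s,
               length(rows))
          next
        }
        Xs <- Xall[rows, , drop = FALSE]
        keep <- apply(Xs, 2, sd) > 0
        nets[[paste0("BPN_", s)]] <- suppressWarnings(stars_select(
          Xs[, keep, drop = FALSE],
          nlambda = cfg$network$nlambda,
          lambda_min_ratio = cfg$network$lambda_min_ratio,
          stars_threshold = cfg$network$stars_threshold,
          n_subsamples = cfg$network$n_subsamples,
          seed = seed + 50L, domains = domains))
      }
    }
    for (nm in names(nets))
      write_network(nets[[nm]]$network,
                    out_file(paste0("network_", nm, ".graphml")),
                    out_file(paste0("network_", nm, "_edges.tsv")))
    write_json_report(lapply(nets, function(x)
      x$lambda_path[c("lambda", "instability", "monotonized", "selected")]),
      out_file("lambda_paths.json"))
    nets
  })

  ## ---- stage 5: stability ----
  res_stab <- stage("stability", {
    out <- list()
    for (nm in names(res_net)) {
      net <- res_net[[nm]]$network
      g <- as_igraph(net)
      metrics <- topology_metrics(net, seed = seed + 60L)
      keys <- if (igraph::vcount(g) >= 5) keystone_nodes(
        net, percentile = cfg$stability$keystone_percentile) else character()
      rob <- random_attack_robustness(
        net, n_iterations = cfg$stability$n_iterations, seed = seed + 70L)
      eff <- efficiency_distribution(net)
      out[[nm]] <- list(metrics = metrics, keystones = as.character(keys),
                        robustness = rob, efficiency = eff)
      write_tsv_matrix(
        data.frame(step = seq_len(rob$N), mean_sigma = rob$sigma,
                   row.names = NULL),
        out_file(paste0("robustness_", nm, ".tsv")))
    }
    write_json_report(lapply(out, function(x) list(
      metrics = x$metrics, keystones = x$keystones,
      R = x$robustness$R, V = x$robustness$V,
      efficiency_mu = x$efficiency$mu, efficiency_sigma = x$efficiency$sigma,
      global_efficiency = x$efficiency$global)),
      out_file("stability.json"))
    out
  })

  ## ---- stage 6: biomass / PPBR ----
  res_ppbr <- stage("ppbr", {
    bio <- abundance_to_biomass(cyto)
    bio <- ppbr(bio)
    write_tsv_matrix(bio[, -1], out_file("ppbr.tsv"))
    bio
  })

  ## ---- stage 7: PLS path model ----
  res_plspm <- stage("plspm", {
    seasons <- meta$season
    season_nets <- paste0("BPN_", seasons)
    have <- season_nets %in% names(res_stab)
    if (!all(have))
      note("plspm: %d samples lack a seasonal network; rows dropped",
           sum(!have))
    rob_by_s <- vapply(res_stab, function(x) x$robustness$R, numeric(1))
    eff_by_s <- vapply(res_stab, function(x) x$efficiency$global, numeric(1))
    env_num <- res_div$env_numeric
    dat <- data.frame(
      temperature = env_num$temperature, salinity = env_num$salinity,
      DO = env_num$DO, TN = env_num$TN, TP = env_num$TP,
      shannon_pico = res_div$alpha$pico$shannon,
      shannon_nano = res_div$alpha$nano$shannon,
      breadth_bacteria = res_niche$community$bacteria$mean_breadth,
      breadth_pico = res_niche$community$pico$mean_breadth,
      breadth_nano = res_niche$community$nano$mean_breadth,
      log10_ppbr_hnf_hb = res_ppbr$log10_ppbr_hnf_hb,
      log10_ppbr_hnf_ppe = res_ppbr$log10_ppbr_hnf_ppe,
      net_robustness = ifelse(have, rob_by_s[season_nets], NA),
      net_efficiency = ifelse(have, eff_by_s[season_nets], NA))
    blocks <- list(
      water_property = c("temperature", "salinity", "DO"),
      water_nutrition = c("TN", "TP"),
      diversity = c("shannon_pico", "shannon_nano"),
      niche_breadth = c("breadth_bacteria", "breadth_pico", "breadth_nano"),
      ppbr = c("log10_ppbr_hnf_hb", "log10_ppbr_hnf_ppe"),
      robustness = "net_robustness",
      efficiency = "net_efficiency")
    p <- length(blocks)
    paths <- matrix(0, p, p, dimnames = list(names(blocks), names(blocks)))
    for (endo in c("diversity", "niche_breadth", "ppbr"))
      paths[endo, c("water_property", "water_nutrition")] <- 1
    for (endo in c("robustness", "efficiency"))
      paths[endo, c("water_property", "water_nutrition", "diversity",
                    "niche_breadth", "ppbr")] <- 1
    if (!is.null(cfg$plspm$paths)) paths <- as.matrix(cfg$plspm$paths)
    spec <- plspm_spec(blocks, paths)
    fit <- fit_plspm(dat, spec)
    if (isTRUE(cfg$plspm$prune)) {
      pruned <- tryCatch(
        prune_loadings(fit, dat, threshold = cfg$plspm$loading_threshold),
        error = function(e) {
          note("plspm: pruning skipped (%s)", conditionMessage(e))
          fit
        })
      if (length(attr(pruned, "pruned")))
        note("plspm: pruned indicators: %s",
             paste(attr(pruned, "pruned"), collapse = ", "))
      fit <- pruned
    }
    boot <- bootstrap_plspm(dat, fit$spec, n_boot = cfg$plspm$n_boot,
                            seed = seed + 80L)
    eff_dec <- effects_decomposition(boot$fit)
    write_json_report(list(
      gof = boot$fit$gof, r_squared = boot$fit$r_squared,
      paths = boot$paths, loadings = boot$loadings,
      effects = eff_dec, n_skipped_boot = boot$n_skipped,
      note = "network robustness/efficiency broadcast per season"),
      out_file("plspm.json"))
    list(fit = boot$fit, bootstrap = boot, effects = eff_dec, data = dat)
  })

  ## ---- manifest ----
  manifest_path <- file.path(outdir, "manifest.json")
  checksums <- tools::md5sum(files[file.exists(files)])
  names(checksums) <- basename(names(checksums))
  manifest <- list(
    package = "fracnet",
    version = as.character(utils::packageVersion("fracnet")),
    seed = seed,
    stages = c("filter", "diversity", "niche", "network", "stability",
               "ppbr", "plspm"),
    parameters = cfg[c("filter", "diversity", "network", "stability",
                       "plspm")],
    divergences = paste("network inference uses MB neighborhood selection",
                        "with StARS in place of the sparse+low-rank variant"),
    warnings = warnings_log,
    checksums = as.list(checksums))
  write_json_report(manifest, manifest_path)

  invisible(list(filter = res_filter, diversity = res_div,
                 niche = res_niche, networks = res_net,
                 stability = res_stab, ppbr = res_ppbr,
                 plspm = res_plspm, manifest = manifest))
}
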