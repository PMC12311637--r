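test_that("generators are bit-identical under a fixed seed", {
  scen <- synthetic_scenario(samples_per_season = 5, seed = 42)
  expect_identical(generate_env_table(scen), generate_env_table(scen))
  s1 <- generate_counts(scen)
  s2 <- generate_counts(scen)
  expect_identical(s1$bacteria$counts, s2$bacteria$counts)
  expect_identical(s1$pico$counts, s2$pico$counts)
  env <- generate_env_table(scen)
  expect_identical(generate_cytometry(env, scen),
                   generate_cytometry(env, scen))
  d1 <- generate_latent_path_data(matrix(0, 2, 2), list(0.8, 0.8), 50,
                                  seed = 7)
  d2 <- generate_latent_path_data(matrix(0, 2, 2), list(0.8, 0.8), 50,
                                  seed = 7)
  expect_identical(d1$indicators, d2$indicators)
})

test_that("environmental table has one row per sample and seasonal nulls", {
  scen <- synthetic_scenario(n_seasons = 4, samples_per_season = 10)
  env <- generate_env_table(scen)
  expect_equal(nrow(env), 40)
  expect_setequal(unique(env$season),
                  c("winter", "spring", "summer", "autumn"))
  expect_error(synthetic_scenario(samples_per_season = 0), "positive")

  # with season_effect = 0 the ANOVA p-values on temperature are uniform
  pvals <- vapply(1:60, function(s) {
    e <- generate_env_table(synthetic_scenario(samples_per_season = 6,
                                               season_effect = 0, seed = s))
    summary(aov(temperature ~ season, data = e))[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("count tables follow the scenario's depth and boundary settings", {
  scen <- synthetic_scenario(samples_per_season = 5, zero_inflation = 0,
                             seed = 3)
  sim <- generate_counts(scen)
  counts <- sim$bacteria$counts
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
  expect_equal(mean(rowSums(counts)) / scen$sequencing_depth, 1,
               tolerance = 0.15)

  # zero_inflation = 1 wipes every count
  scen0 <- synthetic_scenario(samples_per_season = 3, zero_inflation = 1)
  expect_true(all(generate_counts(scen0)$bacteria$counts == 0))

  # chain precision over 10 core ASVs -> 9 ground-truth edges
  scen_chain <- synthetic_scenario(
    n_eligible = c(bacteria = 10, pico = 0, nano = 0),
    n_noise = c(bacteria = 0, pico = 0, nano = 0),
    true_precision = chain_precision(10), samples_per_season = 3)
  expect_equal(nrow(generate_counts(scen_chain)$true_edges), 9)

  # singular precision rejected
  expect_error(synthetic_scenario(
    n_eligible = c(bacteria = 2, pico = 0, nano = 0),
    n_noise = c(bacteria = 0, pico = 0, nano = 0),
    true_precision = matrix(1, 2, 2)), "positive definite")
})

test_that("identity precision yields vanishing latent partial correlations", {
  scen <- synthetic_scenario(
    n_eligible = c(bacteria = 10, pico = 0, nano = 0),
    n_noise = c(bacteria = 0, pico = 0, nano = 0),
    true_precision = diag(10), samples_per_season = 500,
    composition_effect = 0, seed = 9)
  z <- generate_counts(scen)$latent
  pc <- -stats::cov2cor(solve(stats::cov(z)))
  diag(pc) <- 0
  expect_lt(max(abs(pc)), 0.1)
})

test_that("cross-fraction contamination hits the target ratio", {
  scen <- synthetic_scenario(samples_per_season = 10, seed = 5)
  sim <- generate_counts(scen)
  pairs <- data.frame(pico_asv = "P_ASV001", ratio = 3.0)
  inj <- inject_cross_fraction_contamination(sim$pico, sim$nano, pairs)
  rel <- function(m) m / pmax(rowSums(m), 1)
  realized <- mean(rel(inj$nano$counts)[, "P_ASV001"]) /
    mean(rel(inj$pico$counts)[, "P_ASV001"])
  expect_equal(realized, 3.0, tolerance = 0.1)

  # empty pair list leaves the tables untouched
  noop <- inject_cross_fraction_contamination(sim$pico, sim$nano,
                                              data.frame())
  expect_identical(noop$nano$counts, sim$nano$counts)
  expect_error(inject_cross_fraction_contamination(
    sim$pico, sim$nano, data.frame(pico_asv = "nope", ratio = 2)),
    "unknown")

  # ratio target 1 survives the downstream ratio filter in both fractions
  inj1 <- inject_cross_fraction_contamination(
    sim$pico, sim$nano, data.frame(pico_asv = "P_ASV002", ratio = 1.0))
  res <- resolve_shared_asvs(inj1$pico, inj1$nano)
  expect_true("P_ASV002" %in% colnames(res$pico$counts))
  expect_true("P_ASV002" %in% colnames(res$nano$counts))
})

test_that("cytometry counts are positive with controllable variation", {
  scen <- synthetic_scenario(samples_per_season = 5)
  env <- generate_env_table(scen)
  cyto <- generate_cytometry(env, scen)
  expect_true(all(as.matrix(cyto[, -1]) > 0))

  # zero-variance configuration gives constant columns
  scen0 <- synthetic_scenario(samples_per_season = 5, cytometry_sd = 0,
                              env_coupling = 0)
  cyto0 <- generate_cytometry(generate_env_table(scen0), scen0)
  expect_equal(length(unique(cyto0$HB)), 1)

  # equal means across seasons: seasonal ANOVA non-significant >= 90%
  sig <- vapply(1:80, function(s) {
    sc <- synthetic_scenario(samples_per_season = 6, env_coupling = 0,
                             seed = s)
    e <- generate_env_table(sc)
    cy <- generate_cytometry(e, sc)
    p <- summary(aov(log10(cy$HNF) ~ e$season))[[1]][["Pr(>F)"]][1]
    p < 0.05
  }, logical(1))
  expect_gte(mean(!sig), 0.9)
})

test_that("latent path generator matches its structural equations", {
  P <- matrix(0, 2, 2)
  P[2, 1] <- 0.5
  d <- generate_latent_path_data(P, list(1.0, 1.0), 5000, seed = 11)
  expect_equal(cor(d$indicators[[1]], d$indicators[[2]]), 0.5,
               tolerance = 0.05)
  # zero path matrix -> uncorrelated latents
  d0 <- generate_latent_path_data(matrix(0, 3, 3), list(1, 1, 1), 5000,
                                  seed = 12)
  cc <- cor(d0$latents)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
  # cyclic (non-lower-triangular) inner models are rejected
  bad <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(generate_latent_path_data(bad, list(1, 1), 10),
               "lower triangular")
})
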