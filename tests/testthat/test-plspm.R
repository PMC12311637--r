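chain3 <- function() {
  P <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  P["B", "A"] <- 1
  P["C", "B"] <- 1
  P
}

test_that("single-indicator blocks reduce to standardized OLS path analysis", {
  P <- chain3()
  Ptrue <- P * c(0, 0.6, 0, 0, 0, 0.3, 0, 0, 0)  # B<-A 0.6, C<-B 0.3
  d <- generate_latent_path_data(Ptrue, list(1, 1, 1), 300, seed = 5)
  spec <- plspm_spec(d$blocks, P)
  fit <- fit_plspm(d$indicators, spec)
  oracle <- ols_path_oracle(d$indicators, P)
  expect_equal(unname(fit$path_coefficients), unname(oracle),
               tolerance = 1e-8)
  # two single-indicator latents: path = Pearson correlation
  P2 <- matrix(0, 2, 2, dimnames = rep(list(c("A", "B")), 2))
  P2["B", "A"] <- 1
  d2 <- d$indicators[, 1:2]
  names(d2) <- c("A_x1", "B_x1")
  f2 <- fit_plspm(d2, plspm_spec(list(A = "A_x1", B = "B_x1"), P2))
  expect_equal(f2$path_coefficients["B", "A"], cor(d2$A_x1, d2$B_x1),
               tolerance = 1e-10)
})

test_that("fit invariants hold: unit-variance scores, gof identity,
           permutation invariance", {
  P <- chain3()
  Ptrue <- P * c(0, 0.6, 0, 0, 0, 0.3, 0, 0, 0)
  d <- generate_latent_path_data(Ptrue, list(rep(0.9, 3), rep(0.9, 3),
                                             rep(0.9, 3)), 200, seed = 6)
  spec <- plspm_spec(d$blocks, P)
  fit <- fit_plspm(d$indicators, spec)
  expect_equal(unname(apply(fit$scores, 2, var)), rep(1, 3),
               tolerance = 1e-10)
  endo <- !is.na(fit$r_squared)
  expect_equal(fit$gof^2,
               mean(fit$communality) * mean(fit$r_squared[endo]),
               tolerance = 1e-12)
  # permuting sample order changes nothing
  perm <- sample(nrow(d$indicators))
  fit_p <- fit_plspm(d$indicators[perm, ], spec)
  expect_equal(fit_p$path_coefficients, fit$path_coefficients,
               tolerance = 1e-10)
  expect_equal(fit_p$loadings$loading, fit$loadings$loading,
               tolerance = 1e-10)
})

test_that("pruning removes noise indicators and guards empty blocks", {
  P <- matrix(0, 2, 2, dimnames = rep(list(c("A", "B")), 2))
  P["B", "A"] <- 1
  Ptrue <- P * 0.6
  d <- generate_latent_path_data(Ptrue, list(rep(0.95, 3), rep(0.95, 3)),
                                 400, seed = 8)
  ind <- d$indicators
  set.seed(9)
  ind$A_noise <- rnorm(400)  # pure-noise indicator in block A
  blocks <- d$blocks
  blocks$A <- c(blocks$A, "A_noise")
  fit <- fit_plspm(ind, plspm_spec(blocks, P))
  expect_lt(abs(fit$loadings$loading[fit$loadings$indicator == "A_noise"]),
            0.5)
  pruned <- prune_loadings(fit, ind)
  expect_equal(attr(pruned, "pruned"), "A_noise")
  expect_false("A_noise" %in% pruned$loadings$indicator)
  # threshold 0 never prunes; clean fits are fixed points
  expect_identical(attr(prune_loadings(fit, ind, threshold = 0), "pruned"),
                   character(0))
  same <- prune_loadings(pruned, ind)
  expect_equal(same$loadings, pruned$loadings)
  # a block of only-noise indicators empties under pruning: named error
  set.seed(10)
  ind$A_n2 <- rnorm(400)
  ind$A_n3 <- rnorm(400)
  blocks_bad <- list(A = c("A_noise", "A_n2", "A_n3"), B = d$blocks$B)
  fit_bad <- fit_plspm(ind, plspm_spec(blocks_bad, P))
  expect_error(prune_loadings(fit_bad, ind), "block\\(s\\): A")
})

test_that("bootstrap is seeded, degenerate at n_boot = 1, and covers truth", {
  P <- matrix(0, 2, 2, dimnames = rep(list(c("A", "B")), 2))
  P["B", "A"] <- 1
  d <- generate_latent_path_data(P * 0.5, list(rep(0.9, 2), rep(0.9, 2)),
                                 300, seed = 10)
  spec <- plspm_spec(d$blocks, P)
  b1 <- bootstrap_plspm(d$indicators, spec, n_boot = 50, seed = 3)
  b2 <- bootstrap_plspm(d$indicators, spec, n_boot = 50, seed = 3)
  expect_identical(b1$paths, b2$paths)
  expect_true(b1$paths$significant)  # strong true path detected
  expect_true(b1$paths$lower < b1$paths$estimate + 0.2 &&
                b1$paths$upper > b1$paths$estimate - 0.2)
  one <- bootstrap_plspm(d$indicators, spec, n_boot = 1, seed = 4)
  expect_equal(one$paths$lower, one$paths$upper)
})

test_that("effects decomposition multiplies along paths and adds routes", {
  P <- chain3()
  Ptrue <- P
  Ptrue["B", "A"] <- 0.5
  Ptrue["C", "B"] <- 0.4
  d <- generate_latent_path_data(Ptrue, list(1, 1, 1), 100, seed = 11)
  fit <- fit_plspm(d$indicators, plspm_spec(d$blocks, P))
  # overwrite estimated coefficients with exact values to test the algebra
  fit$path_coefficients <- Ptrue
  eff <- effects_decomposition(fit)
  ac <- eff[eff$from == "A" & eff$to == "C", ]
  expect_equal(ac$direct, 0)
  expect_equal(ac$indirect, 0.2)
  expect_equal(ac$total, 0.2)
  # parallel route: direct 0.1 plus 0.5 * 0.4
  P3 <- Ptrue
  P3["C", "A"] <- 0.1
  fit$path_coefficients <- P3
  eff3 <- effects_decomposition(fit)
  expect_equal(eff3$total[eff3$from == "A" & eff3$to == "C"], 0.30)
  # unlinked latents have zero total effect
  P0 <- matrix(0, 3, 3, dimnames = dimnames(P))
  P0["C", "B"] <- 0.7
  fit$path_coefficients <- P0
  eff0 <- effects_decomposition(fit)
  expect_equal(eff0$total[eff0$from == "A" & eff0$to == "C"], 0)
})

test_that("degenerate gof extremes follow the definition", {
  # indicators equal to their latents, latent B a copy of A: gof = 1
  set.seed(12)
  x <- rnorm(100)
  d <- data.frame(A_x1 = x, B_x1 = x)
  P <- matrix(0, 2, 2, dimnames = rep(list(c("A", "B")), 2))
  P["B", "A"] <- 1
  fit <- fit_plspm(d, plspm_spec(list(A = "A_x1", B = "B_x1"), P))
  expect_equal(gof(fit), 1, tolerance = 1e-10)
})
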