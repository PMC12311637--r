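test_that("alpha diversity matches closed forms and vegan's Shannon", {
  m <- rbind(S1 = c(10, 10, 0), S2 = c(7, 0, 0))
  a <- alpha_diversity(asv_table(m, "bacteria"))
  expect_equal(a["S1", "shannon"], log(2), tolerance = 1e-12)
  expect_equal(a["S1", "pielou"], 1, tolerance = 1e-12)
  expect_equal(a["S2", "shannon"], 0)
  expect_true(is.na(a["S2", "pielou"]))

  # S_obs = 10, F1 = 4, F2 = 2: classic 14, bias-corrected 12
  x <- c(1, 1, 1, 1, 2, 2, 3, 4, 5, 6)
  tab <- asv_table(matrix(x, 1, dimnames = list("S", NULL)), "pico")
  expect_equal(alpha_diversity(tab)$chao1, 12)
  expect_equal(alpha_diversity(tab, chao1 = "classic")$chao1, 14)

  skip_if_not_installed("vegan")
  set.seed(1)
  rnd <- matrix(rpois(60, 5), 6, 10)
  rownames(rnd) <- paste0("S", 1:6)
  ours <- alpha_diversity(asv_table(rnd, "bacteria"))$shannon
  expect_equal(ours, unname(vegan::diversity(rnd)), tolerance = 1e-12)
})

test_that("Bray-Curtis matches closed forms and vegan", {
  m <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0),
             d = c(0, 0, 5))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "d"], 1)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))

  skip_if_not_installed("vegan")
  set.seed(2)
  rnd <- matrix(rpois(80, 4), 8, 10)
  rownames(rnd) <- paste0("S", 1:8)
  expect_equal(unname(bray_curtis(rnd)),
               unname(as.matrix(vegan::vegdist(rnd, "bray"))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("NMDS embeds embeddable configurations at near-zero stress", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  d <- as.matrix(dist(sq))
  rownames(d) <- colnames(d) <- paste0("P", 1:4)
  fit <- suppressWarnings(nmds(d, k = 2, seed = 1))
  expect_lt(fit$stress, 0.01)
  # k = n - 1 on a metric distance embeds exactly
  set.seed(3)
  pts <- matrix(rnorm(12), 6, 2)
  d6 <- as.matrix(dist(pts))
  fit6 <- suppressWarnings(nmds(d6, k = 5, seed = 1))
  expect_lt(fit6$stress, 1e-3)
  # determinism and monotone stress trace
  f1 <- suppressWarnings(nmds(d6, k = 2, seed = 9))
  f2 <- suppressWarnings(nmds(d6, k = 2, seed = 9))
  expect_identical(f1$points, f2$points)
  expect_true(all(diff(f1$stress_trace) <= 1e-12))
})

test_that("PERMANOVA pseudo-F matches the Gram-trace oracle everywhere", {
  set.seed(4)
  coords <- matrix(rnorm(16), 8, 2)
  d <- as.matrix(dist(coords))
  rownames(d) <- colnames(d) <- paste0("S", 1:8)
  groups <- rep(c("x", "y"), each = 4)
  res <- permanova(d, groups, n_perm = 99, seed = 1)
  expect_equal(res$statistic, permanova_f_oracle(d, groups),
               tolerance = 1e-6)
  # every balanced relabeling agrees with the oracle too
  combos <- combn(8, 4)
  diffs <- apply(combos, 2, function(idx) {
    g <- rep("y", 8); g[idx] <- "x"
    permanova(d, g, n_perm = 0, seed = 1)$statistic -
      permanova_f_oracle(d, g)
  })
  expect_lt(max(abs(diffs)), 1e-6)
})

test_that("PERMANOVA separates constructed extremes and validates input", {
  # two tight clusters far apart: R2 -> 1, smallest possible p
  coords <- rbind(matrix(rnorm(20, 0, 1e-3), 10),
                  matrix(rnorm(20, 50, 1e-3), 10))
  d <- as.matrix(dist(coords))
  res <- permanova(d, rep(c("a", "b"), each = 10), n_perm = 199, seed = 2)
  expect_gt(res$R2, 0.999)
  expect_equal(res$p_value, 1 / 200)
  expect_error(permanova(d, c("a", rep("b", 19))), "at least two members")
})

test_that("Mantel statistics behave on identities and constructions", {
  set.seed(5)
  pts <- matrix(rnorm(30), 15, 2)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("S", 1:15)
  expect_equal(mantel(d, d, n_perm = 49)$statistic, 1)
  # relabeling both matrices identically leaves r unchanged
  d2 <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
  dimnames(d2) <- dimnames(d)
  perm <- sample(15)
  r1 <- mantel(d, d2, n_perm = 0)$statistic
  r2 <- mantel(d[perm, perm], d2[perm, perm], n_perm = 0)$statistic
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("partial Mantel reduces to the residual partial correlation", {
  set.seed(6)
  mk <- function() {
    d <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
    dimnames(d) <- list(paste0("S", 1:12), paste0("S", 1:12))
    d
  }
  d1 <- mk(); d2 <- mk(); d3 <- mk()
  res <- partial_mantel(d1, d2, d3, method = "pearson", n_perm = 0)
  # oracle: correlation of residuals after regressing each on the control
  v1 <- d1[upper.tri(d1)]; v2 <- d2[upper.tri(d2)]; v3 <- d3[upper.tri(d3)]
  oracle <- cor(resid(lm(v1 ~ v3)), resid(lm(v2 ~ v3)))
  expect_equal(res$statistic, oracle, tolerance = 1e-12)
  # controlling for the second matrix itself sends the statistic to zero
  res0 <- partial_mantel(d1, d2, d2, method = "pearson", n_perm = 0)
  expect_lt(abs(res0$statistic), 1e-10)
})

test_that("Spearman screening honors rank-correlation identities", {
  set.seed(7)
  x <- rnorm(20)
  feats <- cbind(f1 = x, f2 = -x)
  env <- cbind(e1 = x, e2 = exp(x))
  res <- spearman_env_correlations(feats, env)
  expect_equal(res$rho["f1", "e1"], 1)
  expect_equal(res$rho["f1", "e2"], 1)   # monotone-transform invariance
  expect_equal(res$rho["f2", "e1"], -1)
  expect_true(all(res$p_adj >= res$p - 1e-15))
})
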