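test_that("relative abundance normalizes rows and flags empty samples", {
  m <- rbind(S1 = c(1, 4, 4), S2 = c(0, 0, 0), S3 = c(2, 0, 8))
  tab <- relative_abundance(asv_table(m, "bacteria"))
  expect_equal(unname(tab$counts["S1", ]), c(1, 4, 4) / 9)
  expect_equal(unname(tab$counts["S2", ]), c(0, 0, 0))
  expect_equal(tab$empty_samples, "S2")
  nonzero <- rowSums(tab$counts) > 0
  expect_equal(unname(rowSums(tab$counts)[nonzero]),
               rep(1, sum(nonzero)), tolerance = 1e-12)
  # idempotent on already-relative tables
  expect_identical(relative_abundance(tab)$counts, tab$counts)
})

test_that("hellinger transform gives unit-norm rows and handles zeros", {
  m <- rbind(S1 = c(1, 4, 4), S2 = c(0, 0, 0))
  h <- hellinger_transform(asv_table(m, "bacteria"))
  expect_equal(unname(h["S1", ]), c(1 / 3, 2 / 3, 2 / 3))
  expect_equal(unname(h["S2", ]), c(0, 0, 0))
  expect_equal(sum(h["S1", ]^2), 1, tolerance = 1e-12)
})

test_that("aggregation by label conserves row totals", {
  m <- matrix(c(0.1, 0.2, 0.3, 0.4,
                0.25, 0.25, 0.25, 0.25), 2, 4, byrow = TRUE,
              dimnames = list(c("S1", "S2"), paste0("A", 1:4)))
  ad <- data.frame(cls = c("x", "x", "y", "z"))
  tab <- asv_table(m, "pico", asv_data = ad, type = "relative")
  agg <- aggregate_by_label(tab, "cls")
  expect_equal(unname(agg$counts["S1", "x"]), 0.3)
  expect_equal(rowSums(agg$counts), rowSums(m))
  # distinct labels leave the table unchanged up to renaming
  ad2 <- data.frame(cls = paste0("L", 1:4))
  agg2 <- aggregate_by_label(asv_table(m, "pico", asv_data = ad2,
                                       type = "relative"), "cls")
  expect_equal(unname(agg2$counts), unname(m))
})

test_that("shared ASV resolution applies the strict 2 / 0.5 ratio rule", {
  toy <- shared_asv_toy()
  res <- resolve_shared_asvs(toy$pico, toy$nano)
  # ratio 3 and ratio Inf leave pico; ratio 0.4 leaves nano
  expect_setequal(setdiff(colnames(toy$pico$counts),
                          colnames(res$pico$counts)), c("A1", "A6"))
  expect_setequal(setdiff(colnames(toy$nano$counts),
                          colnames(res$nano$counts)), "A2")
  # boundary ratios 2.0 and 0.5 are kept in both fractions
  expect_true(all(c("A3", "A4", "A5") %in% colnames(res$pico$counts)))
  expect_true(all(c("A3", "A4", "A5") %in% colnames(res$nano$counts)))
  rep <- res$report
  expect_equal(rep$ratio[rep$asv == "A1"], 3)
  expect_equal(rep$ratio[rep$asv == "A2"], 0.4)
  expect_equal(rep$ratio[rep$asv == "A6"], Inf)
  expect_equal(rep$action[rep$asv == "A4"], "keep")
})

test_that("shared ASV resolution is idempotent", {
  toy <- shared_asv_toy()
  once <- resolve_shared_asvs(toy$pico, toy$nano)
  twice <- resolve_shared_asvs(once$pico, once$nano)
  expect_identical(once$pico$counts, twice$pico$counts)
  expect_identical(once$nano$counts, twice$nano$counts)
})

test_that("network ASV selection applies strict prevalence/abundance rules", {
  # 12 samples over 4 seasons; rows sum to 1 via a filler column
  meta <- season_meta(3)
  mk <- function(asv_cols) {
    filler <- 1 - rowSums(asv_cols)
    m <- cbind(asv_cols, filler = filler)
    rownames(m) <- paste0("S", seq_len(nrow(m)))
    asv_table(m, "bacteria", sample_data = meta, type = "relative")
  }
  # A: in 5/12 samples spanning all 4 seasons, mean 0.002 -> kept
  A <- rep(0, 12); A[c(1, 4, 7, 10, 11)] <- 0.0048
  # B: in 3/12 samples (3 <= 12/3) -> dropped regardless of abundance
  B <- rep(0, 12); B[c(1, 4, 7)] <- 0.2
  # C: mean exactly 0.001 -> dropped (strict)
  C <- rep(0, 12); C[c(1, 4, 7, 10, 12)] <- 0.0024
  # D: high abundance but absent from winter (samples 1:3) -> dropped
  D <- rep(0.1, 12); D[1:3] <- 0
  tab <- mk(cbind(A = A, B = B, C = C, D = D))
  expect_equal(mean(C), 0.001)
  sel <- select_network_asvs(tab)
  expect_setequal(setdiff(colnames(sel$counts), "filler"), "A")
  # re-running on its own output changes nothing
  sel2 <- select_network_asvs(sel)
  expect_identical(sel$counts, sel2$counts)
  # missing season metadata is an error
  tab2 <- asv_table(tab$counts, "bacteria", type = "relative")
  expect_error(select_network_asvs(tab2), "season")
})
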