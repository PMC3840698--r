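test_that("outlier filter uses strict bounds and is idempotent", {
  rates <- tibble::tibble(
    gene_id = paste0("g", 1:5), species = "rice",
    dS = c(2.0, 2.0001, 0.5, 1.0, 3.0),
    dN = c(0.1, 0.1, 0.5, 0.51, 0.2))
  kept <- filter_outliers(rates)
  expect_setequal(kept$gene_id, c("g1", "g3"))  # dS = 2.0 and dN = 0.5 kept
  expect_identical(filter_outliers(kept), kept)
  empty <- filter_outliers(rates[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("rate differences are computed within genes against rice", {
  rates <- tibble::tibble(
    gene_id = rep("g1", 5),
    species = c("wheat", "barley", "lolium", "rice", "maize"),
    gtr_distance = c(0.2, 0.25, 0.3, 0.15, 0.3),
    dS = c(0.5, 0.55, 0.6, 0.45, 0.7),
    dN = c(0.10, 0.12, 0.14, 0.08, 0.2))
  # worked example: CP mean dN (0.10+0.12+0.14)/3 = 0.12, minus rice 0.08
  d <- rate_difference(rates, "core_pooideae", metric = "dN")
  expect_equal(d$difference, 0.04, tolerance = 1e-12)
  # species equal to reference: difference 0
  d0 <- rate_difference(rates, "rice", metric = "dS")
  expect_equal(d0$difference, 0)
  # genes lacking the reference are skipped
  norice <- dplyr::filter(rates, species != "rice")
  expect_equal(nrow(rate_difference(norice, "wheat", metric = "dN")), 0L)
})

test_that("resampling p-values agree with exhaustive enumeration", {
  vals <- setNames(c(3, 1, 4, 1, 5, 9), paste0("g", 1:6))
  subset <- c("g5", "g6")
  exact <- exact_resample_p(vals, subset, median)
  set.seed(10)
  mc <- resample_pvalue(vals, subset, "median", n_resamples = 4000)
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(mc$p_value - exact), 3 * se + 1e-12)
  # third-quartile statistic, R's default quantile definition
  exact_q3 <- exact_resample_p(vals, subset,
                               function(x) unname(quantile(x, 0.75)))
  mc_q3 <- resample_pvalue(vals, subset, "third_quartile",
                           n_resamples = 4000)
  se3 <- sqrt(exact_q3 * (1 - exact_q3) / 4000) + 1e-12
  expect_lt(abs(mc_q3$p_value - exact_q3), 3 * se3)
})

test_that("degenerate and directional resampling cases behave as defined", {
  vals <- setNames(1:5, paste0("g", 1:5))
  # subset = whole population: every resample equals the observed statistic
  all_p <- resample_pvalue(vals, names(vals), "median", n_resamples = 500)
  expect_equal(all_p$p_value, 1)
  expect_error(resample_pvalue(vals, "nope", "median"), "empty subset")
  # seed reproducibility
  a <- resample_pvalue(vals, c("g4", "g5"), "median", n_resamples = 200,
                       seed = 99)
  b <- resample_pvalue(vals, c("g4", "g5"), "median", n_resamples = 200,
                       seed = 99)
  expect_identical(a$p_value, b$p_value)
  # plus-one correction bounds P away from zero
  c1 <- resample_pvalue(vals, c("g4", "g5"), "median", n_resamples = 100,
                        seed = 1, plus_one = TRUE)
  expect_gt(c1$p_value, 0)
})

test_that("BH adjustment matches the hand-worked step-up example", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_adjust(c(0.1, NA)))
  # monotone in input ranks and bounded by 1
  set.seed(6)
  p <- runif(30)
  q <- fdr_adjust(p)
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("selection enrichment counts and null behaviour are sane", {
  res <- tibble::tibble(
    gene_id = paste0("g", 1:10), foreground = "BP_ancestral",
    p_value = rep(0.9, 10), q_value = rep(0.9, 10), skipped = FALSE)
  labels <- tibble::tibble(gene_id = paste0("g", 1:10),
                           is_lti = c(rep(TRUE, 3), rep(FALSE, 7)))
  # no significant genes anywhere: observed proportion 0, P = 1
  enr <- selection_enrichment(res, labels, n_resamples = 300, seed = 2)
  expect_equal(enr$n_significant, 0L)
  expect_equal(enr$prop_lti, 0)
  expect_equal(enr$resampling_p, 1)
  # strong enrichment: all three LTI genes significant, background clean
  res2 <- res
  res2$q_value[1:3] <- 0.001
  enr2 <- selection_enrichment(res2, labels, n_resamples = 2000, seed = 3)
  expect_equal(enr2$n_lti_significant, 3L)
  expect_lt(enr2$resampling_p, 0.05)
  # per-resample FDR recomputation variant runs and returns a probability
  enr3 <- selection_enrichment(res2, labels, n_resamples = 200, seed = 4,
                               recompute_fdr = TRUE)
  expect_true(enr3$resampling_p >= 0 && enr3$resampling_p <= 1)
})
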