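test_that("the normality screen separates normal from bimodal samples", {
  set.seed(31)
  norm_p <- replicate(100, normality_test(rnorm(500))$p_value)
  expect_gte(mean(norm_p > 0.05), 0.90)
  bimodal_p <- replicate(100, {
    x <- c(rnorm(250, -4), rnorm(250, 4))
    normality_test(x)$p_value
  })
  expect_gte(mean(bimodal_p < 0.05), 0.95)
  expect_error(normality_test(rep(5, 10)), "identical")
  expect_error(normality_test(c(1, 2)), "n >= 3")
})

test_that("rank-sum test: exact enumeration and approximation behave", {
  r <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 0.1)
  same <- rank_sum_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(same$p_value, 0.95)
  expect_error(rank_sum_test(1, c(1, 2)), "n >= 2")
  # exact path agrees with full enumeration for all n1, n2 <= 6
  set.seed(8)
  for (n1 in 2:6) for (n2 in 2:6) {
    g1 <- rnorm(n1); g2 <- rnorm(n2, 1)
    expect_equal(rank_sum_test(g1, g2)$p_value, oracle_ranksum_p(g1, g2),
                 tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis squares the two-group rank-sum z", {
  set.seed(9)
  g1 <- rnorm(25, 0); g2 <- rnorm(20, 0.4)
  kw <- kruskal_wallis(list(g1, g2))
  rs <- rank_sum_test(g1, g2)
  expect_equal(kw$p_value, rs$p_value, tolerance = 0.02)
  trio <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_lt(trio$statistic, 1e-9)
  expect_gt(trio$p_value, 0.99)
  expect_error(kruskal_wallis(list(c(1, 2))), ">= 2 groups")
})

test_that("rank-sum type-I error sits at the nominal level", {
  set.seed(77)
  rej <- replicate(500, rank_sum_test(rnorm(20), rnorm(20))$p_value < 0.05)
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("cohort comparison reproduces the expected significance pattern", {
  co <- generate_cohort(cohort_spec(seed = 41))
  tab <- compare_cohort(co)
  expect_equal(tab$feature[tab$test == "Kruskal-Wallis"],
               c("grad_E_rise", "grad_E_fall", "grad_T_rise"))
  expect_true(all(tab$significant[tab$feature %in% c("median_E", "median_T")]))
  expect_error(compare_cohort(co[co$label == "GBM", ]), "both classes")
})

test_that("a null cohort (shared generator law) stays mostly non-significant", {
  # one LOI per subject keeps the 40 lines independent, so the rank tests
  # see iid samples and their nominal size applies
  cs <- cohort_spec(n_gbm = 20, n_abscess = 20, lois_per_subject = 1,
                    abscess_spec = default_gbm_spec(), seed = 51)
  n_sig <- 0L
  for (s in 1:5) {
    cs$seed <- 50L + s
    n_sig <- n_sig + sum(compare_cohort(generate_cohort(cs))$significant)
  }
  expect_lte(n_sig / (5 * 7), 0.10)
})

test_that("tiny cohorts run through the exact rank-sum path", {
  co <- generate_cohort(cohort_spec(n_gbm = 2, n_abscess = 2,
                                    lois_per_subject = 1, seed = 13))
  r <- rank_sum_test(co$median_E[co$label == "GBM"],
                     co$median_E[co$label == "ABSCESS"])
  expect_equal(r$method, "exact")
  expect_s3_class(compare_cohort(co), "data.frame")
})

test_that("holm adjustment only tightens significance", {
  co <- generate_cohort(cohort_spec(seed = 61))
  raw <- compare_cohort(co)
  adj <- compare_cohort(co, p_adjust = "holm")
  expect_true(all(adj$p_value >= raw$p_value - 1e-15))
  expect_true(all(!adj$significant | raw$significant))
})
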