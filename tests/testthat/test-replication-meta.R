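test_that("the two-cohort heterogeneity statistic behaves as derived", {
  expect_equal(heterogeneity_test(0.2, 0.1, 0.2, 0.1),
               data.frame(het_stat = 0, het_pval = 1))
  h <- heterogeneity_test(0.1, 0.1, -0.1, 0.1)
  expect_equal(h$het_stat, 2.0)
  expect_equal(h$het_pval, pchisq(2, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(h$het_pval, 3), 0.157)
  expect_error(heterogeneity_test(0.1, 0, 0.1, 0.1), "positive")

  # a protective effect in one cohort vs a flat one in the other, from
  # printed OR/CI pairs, is detected as heterogeneous
  cohort1 <- from_or_ci(0.90, 0.86, 0.93)
  cohort2 <- from_or_ci(1.01, 0.97, 1.05)
  het <- heterogeneity_test(cohort1$beta, cohort1$se, cohort2$beta, cohort2$se)
  expect_lt(het$het_pval, 0.05)
})

test_that("type-I error of the heterogeneity test is nominal", {
  set.seed(121L)
  n <- 10000L
  b1 <- 0.2 + rnorm(n, sd = 0.05)
  b2 <- 0.2 + rnorm(n, sd = 0.08)
  h <- heterogeneity_test(b1, 0.05, b2, 0.08)
  expect_lt(abs(mean(h$het_pval < 0.05) - 0.05), 0.01)
})

test_that("OR/CI inversion recovers betas, SEs and Wald p-values", {
  # symmetric CI constructed from known (beta, se) inverts exactly
  beta <- 0.3; se <- 0.07
  zc <- qnorm(0.975)
  got <- from_or_ci(exp(beta), exp(beta - zc * se), exp(beta + zc * se))
  expect_equal(got$beta, beta, tolerance = 1e-12)
  expect_equal(got$se, se, tolerance = 1e-12)

  # printed two-decimal OR/CI rows reproduce their reported p-values
  rows <- from_or_ci(c(1.01, 0.96, 0.77),
                     c(0.97, 0.83, 0.38),
                     c(1.05, 1.11, 1.54))
  expect_equal(round(rows$pval, 2), c(0.62, 0.58, 0.46))
  expect_lt(abs(rows$beta[1] - 0.00995), 1e-4)
  expect_lt(abs(rows$se[1] - 0.02022), 1e-4)

  # degenerate CI yields se 0 and an undefined p
  deg <- from_or_ci(1.0, 1.0, 1.0)
  expect_equal(deg$se, 0)
  expect_true(is.na(deg$pval))
  expect_error(from_or_ci(1.0, 1.1, 1.2), "ci_low")
  expect_error(from_or_ci(-1, 0.5, 1), "positive")
})

test_that("IVW meta-analysis pools by precision", {
  m <- ivw_meta(c(0.2, 0.0), c(0.1, 0.1))
  expect_equal(m$beta_meta, 0.1)
  expect_equal(m$se_meta, 0.1 / sqrt(2))

  m2 <- ivw_meta(c(0.3, 0.1), c(0.1, 0.2))
  expect_equal(m2$beta_meta, 0.26)
  expect_equal(m2$se_meta, 0.0894, tolerance = 1e-3)
  expect_true(m2$codirectional)
  expect_false(ivw_meta(c(0.3, -0.1), c(0.1, 0.1))$codirectional)
  expect_true(ivw_meta(c(0.3, 0), c(0.1, 0.1))$codirectional)

  # k identical studies: se_meta = se / sqrt(k)
  for (k in 2:5) {
    mk <- ivw_meta(rep(0.2, k), rep(0.07, k))
    expect_equal(mk$se_meta, 0.07 / sqrt(k), tolerance = 1e-12)
    expect_equal(mk$het_stat, 0)
  }
  # for two studies Cochran's Q equals the two-cohort statistic
  q <- ivw_meta(c(0.25, 0.05), c(0.06, 0.11))
  expect_equal(q$het_stat,
               heterogeneity_test(0.25, 0.06, 0.05, 0.11)$het_stat,
               tolerance = 1e-12)
  expect_error(ivw_meta(0.2, 0.1), "two")
  # the pooled SE never exceeds the smallest input SE
  expect_lte(m2$se_meta, 0.1)
})

test_that("replication classification covers the rule lattice exhaustively", {
  thr <- significance_thresholds()
  rec <- function(p, sgn = 1) list(beta = sgn * 0.2, se = 0.04, pval = p)
  cats <- c("meta_significant", "replicated", "discovery_only_mts",
            "not_supported")

  # representative rule combinations
  expect_equal(classify_replication(rec(1e-10), rec(0.01),
                                    meta = list(pval_meta = 1e-12),
                                    thresholds = thr)$category,
               "meta_significant")
  # MTS discovery with a counter-directional replication
  expect_equal(classify_replication(rec(1e-10), rec(0.2, sgn = -1),
                                    thresholds = thr)$category,
               "discovery_only_mts")
  # GWS-not-MTS discovery: meta decides
  expect_equal(classify_replication(rec(3e-8), rec(0.2),
                                    meta = list(pval_meta = 2e-8),
                                    thresholds = thr)$category,
               "meta_significant")
  expect_equal(classify_replication(rec(3e-8), rec(0.2),
                                    meta = list(pval_meta = 1e-7),
                                    thresholds = thr)$category,
               "not_supported")
  # GWS discovery replicating at p < 0.05 without meta significance
  expect_equal(classify_replication(rec(3e-8), rec(0.01),
                                    meta = list(pval_meta = 1e-7),
                                    thresholds = thr)$category,
               "replicated")

  # exhaustive lattice: every combination lands in exactly one category
  for (disc_p in c(1e-10, 3e-8, 1e-7, 0.01)) {
    for (rep_p in c(0.01, 0.2)) {
      for (sgn in c(1, -1)) {
        for (meta_p in c(1e-12, 2e-8, 1e-7)) {
          call <- classify_replication(rec(disc_p), rec(rep_p, sgn),
                                       meta = list(pval_meta = meta_p),
                                       thresholds = thr)
          expect_length(call$category, 1L)
          expect_true(call$category %in% cats)
          if (sgn < 0) {
            # counter-directional pairs can never be meta-significant
            # or replicated
            expect_true(call$category %in%
                          c("discovery_only_mts", "not_supported"))
          }
        }
      }
    }
  }

  # when co-directional and no meta is passed, it is computed internally
  auto <- classify_replication(rec(1e-10), list(beta = 0.2, se = 0.04,
                                                pval = 1e-8),
                               thresholds = thr)
  expect_false(is.null(auto$meta))
  expect_equal(auto$category, "meta_significant")
})
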