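test_that("the model space implements the prior-halving rule", {
  ms2 <- build_model_space(c("A", "B"))
  w <- setNames(ms2$prior_weight, ms2$name)
  expect_equal(unname(w[c("null", "fixed", "correlated", "A", "B")]),
               c(1/4, 1/8, 1/8, 1/4, 1/4))
  expect_equal(sum(ms2$prior_weight), 1)

  # K = 4 with one declared subset: C = 7 compared models
  ms4 <- build_model_space(paste0("P", 1:4), subset_models = list(sp = 1:2))
  expect_equal(sum(ms4$prior_weight), 1)
  expect_equal(ms4$prior_weight[ms4$kind == "fixed"], 1/14)
  expect_equal(ms4$prior_weight[ms4$kind == "correlated"], 1/14)
  expect_equal(ms4$prior_weight[ms4$name == "sp"], 1/7)
  expect_error(build_model_space(paste0("P", 1:4),
                                 subset_models = list(1:2, c(2L, 1L))),
               "duplicate")

  # priors sum to 1 for arbitrary configurations
  for (K in c(2, 3, 5, 8)) {
    subs <- if (K > 2) list(1:2, 2:3) else NULL
    expect_equal(sum(build_model_space(paste0("P", 1:K), subs)$prior_weight), 1)
  }
})

test_that("posteriors match an independent first-principles computation", {
  space <- build_model_space(c("P1", "P2"))
  pr <- prior_config()
  cases <- list(
    list(betas = c(0.3, 0.3), ses = c(0.02, 0.02), R = diag(2)),
    list(betas = c(0.0, 0.0), ses = c(0.02, 0.02), R = diag(2)),
    list(betas = c(0.3, 0.0), ses = c(0.02, 0.02), R = diag(2)),
    list(betas = c(0.05, -0.04), ses = c(0.03, 0.05),
         R = matrix(c(1, 0.3, 0.3, 1), 2)),
    list(betas = c(0.12, 0.10), ses = c(0.02, 0.08),
         R = matrix(c(1, 0.5, 0.5, 1), 2)))
  for (cs in cases) {
    got <- model_posteriors(cs$betas, cs$ses, overlap_corr = cs$R,
                            model_space = space, prior = pr)
    want <- oracle_posteriors(cs$betas, cs$ses, cs$R, space,
                              pr$tau, pr$r_corr)
    expect_equal(got$posteriors, want, tolerance = 1e-9)
    expect_equal(sum(got$posteriors), 1, tolerance = 1e-9)
    expect_equal(got$shared_posterior,
                 unname(want["fixed"] + want["correlated"]),
                 tolerance = 1e-9)
  }
  # headline patterns
  expect_gt(model_posteriors(c(0.3, 0.3), c(0.02, 0.02))$shared_posterior,
            0.99)
  expect_equal(model_posteriors(c(0, 0), c(0.02, 0.02))$call, "null")
  mp_single <- model_posteriors(c(0.3, 0), c(0.02, 0.02))
  expect_equal(names(which.max(mp_single$compared)), "P1")
})

test_that("classification applies the posterior threshold with an uncertain fallback", {
  mk <- function(compared) {
    structure(list(compared = compared,
                   shared_posterior = unname(compared["shared"])),
              class = "model_posterior")
  }
  # a 73.3% shared posterior misses a 75% bar but passes 70%
  p <- mk(c(null = 0.10, shared = 0.733, P1 = 0.10, P2 = 0.067))
  expect_equal(classify_variant(p, threshold = 0.75), "uncertain")
  expect_equal(classify_variant(p, threshold = 0.70), "shared")
  expect_equal(classify_variant(
    mk(c(null = 0.9, shared = 0.05, P1 = 0.03, P2 = 0.02)), 0.7), "null")
  expect_equal(classify_variant(
    mk(c(null = 0.05, shared = 0.45, P1 = 0.45, P2 = 0.05)), 0.7),
    "uncertain")
})

test_that("with one phenotype the framework reduces to the Wakefield ABF", {
  beta <- 0.08; se <- 0.02; tau <- 0.2
  mp <- model_posteriors(beta, se, model_space = build_model_space("A"),
                         prior = prior_config(tau = tau))
  # hand-computed two-model posterior: ABF = sqrt(se^2/(se^2+tau^2)) *
  # exp(z^2 tau^2 / (2 (se^2+tau^2))), equal priors
  z2 <- (beta / se)^2
  abf <- sqrt(se^2 / (se^2 + tau^2)) * exp(z2 * tau^2 / (2 * (se^2 + tau^2)))
  expect_equal(unname(mp$posteriors["A"]), abf / (1 + abf), tolerance = 1e-9)
})

test_that("calls are invariant under joint rescaling of betas, ses and tau", {
  set.seed(91L)
  for (i in 1:10) {
    betas <- rnorm(2, sd = 0.1); ses <- runif(2, 0.01, 0.05)
    s <- runif(1, 0.5, 3)
    a <- model_posteriors(betas, ses, prior = prior_config(tau = 0.2))
    b <- model_posteriors(s * betas, s * ses,
                          prior = prior_config(tau = s * 0.2))
    expect_equal(a$posteriors, b$posteriors, tolerance = 1e-8)
  }
})

test_that("overlap correlation is estimated from null z-scores or the design", {
  # disjoint subjects: off-diagonal near zero
  set.seed(101L)
  Z <- matrix(rnorm(2e4), 1e4, 2)
  R0 <- estimate_overlap_correlation(Z)
  expect_lt(abs(R0[1, 2]), 0.03)

  # the same phenotype twice: correlation near one
  z1 <- rnorm(5e3)
  R1 <- estimate_overlap_correlation(cbind(z1, z1 + rnorm(5e3, sd = 1e-3)))
  expect_gt(R1[1, 2], 0.99)

  # too few null variants directs to the design route
  expect_error(estimate_overlap_correlation(matrix(rnorm(200), 100, 2)),
               "design")

  # empirical estimate agrees with the known generating correlation
  d <- overlap_design(c("A", "B"), c(4000L, 6000L), 150000L)
  R_true <- overlap_correlation_design(d)
  tabs <- simulate_sumstats_direct(d, effect_config("null"), 15000L,
                                   seed = 102L)
  Zs <- cbind(tabs$A$beta / tabs$A$se, tabs$B$beta / tabs$B$se)
  R_emp <- estimate_overlap_correlation(Zs)
  expect_equal(R_emp[1, 2], R_true[1, 2], tolerance = 0.05)

  # design route sanity: equal case pools sharing all controls
  d2 <- overlap_design(c("A", "B"), c(1000L, 1000L), 1000L)
  expect_equal(overlap_correlation_design(d2)[1, 2], 0.5)
})

test_that("batch classification equals the per-variant path", {
  set.seed(111L)
  B <- matrix(rnorm(20, sd = 0.1), 10, 2)
  space <- build_model_space(c("P1", "P2"))
  batch <- classify_effects(B, c(0.02, 0.02), model_space = space)
  for (i in 1:10) {
    one <- model_posteriors(B[i, ], c(0.02, 0.02), model_space = space)
    expect_equal(batch$call[i], one$call)
    expect_equal(batch$shared_posterior[i], one$shared_posterior,
                 tolerance = 1e-9)
  }
})
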