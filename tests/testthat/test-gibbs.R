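## shared small data set with enough random-effect levels for the flat
## scalar-variance priors (pens, groups, dams, litters all > 2 levels)
gibbs_fixture <- local({
  sc <- sim_scenario(n_phenotyped = 100, n_founders = 30, n_generations = 2,
                     n_markers = 0, groups_per_pen = 2L, seed = 1234)
  d <- simulate_sge_data(sc)
  list(data = d$data, kern = relationship_set(d$pedigree),
       truth = d$scenario$components)
})

test_that("chain configuration does the retention arithmetic", {
  cfg <- gibbs_config(rounds = 550000, burn_in = 50000, thin = 50)
  expect_identical(cfg$n_retained, 10000L)
  expect_identical(gibbs_config(rounds = 100, burn_in = 0, thin = 1)$n_retained,
                   100L)
  expect_error(gibbs_config(rounds = 100, burn_in = 100), "burn_in")
  expect_error(gibbs_config(rounds = 100, burn_in = 10, thin = 7),
               "divisible")
})

test_that("summaries handle constant and reduced chains", {
  draws <- data.frame(var_aD = rep(5, 20), var_e = rep(2, 20))
  sm <- summarize_chain(draws)
  expect_equal(sm$mean, c(5, 2))
  expect_equal(sm$sd, c(0, 0))
})

test_that("location-only sampling centres on the MME solutions", {
  vc <- do.call(variance_components, gibbs_fixture$truth)
  cfg <- gibbs_config(rounds = 120000, burn_in = 20000, thin = 10, seed = 41)
  fit <- gibbs_fit(gibbs_fixture$data, gibbs_fixture$kern, cfg,
                   update_variances = FALSE, start = gibbs_fixture$truth)
  sol <- solve_mme(gibbs_fixture$data, gibbs_fixture$kern, vc)
  ## posterior means equal BLUP up to Monte-Carlo error, on the scale of
  ## the solutions themselves
  expect_gt(cor(fit$solutions$a_D, sol$a_D), 0.98)
  expect_lt(max(abs(fit$solutions$a_D - sol$a_D)), 0.15 * sd(sol$a_D) + 0.5)
  expect_lt(max(abs(fit$solutions$l - sol$l)), 0.15 * sd(sol$l) + 0.5)
})

test_that("single-site sampler agrees with an independent blocked sampler", {
  ## weakly-proper scalar priors on both routes: with only 8 pens a flat
  ## prior lets the pen variance wander to numerical infinity, where the
  ## nested pen/group columns become exactly collinear
  set.seed(99)
  ref <- blocked_gibbs_oracle(gibbs_fixture$data, gibbs_fixture$kern,
                              n_iter = 1100, burn_in = 300,
                              nu_sc = 6, s_sc = 300)
  fit <- gibbs_fit(gibbs_fixture$data, gibbs_fixture$kern,
                   gibbs_config(rounds = 24000, burn_in = 4000, thin = 4,
                                seed = 99, nu_scalar = 6, s_scalar = 300))
  m_ref <- colMeans(ref)
  m_fit <- colMeans(fit$samples)[names(m_ref)]
  ## agree on the well-identified scale parameters ...
  expect_lt(abs(m_fit["var_e"] - m_ref["var_e"]) / m_ref["var_e"], 0.15)
  expect_lt(abs(m_fit["var_aD"] - m_ref["var_aD"]) / m_ref["var_aD"], 0.5)
  tot <- function(m) sum(m[c("var_aD", "var_c", "var_g", "var_pe",
                             "var_l", "var_e")])
  expect_lt(abs(tot(m_fit) - tot(m_ref)) / tot(m_ref), 0.2)
  ## ... and neither chain is pinned at a singular covariance block
  r_fit <- fit$samples$cov_aDaS / sqrt(fit$samples$var_aD * fit$samples$var_aS)
  r_ref <- ref$cov_aDaS / sqrt(ref$var_aD * ref$var_aS)
  expect_lt(max(abs(r_fit)), 0.9999)
  expect_lt(max(abs(r_ref)), 0.9999)
})

test_that("reduced animal model recovers heritability from clean data", {
  eps <- 1e-8
  sc <- sim_scenario(n_phenotyped = 500, n_founders = 60, n_generations = 2,
                     n_markers = 0, seed = 2024,
                     components = list(var_aD = 2235, var_aS = eps,
                                       cov_aDaS = 0, var_c = eps, var_g = eps,
                                       var_pe = eps, var_l = eps, var_k = eps,
                                       cov_lk = 0, var_e = 3299))
  d <- simulate_sge_data(sc)
  fit <- gibbs_fit(d$data, relationship_set(d$pedigree),
                   gibbs_config(rounds = 15000, burn_in = 3000, thin = 3,
                                seed = 7),
                   random_terms = character(0))
  h2_draws <- fit$samples$var_aD / (fit$samples$var_aD + fit$samples$var_e)
  h2_true <- 2235 / (2235 + 3299)
  expect_lt(abs(mean(h2_draws) - h2_true), 2 * sd(h2_draws))
})

test_that("chains are reproducible from the seed", {
  cfg <- gibbs_config(rounds = 2000, burn_in = 500, thin = 3, seed = 11)
  f1 <- gibbs_fit(gibbs_fixture$data, gibbs_fixture$kern, cfg)
  f2 <- gibbs_fit(gibbs_fixture$data, gibbs_fixture$kern, cfg)
  expect_identical(f1$samples, f2$samples)
})

test_that("posterior_components collects full-model posterior means", {
  fit <- gibbs_fit(gibbs_fixture$data, gibbs_fixture$kern,
                   gibbs_config(rounds = 3000, burn_in = 1000, thin = 2,
                                seed = 3))
  vc <- posterior_components(fit)
  expect_s3_class(vc, "variance_components")
  expect_equal(vc$var_e, mean(fit$samples$var_e))
})
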