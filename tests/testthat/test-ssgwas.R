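test_that("back-solving inverts the breeding-value projection", {
  ## scalar closed form: u = a / z for one animal, one marker
  g1 <- genotype_matrix(matrix(2, 1, 1, dimnames = list("a", "m1")),
                        data.frame(marker = "m1", chrom = 1, pos = 1))
  g1$p <- 0.25  # centring fixed externally so z = 2 - 0.5 = 1.5
  eff <- backsolve_snp_effects(g1, a_g = 3, effect_kind = "DGE")
  expect_equal(unname(eff$u_hat), 3 / 1.5)

  ## zero breeding values give zero effects (fixed reference frequencies:
  ## with sample frequencies Z is column-centred and Z Z' is singular,
  ## which is why the pipeline blends G in practice)
  set.seed(12)
  g <- random_genotypes(10, 25)
  g$p <- rep(0.45, 25)
  eff0 <- backsolve_snp_effects(g, rep(0, 10))
  expect_equal(unname(eff0$u_hat), rep(0, 25))

  ## projection identity Z u = a_g on a random instance
  set.seed(13)
  g <- random_genotypes(15, 40)
  g$p <- runif(40, 0.3, 0.7)
  a_g <- rnorm(15, 0, 30)
  w <- runif(40, 0.5, 2)
  eff <- backsolve_snp_effects(g, a_g, weights = w)
  Z <- sweep(g$dosage, 2, 2 * g$p)
  expect_lt(max(abs(Z %*% eff$u_hat - a_g)), 1e-8)
})

test_that("weight updates conserve the carried genetic variance", {
  ## equal effects and frequencies give equal weights
  w <- update_weights(rep(2, 5), rep(0.3, 5))
  expect_equal(w, rep(w[1], 5))

  ## a single nonzero effect carries the whole normalisation mass
  p <- rep(0.5, 4)
  w <- update_weights(c(3, 0, 0, 0), p)
  expect_equal(w[-1], rep(0, 3))
  expect_equal(sum(w * 2 * p * (1 - p)), sum(1 * 2 * p * (1 - p)))

  ## conservation across an iteration chain, to 1e-12
  set.seed(14)
  u <- rnorm(100)
  p <- runif(100, 0.05, 0.95)
  het <- 2 * p * (1 - p)
  w1 <- update_weights(u, p)
  expect_lt(abs(sum(w1 * het) - sum(het)), 1e-12)
  w2 <- update_weights(rnorm(100), p, prev_weights = w1)
  expect_lt(abs(sum(w2 * het) - sum(w1 * het)), 1e-12)

  expect_error(update_weights(rep(0, 4), p[1:4]), "zero")
})

test_that("window variance decomposes the genomic variance by map position", {
  ## all markers in one window, self-normalised: 100%
  set.seed(15)
  g <- random_genotypes(12, 10)
  u <- rnorm(10)
  eff <- structure(list(u_hat = setNames(u, g$map$marker),
                        weights = rep(1, 10), iteration = 1L,
                        effect_kind = "DGE", map = g$map, p = g$p),
                   class = "snp_effect_set")
  wv <- window_variance(eff, g)
  expect_equal(nrow(wv), 1L)
  expect_equal(wv$pct_var, 100)

  ## zero effects with a fixed denominator: all windows 0
  eff0 <- eff
  eff0$u_hat[] <- 0
  wv0 <- window_variance(eff0, g, sigma2_a = 100)
  expect_equal(wv0$pct_var, 0)

  ## two engineered orthogonal blocks on separate chromosomes: 50% / 50%
  dos <- cbind(c(0, 0, 2, 2), c(0, 2, 0, 2))
  rownames(dos) <- sprintf("a%d", 1:4)
  g2 <- genotype_matrix(dos, data.frame(marker = c("mA", "mB"),
                                        chrom = c(1, 2), pos = c(100, 100)))
  eff2 <- structure(list(u_hat = c(mA = 1, mB = 1), weights = c(1, 1),
                         iteration = 1L, effect_kind = "DGE", map = g2$map,
                         p = g2$p),
                    class = "snp_effect_set")
  wv2 <- window_variance(eff2, g2)
  expect_equal(wv2$pct_var, c(50, 50), tolerance = 1e-6)
})

test_that("the window decomposition audit closes exactly", {
  set.seed(16)
  g <- random_genotypes(20, 30, n_chrom = 3)
  u <- rnorm(30, 0, 2)
  eff <- structure(list(u_hat = setNames(u, g$map$marker),
                        weights = rep(1, 30), iteration = 1L,
                        effect_kind = "SGE", map = g$map, p = g$p),
                   class = "snp_effect_set")
  wv <- window_variance(eff, g, keep_values = TRUE)
  gv <- attr(wv, "genomic_values")
  total_var <- var(rowSums(gv))
  cv <- cov(gv)
  expect_equal(sum(diag(cv)) + 2 * sum(cv[upper.tri(cv)]), total_var,
               tolerance = 1e-10)
  ## percentages are invariant to rescaling the breeding values in
  ## self-normalised mode
  eff_s <- eff
  eff_s$u_hat <- eff$u_hat * 4.2
  wv_s <- window_variance(eff_s, g)
  expect_equal(wv_s$pct_var, wv$pct_var, tolerance = 1e-10)
})

test_that("QTL calling is inclusive at the threshold and sorted", {
  wv <- structure(data.frame(chrom = 1, start_bp = c(1, 1e6 + 1, 2e6 + 1),
                             end_bp = c(1e6, 2e6, 3e6),
                             label = c("w1", "w2", "w3"), n_snps = 5,
                             pct_var = c(0.4, 0.5, 2.0)),
                  class = c("snp_window_result", "data.frame"))
  hits <- call_qtl(wv)
  expect_equal(hits$label, c("w3", "w2"))
  expect_equal(nrow(call_qtl(wv, threshold_pct = 3)), 0L)
})

test_that("a single ssGWAS iteration is a plain back-solve", {
  set.seed(18)
  sc <- sim_scenario(n_phenotyped = 120, n_founders = 30, n_generations = 2,
                     n_markers = 60, n_chromosomes = 2, chromosome_bp = 3e6,
                     genotyped = "phenotyped", seed = 18)
  d <- simulate_sge_data(sc)
  geno <- qc_genotypes(subset_genotypes(d$genotypes, d$genotyped_ids))$genotypes
  kern <- relationship_set(d$pedigree, geno)
  vc <- table1_components()
  eff1 <- run_ssgwas(d$data, kern, vc, "DGE", n_iterations = 1)
  sol <- solve_mme(d$data, kern, vc)
  ref <- backsolve_snp_effects(geno, sol$a_D[kern$genotyped_index],
                               effect_kind = "DGE",
                               blend_eps = kern$blend_eps, A22 = kern$A22,
                               q = kern$q)
  expect_equal(eff1$u_hat, ref$u_hat, tolerance = 1e-10)

  ## DGE and SGE runs differ (effect-kind-specific weights)
  effS <- run_ssgwas(d$data, kern, vc, "SGE", n_iterations = 1)
  expect_false(isTRUE(all.equal(eff1$u_hat, effS$u_hat)))
})
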