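test_that("pedigree simulation produces valid structured pedigrees", {
  sc <- sim_scenario(n_phenotyped = 4, n_founders = 6, n_generations = 1,
                     n_markers = 0, seed = 1)
  set.seed(1)
  sim <- simulate_pedigree(sc)
  expect_s3_class(sim$ped, "pedigree")
  expect_equal(sum(sim$meta$generation == 0L), 6L)
  expect_equal(sum(sim$meta$generation == 1L), 4L)

  ## founders only
  sc0 <- sim_scenario(n_phenotyped = 4, n_founders = 10, n_generations = 1,
                      n_markers = 0, seed = 2)
  set.seed(2)
  sim0 <- simulate_pedigree(sc0)
  expect_true(all(is.na(sim0$meta$litter[sim0$meta$generation == 0L])))

  ## family sizes track the configured mean on a large run
  sc2 <- sim_scenario(n_phenotyped = 2000, n_founders = 100,
                      n_generations = 2, n_markers = 0, seed = 3)
  set.seed(3)
  sim2 <- simulate_pedigree(sc2)
  fam <- table(paste(sim2$meta$sire, sim2$meta$dam, sim2$meta$litter)[
    sim2$meta$generation > 0])
  expect_lt(abs(mean(fam) - 4.12) / 4.12, 0.10)
  ## dams are reused across litters
  kids <- sim2$meta[sim2$meta$generation > 0, ]
  expect_gt(mean(table(unique(kids[c("dam", "litter")])$dam)), 2)
})

test_that("gene dropping respects allele frequencies and inheritance", {
  ## fixed allele: every dosage is 2
  sc <- sim_scenario(n_phenotyped = 20, n_founders = 10, n_generations = 1,
                     n_markers = 5, n_chromosomes = 1, maf_range = c(1, 1),
                     seed = 4)
  set.seed(4)
  sim <- simulate_pedigree(sc)
  g <- simulate_genotypes(sim, sc)
  expect_true(all(g$dosage == 2))

  ## founders sit in Hardy-Weinberg proportions at p = 0.5
  sc2 <- sim_scenario(n_phenotyped = 4, n_founders = 3000, n_generations = 1,
                      n_markers = 1, n_chromosomes = 1,
                      maf_range = c(0.5, 0.5), seed = 5)
  set.seed(5)
  sim2 <- simulate_pedigree(sc2)
  g2 <- simulate_genotypes(sim2, sc2)
  fr <- table(factor(g2$dosage[sim2$meta$generation == 0L, 1], 0:2)) / 3000
  expect_lt(max(abs(fr - c(0.25, 0.5, 0.25))), 3 * sqrt(0.25 * 0.75 / 3000))

  ## genomic relationship of full sibs is centred on the pedigree value 0.5
  sc3 <- sim_scenario(n_phenotyped = 400, n_founders = 60, n_generations = 1,
                      n_markers = 400, n_chromosomes = 2, seed = 6)
  set.seed(6)
  sim3 <- simulate_pedigree(sc3)
  g3 <- simulate_genotypes(sim3, sc3)
  gb <- build_G(g3, target_mean_diag = 1 + 0)
  kids <- sim3$meta[sim3$meta$generation == 1L, ]
  fs <- merge(kids, kids, by = "litter")
  fs <- fs[fs$id.x < fs$id.y, ]
  rel <- gb$G[cbind(fs$id.x, fs$id.y)]
  ## pairs share markers, so their relationships are correlated; an
  ## absolute band replaces the naive 3-SE bound
  expect_lt(abs(mean(rel) - 0.5), 0.02)
})

test_that("phenotypes follow the generative model equation", {
  ## all variances zero: records equal the fixed part exactly
  z <- 0
  sc <- sim_scenario(n_phenotyped = 60, n_founders = 20, n_generations = 1,
                     n_markers = 0, seed = 7,
                     components = list(var_aD = z, var_aS = z, cov_aDaS = z,
                                       var_c = z, var_g = z, var_pe = z,
                                       var_l = z, var_k = z, cov_lk = z,
                                       var_e = z))
  d <- simulate_sge_data(sc)
  expect_equal(d$data$records$y, unname(d$truth$fixed), tolerance = 1e-12)

  ## uncorrelated components: empirical corr(a_D, a_S) near zero
  sc2 <- sim_scenario(n_phenotyped = 1200, n_founders = 100,
                      n_generations = 2, n_markers = 0, seed = 8,
                      components = list(var_aD = 2235, var_aS = 16,
                                        cov_aDaS = 0, var_c = 43, var_g = 227,
                                        var_pe = 48, var_l = 218, var_k = 17,
                                        cov_lk = 0, var_e = 3299))
  d2 <- simulate_sge_data(sc2)
  expect_lt(abs(cor(d2$truth$a_D, d2$truth$a_S)), 0.15)

  ## non-positive-definite genetic block is rejected
  expect_error(sim_scenario(components = list(
    var_aD = 10, var_aS = 10, cov_aDaS = 11, var_c = 1, var_g = 1,
    var_pe = 1, var_l = 1, var_k = 1, cov_lk = 0, var_e = 1)),
    "positive semidefinite")
})

test_that("large simulations reproduce the phenotypic-variance arithmetic", {
  sc <- sim_scenario(n_phenotyped = 3000, n_founders = 150,
                     n_generations = 3, n_markers = 0, seed = 9)
  d <- simulate_sge_data(sc)
  gp <- genetic_parameters(table1_components(), d$data$mean_group_size)
  ## total phenotypic variance matches the model formula
  expect_lt(abs(var(d$data$records$y) - var(d$truth$fixed) - gp$var_P) /
              gp$var_P, 0.10)
  ## realized T2 (variance of true TBV over phenotypic variance) is close
  ## to the formula value
  t2_emp <- var(d$truth$TBV[d$data$records$animal]) /
    (var(d$data$records$y) - var(d$truth$fixed))
  expect_lt(abs(t2_emp - gp$T2), 0.05)
})

test_that("planted QTLs carry the requested variance fraction", {
  sc <- sim_scenario(n_phenotyped = 800, n_founders = 80, n_generations = 1,
                     n_markers = 100, n_chromosomes = 2,
                     genotyped = "phenotyped",
                     planted_qtl = data.frame(marker = "auto", frac = 0.10),
                     seed = 10)
  d <- simulate_sge_data(sc)
  qm <- names(d$truth$beta)
  expect_length(qm, 1L)
  z <- d$genotypes$dosage[names(d$truth$a_D), qm]
  qtl_var <- var(z * d$truth$beta)
  expect_lt(abs(qtl_var - 0.10 * 2235) / (0.10 * 2235), 0.25)
  expect_lt(abs(var(d$truth$a_D) - 2235) / 2235, 0.25)
})
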