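test_that("A matrix reproduces textbook path coefficients", {
  ## two unrelated founders
  f2 <- pedigree(c("A", "B"), c(NA, NA), c(NA, NA))
  expect_equal(unname(build_A(f2)), diag(2))

  ## founder pair + offspring
  trio <- pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
  A <- build_A(trio)
  expect_equal(A["C", "A"], 0.5)
  expect_equal(A["C", "C"], 1.0)

  ## offspring of full sibs is inbred with F = 0.25
  ped <- pedigree(c("A", "B", "C", "D", "E"),
                  c(NA, NA, "A", "A", "C"),
                  c(NA, NA, "B", "B", "D"))
  expect_equal(build_A(ped)["E", "E"], 1.25)
  expect_equal(unname(inbreeding(ped)["E"]), 0.25)
})

test_that("A equals the recursive-kinship oracle exactly on small pedigrees", {
  set.seed(421)
  for (rep in 1:40) {
    ped <- random_pedigree(sample(1:12, 1L))
    expect_identical(unname(build_A(ped)), kinship_oracle(ped))
  }
})

test_that("A-inverse follows Henderson's rules with inbreeding", {
  f3 <- pedigree(c("A", "B", "C"), rep(NA, 3), rep(NA, 3))
  expect_equal(as.matrix(build_A_inverse(f3)), diag(3),
               ignore_attr = TRUE)

  trio <- pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
  expect_lt(max(abs(as.matrix(build_A_inverse(trio) %*% build_A(trio)) -
                    diag(3))), 1e-10)

  ## inbred pedigree: matches the dense inverse
  ped <- pedigree(sprintf("I%d", 1:10),
                  c(NA, NA, "I1", "I1", "I3", "I3", "I5", "I5", "I7", "I7"),
                  c(NA, NA, "I2", "I2", "I4", "I4", "I6", "I6", "I8", "I8"))
  expect_lt(max(abs(as.matrix(build_A_inverse(ped)) - solve(build_A(ped)))),
            1e-8)
})

test_that("A-inverse times A is the identity on random pedigrees", {
  set.seed(77)
  for (n in c(25, 60, 100)) {
    ped <- random_pedigree(n)
    err <- max(abs(as.matrix(build_A_inverse(ped) %*% build_A(ped)) - diag(n)))
    expect_lt(err, 1e-8)
  }
})

test_that("A matches Monte-Carlo gene dropping on a 30-animal pedigree", {
  set.seed(90210)
  n <- 30L
  ped <- random_pedigree(n)
  A <- build_A(ped)
  R <- 200000L
  ## drop two uniquely labelled alleles per founder down the pedigree
  al1 <- al2 <- vector("list", n)
  lab <- 0L
  for (i in seq_len(n)) {
    pick <- function(p) {
      if (p == 0L) {
        lab <<- lab + 1L
        rep.int(lab, R)
      } else {
        sw <- stats::runif(R) < 0.5
        ifelse(sw, al1[[p]], al2[[p]])
      }
    }
    al1[[i]] <- pick(ped$sire[i])
    al2[[i]] <- pick(ped$dam[i])
  }
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      if (i == j) next
      k_rep <- ((al1[[i]] == al1[[j]]) + (al1[[i]] == al2[[j]]) +
                (al2[[i]] == al1[[j]]) + (al2[[i]] == al2[[j]])) / 4
      est <- mean(k_rep)
      se <- stats::sd(k_rep) / sqrt(R)
      ## 4 SE: family-wise slack over the 435 simultaneous checks
      expect_lt(abs(A[i, j] / 2 - est), 4 * se + 1e-5)
    }
  }
})

test_that("G construction scales, weights and matches brute force", {
  ## one marker, p = 0.5, dosages 0/1/2: Z = (-1, 0, 1), q = 1
  g1 <- genotype_matrix(matrix(c(0, 1, 2), 3, 1,
                               dimnames = list(c("a", "b", "c"), "m1")),
                        data.frame(marker = "m1", chrom = 1, pos = 100))
  gb <- build_G(g1)
  expect_equal(gb$q, 1)
  expect_equal(unname(gb$G), tcrossprod(c(-1, 0, 1)))

  ## doubling weights at fixed target leaves G unchanged, halves q
  set.seed(5)
  g <- random_genotypes(12, 8)
  b1 <- build_G(g, weights = rep(1, 8), target_mean_diag = 1)
  b2 <- build_G(g, weights = rep(2, 8), target_mean_diag = 1)
  expect_equal(b2$G, b1$G, tolerance = 1e-12)
  expect_equal(b2$q, b1$q / 2)

  ## 20 x 50 instance against the naive triple product
  set.seed(6)
  g <- random_genotypes(20, 50)
  w <- stats::runif(50, 0.5, 2)
  gb <- build_G(g, weights = w, target_mean_diag = 1.01)
  Z <- sweep(g$dosage, 2, 2 * g$p)
  ref <- Z %*% diag(w) %*% t(Z)
  ref <- ref * 1.01 / mean(diag(ref))
  expect_lt(max(abs(gb$G - ref)), 1e-10)
  expect_lt(abs(mean(diag(gb$G)) - 1.01), 1e-10)

  ## monomorphic marker and empty set are rejected
  gm <- genotype_matrix(matrix(c(2, 2, 2, 0, 1, 2), 3, 2,
                               dimnames = list(c("a", "b", "c"), NULL)),
                        data.frame(marker = c("m1", "m2"), chrom = 1,
                                   pos = c(1, 2)))
  expect_error(build_G(gm), "monomorphic")
})

test_that("H-inverse has the printed block structure", {
  set.seed(8)
  ped <- random_pedigree(8)
  A <- build_A(ped)
  Ainv <- build_A_inverse(ped)

  ## no genotyped animals: H^-1 = A^-1
  H0 <- build_H_inverse(Ainv, NULL, NULL, integer(0))
  expect_lt(max(abs(as.matrix(H0) - as.matrix(Ainv))), 1e-12)

  ## G = A22: the block cancels
  gi <- c(2L, 4L, 5L, 7L)
  A22 <- A[gi, gi]
  H1 <- build_H_inverse(Ainv, solve(A22), solve(A22), gi)
  expect_lt(max(abs(as.matrix(H1) - as.matrix(Ainv))), 1e-10)

  ## general case against explicit dense assembly
  set.seed(9)
  g <- random_genotypes(4, 30)
  rownames(g$dosage) <- ped$id[gi]
  gb <- build_G(g, target_mean_diag = mean(diag(A22)),
                blend_eps = 0.05, A22 = A22)
  H <- build_H_inverse(Ainv, solve(A22), solve(gb$G), gi)
  ref <- as.matrix(Ainv)
  ref[gi, gi] <- ref[gi, gi] + solve(gb$G) - solve(A22)
  expect_lt(max(abs(as.matrix(H) - ref)), 1e-10)
  expect_lt(max(abs(as.matrix(H) - t(as.matrix(H)))), 1e-12)
  ## positive definite with blending on
  expect_gt(min(eigen(as.matrix(H), symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("relationship_set wires pedigree and genomic parts together", {
  set.seed(10)
  ped <- random_pedigree(12)
  g <- random_genotypes(5, 40)
  rownames(g$dosage) <- ped$id[c(3, 5, 8, 10, 12)]
  g <- genotype_matrix(g$dosage, g$map)
  ks <- relationship_set(ped, g)
  expect_identical(ks$genotyped_index, c(3L, 5L, 8L, 10L, 12L))
  expect_lt(abs(mean(diag(ks$G)) - mean(diag(ks$A22))), 1e-10)
  expect_lt(max(abs(as.matrix(ks$G_inv %*% ks$G) - diag(5))), 1e-8)
})
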