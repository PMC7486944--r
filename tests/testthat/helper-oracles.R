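## Independent oracles and small fixtures shared across the test files.

## random pedigree: animal i draws each parent from earlier animals (or
## unknown); uses the ambient RNG state
random_pedigree <- function(n, p_known = 0.7) {
  sire <- dam <- rep(NA_character_, n)
  ids <- sprintf("P%03d", seq_len(n))
  for (i in seq_len(n)) {
    if (i >= 3L) {
      if (stats::runif(1) < p_known) sire[i] <- ids[sample.int(i - 1L, 1L)]
      if (stats::runif(1) < p_known) {
        d <- ids[sample.int(i - 1L, 1L)]
        if (is.na(sire[i]) || d != sire[i]) dam[i] <- d
      }
    }
  }
  pedigree(ids, sire, dam)
}

## recursive-kinship brute force: phi(i,i) = 0.5 (1 + phi(s,d)),
## phi(i,j) = 0.5 (phi(s_i,j) + phi(d_i,j)) for j < i; A = 2 phi
kinship_oracle <- function(ped) {
  n <- length(ped$id)
  si <- ped$sire
  di <- ped$dam
  phi <- matrix(NA_real_, n, n)
  get <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (!is.na(phi[i, j])) return(phi[i, j])
    v <- if (i == j) {
      0.5 * (1 + get(si[i], di[i]))
    } else if (i > j) {
      0.5 * (get(si[i], j) + get(di[i], j))
    } else {
      0.5 * (get(si[j], i) + get(di[j], i))
    }
    phi[i, j] <<- v
    phi[j, i] <<- v
    v
  }
  for (i in seq_len(n)) for (j in seq_len(i)) get(i, j)
  2 * phi
}

## dense GLS / BLUP oracle for the full social-effects model:
## b = (X'V^-1 X)^-1 X'V^-1 y on the marginal covariance V, random effects
## u_r = Cov(u_r, y) V^-1 (y - X b)
gls_oracle <- function(data, ped, components) {
  des <- build_design(data, ped)
  A <- build_A(ped)
  X <- as.matrix(des$X)
  y <- des$y
  ZD <- as.matrix(des$Z_D); ZS <- as.matrix(des$Z_S)
  W <- as.matrix(des$W); V <- as.matrix(des$V); Tm <- as.matrix(des$T)
  U <- as.matrix(des$U); Q <- as.matrix(des$Q)
  cm <- components
  AD <- A %*% t(ZD); AS <- A %*% t(ZS)
  Vy <- cm$var_aD * ZD %*% AD + cm$var_aS * ZS %*% AS +
    cm$cov_aDaS * (ZD %*% AS + ZS %*% AD) +
    cm$var_c * tcrossprod(W) + cm$var_g * tcrossprod(V) +
    cm$var_pe * tcrossprod(Tm) + cm$var_l * tcrossprod(U) +
    cm$cov_lk * (U %*% t(Q) + Q %*% t(U)) + cm$var_k * tcrossprod(Q) +
    diag(cm$var_e, length(y))
  Vi <- solve(Vy)
  XtVi <- t(X) %*% Vi
  b <- solve(XtVi %*% X, XtVi %*% y)
  r <- Vi %*% (y - X %*% b)
  list(b = drop(b),
       a_D = drop((cm$var_aD * AD + cm$cov_aDaS * AS) %*% r),
       a_S = drop((cm$cov_aDaS * AD + cm$var_aS * AS) %*% r),
       c = drop(cm$var_c * t(W) %*% r),
       g = drop(cm$var_g * t(V) %*% r),
       pe = drop(cm$var_pe * t(Tm) %*% r),
       l = drop((cm$var_l * t(U) + cm$cov_lk * t(Q)) %*% r),
       k = drop((cm$cov_lk * t(U) + cm$var_k * t(Q)) %*% r))
}

## hand-built 6-record data set: 4 founders, 6 offspring in 2 groups of 3
toy_data <- function() {
  ped <- pedigree(c("S1", "S2", "D1", "D2", "O1", "O2", "O3", "O4", "O5", "O6"),
                  c(NA, NA, NA, NA, "S1", "S1", "S1", "S2", "S2", "S2"),
                  c(NA, NA, NA, NA, "D1", "D1", "D2", "D2", "D2", "D1"))
  rec <- data.frame(
    animal = c("O1", "O2", "O3", "O4", "O5", "O6"),
    y = c(810, 795, 830, 788, 805, 821),
    yearmonth = rep("m1", 6),
    sex = c("M", "M", "M", "F", "F", "F"),
    age = c(150, 152, 148, 155, 151, 149),
    pen = c("p1", "p1", "p1", "p2", "p2", "p2"),
    group = c("g1", "g1", "g1", "g2", "g2", "g2"),
    litter = c("L1", "L1", "L2", "L3", "L3", "L1"),
    dam = c("D1", "D1", "D2", "D2", "D2", "D1"),
    stringsAsFactors = FALSE)
  list(ped = ped, data = grouped_phenotypes(rec))
}

table1_components <- function() {
  variance_components(var_aD = 2235, var_aS = 16, cov_aDaS = 43,
                      var_c = 43, var_g = 227, var_pe = 48,
                      var_l = 218, var_k = 17, cov_lk = 36, var_e = 3299)
}

## small random genotype panel (no pedigree structure)
random_genotypes <- function(n_animals, n_markers, n_chrom = 1L) {
  p0 <- stats::runif(n_markers, 0.2, 0.8)
  dos <- sapply(p0, function(p) stats::rbinom(n_animals, 2L, p))
  ## regenerate monomorphic columns deterministically
  for (j in seq_len(n_markers)) {
    while (length(unique(dos[, j])) == 1L)
      dos[, j] <- stats::rbinom(n_animals, 2L, 0.5)
  }
  rownames(dos) <- sprintf("G%03d", seq_len(n_animals))
  per <- ceiling(n_markers / n_chrom)
  map <- data.frame(marker = sprintf("m%03d", seq_len(n_markers)),
                    chrom = rep(seq_len(n_chrom), each = per)[seq_len(n_markers)],
                    pos = rep(seq_len(per) * 1000L, n_chrom)[seq_len(n_markers)])
  genotype_matrix(dos, map)
}
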