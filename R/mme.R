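## Shared assembly of the mixed-model equation pieces used by both the
## direct solver and the Gibbs sampler.  Effect layout (fixed order for
## reproducible output): b, a_D, a_S, c (pen), g (group), pe (dam), l, k.

.as_general_csparse <- function(m) {
  methods::as(methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix"),
              "dMatrix")
}

.mme_structures <- function(data, kernel,
                            random_terms = c("sge", "pen", "group", "pe",
                                             "litter")) {
  stopifnot(inherits(data, "grouped_phenotypes"),
            inherits(kernel, "relationship_set"))
  des <- build_design(data, kernel$pedigree)
  has <- function(t) t %in% random_terms

  X <- des$X
  ## guard against a rank-deficient fixed block: drop dependent columns
  qrX <- qr(as.matrix(X))
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    message("fixed-effect block rank deficient; dropping column(s): ",
            paste(colnames(X)[-keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    des$levels$fixed <- colnames(X)
  }

  blocks <- list(X)
  nped <- length(kernel$pedigree$id)
  nlit <- length(des$levels$litter)
  len <- c(fix = ncol(X), aD = nped, aS = if (has("sge")) nped else 0L,
           c = if (has("pen")) ncol(des$W) else 0L,
           g = if (has("group")) ncol(des$V) else 0L,
           pe = if (has("pe")) ncol(des$T) else 0L,
           l = if (has("litter")) nlit else 0L,
           k = if (has("litter")) nlit else 0L)
  blocks <- c(blocks, list(des$Z_D))
  if (has("sge")) blocks <- c(blocks, list(des$Z_S))
  if (has("pen")) blocks <- c(blocks, list(des$W))
  if (has("group")) blocks <- c(blocks, list(des$V))
  if (has("pe")) blocks <- c(blocks, list(des$T))
  if (has("litter")) blocks <- c(blocks, list(des$U, des$Q))
  Wf <- do.call(cbind, blocks)
  off <- cumsum(c(0L, unname(len)))[seq_along(len)]
  names(off) <- names(len)

  y <- des$y
  list(Wf = Wf,
       WtW = .as_general_csparse(Matrix::crossprod(Wf)),
       Wty = as.numeric(Matrix::crossprod(Wf, y)),
       yty = sum(y^2), n_records = length(y),
       Kinv = .as_general_csparse(kernel$H_inv),
       off = off, len = len, des = des,
       random_terms = random_terms)
}

## sigma_e^2 * (prior precision) as one sparse block-diagonal matrix
.prior_precision <- function(str, components) {
  len <- str$len
  blocks <- list(Matrix::Matrix(0, len["fix"], len["fix"], sparse = TRUE))
  Kinv <- str$Kinv
  if (len["aS"] > 0L) {
    Cm <- with(components, matrix(c(var_aD, cov_aDaS, cov_aDaS, var_aS), 2L))
    blocks <- c(blocks, list(kronecker(solve(Cm), Kinv)))
  } else {
    blocks <- c(blocks, list(Kinv / components$var_aD))
  }
  if (len["c"] > 0L)
    blocks <- c(blocks, list(Matrix::Diagonal(len["c"]) / components$var_c))
  if (len["g"] > 0L)
    blocks <- c(blocks, list(Matrix::Diagonal(len["g"]) / components$var_g))
  if (len["pe"] > 0L)
    blocks <- c(blocks, list(Matrix::Diagonal(len["pe"]) / components$var_pe))
  if (len["l"] > 0L) {
    B <- with(components, matrix(c(var_l, cov_lk, cov_lk, var_k), 2L))
    blocks <- c(blocks, list(kronecker(solve(B), Matrix::Diagonal(len["l"]))))
  }
  do.call(Matrix::bdiag, blocks)
}

.split_solutions <- function(theta, str) {
  len <- str$len
  off <- str$off
  lev <- str$des$levels
  grab <- function(slot, labels) {
    if (len[slot] == 0L) return(NULL)
    stats::setNames(theta[(off[slot] + 1L):(off[slot] + len[slot])], labels)
  }
  list(b = grab("fix", lev$fixed),
       a_D = grab("aD", lev$animal),
       a_S = grab("aS", lev$animal),
       c = grab("c", lev$pen),
       g = grab("g", lev$group),
       pe = grab("pe", lev$pe),
       l = grab("l", lev$litter),
       k = grab("k", lev$litter))
}

#' Solve Henderson's mixed-model equations
#'
#' Computes BLUE fixed-effect and BLUP random-effect solutions of the full
#' social-effects model at fixed variance components, using the single-step
#' relationship kernel (`H^-1`, which is `A^-1` when no animals are
#' genotyped).  The direct (`a_D`) and social (`a_S`) genetic solution
#' vectors feed the single-step GWAS.
#'
#' @param data a [grouped_phenotypes()] object.
#' @param kernel a [relationship_set()].
#' @param components a [variance_components()] object.
#' @param random_terms random terms to include besides the direct genetic
#'   effect; the default is the full model.  `"sge"` adds the social genetic
#'   effect, `"litter"` adds the correlated birth-litter/early-life pair.
#' @return list of named solution vectors `b`, `a_D`, `a_S`, `c`, `g`, `pe`,
#'   `l`, `k` (absent terms are `NULL`).
#' @export
solve_mme <- function(data, kernel, components,
                      random_terms = c("sge", "pen", "group", "pe",
                                       "litter")) {
  stopifnot(inherits(components, "variance_components"))
  str <- .mme_structures(data, kernel, random_terms)
  C <- str$WtW + components$var_e * .prior_precision(str, components)
  theta <- as.numeric(Matrix::solve(C, str$Wty))
  out <- .split_solutions(theta, str)
  out$mean_group_size <- str$des$mean_group_size
  out
}
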