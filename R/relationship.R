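#' Genomic relationship matrix (VanRaden method 1, weighted)
#'
#' Computes `G = Z D Z' q` where `Z` is the allele-frequency-centred gene
#' content matrix, `D = diag(weights)` and `q` is a scaling factor chosen so
#' that the mean diagonal of `G` equals `target_mean_diag` (conventionally the
#' mean diagonal of the pedigree submatrix `A22` for the genotyped animals).
#' Optionally the scaled matrix is blended with `A22`,
#' `G <- (1 - blend_eps) G + blend_eps A22`, to guarantee invertibility;
#' `blend_eps = 0` reproduces the unblended formula exactly.
#'
#' @param geno a [genotype_matrix()] with no missing dosages and no
#'   monomorphic markers.
#' @param weights per-marker weights (default all 1).
#' @param target_mean_diag scalar; default the raw mean diagonal of `Z D Z'`
#'   (giving `q = 1`).
#' @param blend_eps blending proportion toward `A22` in `[0, 1)`.
#' @param A22 pedigree relationship submatrix of the genotyped animals;
#'   required when `blend_eps > 0`.
#' @return list with elements `G` (symmetric PSD matrix), `q`, `weights`,
#'   `blend_eps`.
#' @export
build_G <- function(geno, weights = NULL, target_mean_diag = NULL,
                    blend_eps = 0, A22 = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  m <- ncol(geno$dosage)
  if (m == 0L) stop("empty marker set")
  if (any(geno$p <= 0 | geno$p >= 1))
    stop("monomorphic marker(s): ",
         paste(utils::head(geno$map$marker[geno$p <= 0 | geno$p >= 1], 5L),
               collapse = ", "))
  if (is.null(weights)) weights <- rep(1, m)
  stopifnot(length(weights) == m, all(weights >= 0))
  Z <- center_genotypes(geno)
  ZDZt <- tcrossprod(Z %*% diag(weights, m), Z)
  md <- mean(diag(ZDZt))
  if (md <= 0) stop("Z D Z' has nonpositive mean diagonal; degenerate weights")
  if (is.null(target_mean_diag)) target_mean_diag <- md
  q <- target_mean_diag / md
  G <- ZDZt * q
  if (blend_eps > 0) {
    if (is.null(A22)) stop("blend_eps > 0 requires A22")
    G <- (1 - blend_eps) * G + blend_eps * A22
  }
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(Z), rownames(Z))
  list(G = G, q = q, weights = weights, blend_eps = blend_eps)
}

#' Single-step H-inverse
#'
#' Assembles the inverse of the combined pedigree/genomic relationship
#' matrix: `H^-1 = A^-1` plus the block `G^-1 - A22^-1` added at the
#' positions of the genotyped animals.  With no genotyped animals
#' `H^-1 = A^-1`.
#'
#' @param A_inv pedigree relationship inverse (n x n, sparse or dense).
#' @param A22_inv inverse of the pedigree relationship submatrix of the
#'   genotyped animals.
#' @param G_inv inverse of the genomic relationship matrix.
#' @param genotyped_index integer positions of the genotyped animals within
#'   the pedigree ordering.
#' @return sparse symmetric matrix (`Matrix` package).
#' @export
build_H_inverse <- function(A_inv, A22_inv, G_inv, genotyped_index) {
  n <- nrow(A_inv)
  H <- methods::as(methods::as(A_inv, "CsparseMatrix"), "generalMatrix")
  if (length(genotyped_index) == 0L) return(H)
  ng <- length(genotyped_index)
  stopifnot(nrow(G_inv) == ng, nrow(A22_inv) == ng,
            all(genotyped_index >= 1L), all(genotyped_index <= n))
  blk <- as.matrix(G_inv - A22_inv)
  B <- Matrix::sparseMatrix(i = rep(genotyped_index, times = ng),
                            j = rep(genotyped_index, each = ng),
                            x = as.vector(blk), dims = c(n, n))
  H <- H + B
  methods::as(Matrix::forceSymmetric((H + Matrix::t(H)) / 2), "generalMatrix")
}

#' Relationship kernel for single-step evaluation
#'
#' Builds every relationship matrix the model needs from a pedigree and
#' (optionally) genotypes of a subset of the pedigree animals: `A`, `A^-1`,
#' `A22`, `A22^-1`, `G`, `G^-1`, `H^-1` and the scaling factor `q`.  With no
#' genotypes the kernel reduces to the pedigree matrices and `H^-1 = A^-1`.
#'
#' @param ped a [pedigree()].
#' @param geno optional [genotype_matrix()] whose animals all appear in the
#'   pedigree; these define the genotyped subset.
#' @param weights optional per-marker weights for `G`.
#' @param blend_eps blending of `G` toward `A22` before inversion (default
#'   0.05); set 0 for the raw VanRaden matrix (may be singular).
#' @return object of class `"relationship_set"`.
#' @export
relationship_set <- function(ped, geno = NULL, weights = NULL,
                             blend_eps = 0.05) {
  stopifnot(inherits(ped, "pedigree"))
  A <- build_A(ped)
  A_inv <- build_A_inverse(ped)
  out <- list(pedigree = ped, A = A, A_inv = A_inv,
              genotyped_index = integer(0), genotypes = NULL,
              A22 = NULL, A22_inv = NULL, G = NULL, G_inv = NULL,
              q = NA_real_, weights = NULL, blend_eps = blend_eps,
              H_inv = methods::as(methods::as(A_inv, "CsparseMatrix"),
                                  "generalMatrix"))
  class(out) <- "relationship_set"
  if (is.null(geno)) return(out)

  stopifnot(inherits(geno, "genotype_matrix"))
  gi <- match(rownames(geno$dosage), ped$id)
  if (anyNA(gi))
    stop("genotyped animals absent from pedigree: ",
         paste(rownames(geno$dosage)[is.na(gi)], collapse = ", "))
  A22 <- A[gi, gi, drop = FALSE]
  gb <- build_G(geno, weights = weights,
                target_mean_diag = mean(diag(A22)),
                blend_eps = blend_eps, A22 = A22)
  G_inv <- tryCatch(solve(gb$G), error = function(e)
    stop("G is singular; increase blend_eps (currently ", blend_eps,
         ") to stabilise it", call. = FALSE))
  out$genotyped_index <- gi
  out$genotypes <- geno
  out$A22 <- A22
  out$A22_inv <- solve(A22)
  out$G <- gb$G
  out$G_inv <- G_inv
  out$q <- gb$q
  out$weights <- gb$weights
  out$H_inv <- build_H_inverse(A_inv, out$A22_inv, G_inv, gi)
  out
}

#' @export
print.relationship_set <- function(x, ...) {
  cat("relationship_set:", length(x$pedigree$id), "animals,",
      length(x$genotyped_index), "genotyped\n")
  invisible(x)
}

#' Rebuild the genomic part of a relationship kernel with new SNP weights
#'
#' Used by the iterative ssGWAS: recomputes `G`, `G^-1` and `H^-1` with an
#' updated weight diagonal, keeping the target mean diagonal (that of `A22`)
#' and the blending proportion unchanged.
#'
#' @param kernel a [relationship_set()] with genotypes.
#' @param weights new per-marker weights.
#' @return updated `relationship_set`.
#' @export
update_G <- function(kernel, weights) {
  stopifnot(inherits(kernel, "relationship_set"),
            !is.null(kernel$genotypes))
  gb <- build_G(kernel$genotypes, weights = weights,
                target_mean_diag = mean(diag(kernel$A22)),
                blend_eps = kernel$blend_eps, A22 = kernel$A22)
  kernel$G <- gb$G
  kernel$q <- gb$q
  kernel$weights <- gb$weights
  kernel$G_inv <- tryCatch(solve(gb$G), error = function(e)
    stop("reweighted G is singular; increase blend_eps", call. = FALSE))
  kernel$H_inv <- build_H_inverse(kernel$A_inv, kernel$A22_inv,
                                  kernel$G_inv, kernel$genotyped_index)
  kernel
}
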