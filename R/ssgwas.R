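#' Back-solve SNP effects from genomic breeding values
#'
#' Converts the breeding values of the genotyped animals into per-marker
#' effects: `u = D Z' (Z D Z')^-1 a_g`, where `Z` is the centred gene-content
#' matrix and `D = diag(weights)`.  The projection identity `Z u = a_g`
#' holds whenever `Z D Z'` is inverted exactly (`blend_eps = 0`).  With
#' `blend_eps > 0` the same stabilisation used for `G` is applied:
#' `(Z D Z')` is replaced by `((1 - eps) Z D Z' q + eps A22) / q`.
#'
#' @param geno [genotype_matrix()] of the genotyped animals.
#' @param a_g breeding values of those animals (same order as `geno` rows).
#' @param weights per-marker weight diagonal `D` (default all 1).
#' @param effect_kind `"DGE"` or `"SGE"` (bookkeeping label).
#' @param blend_eps,A22,q stabilisation: blending proportion, pedigree
#'   submatrix and G-scaling factor (only used when `blend_eps > 0`).
#' @return object of class `"snp_effect_set"`: `u_hat`, `weights`,
#'   `iteration`, `effect_kind`, plus the marker map and frequencies.
#' @export
backsolve_snp_effects <- function(geno, a_g, weights = NULL,
                                  effect_kind = c("DGE", "SGE"),
                                  blend_eps = 0, A22 = NULL, q = NULL) {
  effect_kind <- match.arg(effect_kind)
  stopifnot(inherits(geno, "genotype_matrix"))
  m <- ncol(geno$dosage)
  if (is.null(weights)) weights <- rep(1, m)
  if (nrow(geno$dosage) != length(a_g))
    stop("a_g length (", length(a_g), ") != genotyped animals (",
         nrow(geno$dosage), ")")
  Z <- center_genotypes(geno)
  M <- tcrossprod(Z %*% diag(weights, m), Z)
  if (blend_eps > 0) {
    if (is.null(A22) || is.null(q))
      stop("blend_eps > 0 requires A22 and q")
    M <- (1 - blend_eps) * M + (blend_eps / q) * A22
  }
  sol <- tryCatch(solve(M, a_g), error = function(e)
    stop("Z D Z' is singular; set blend_eps > 0 to stabilise it",
         call. = FALSE))
  u <- weights * as.numeric(crossprod(Z, sol))
  structure(list(u_hat = stats::setNames(u, geno$map$marker),
                 weights = weights, iteration = 1L,
                 effect_kind = effect_kind, map = geno$map, p = geno$p),
            class = "snp_effect_set")
}

#' @export
print.snp_effect_set <- function(x, ...) {
  cat("snp_effect_set (", x$effect_kind, "): ", length(x$u_hat),
      " markers, iteration ", x$iteration, "\n", sep = "")
  invisible(x)
}

#' Update SNP weights from estimated effects
#'
#' Raw weights `d_i = u_i^2 2 p_i (1 - p_i)` (the marker's contribution to
#' additive variance), rescaled by a single constant so that the total
#' genetic variance carried by the weights, `sum d_i 2 p_i (1 - p_i)`, is
#' unchanged from the previous iteration.
#'
#' @param u_hat per-marker effect estimates.
#' @param p per-marker allele frequencies.
#' @param prev_weights the weights of the previous iteration (default all 1).
#' @return numeric weight vector satisfying the conservation constraint.
#' @export
update_weights <- function(u_hat, p, prev_weights = NULL) {
  stopifnot(length(u_hat) == length(p))
  if (is.null(prev_weights)) prev_weights <- rep(1, length(p))
  het <- 2 * p * (1 - p)
  raw <- u_hat^2 * het
  mass <- sum(raw * het)
  if (mass <= 0) stop("all raw SNP weights are zero; degenerate effects")
  unname(raw * sum(prev_weights * het) / mass)
}

#' Iterative single-step GWAS
#'
#' Runs the SNP-effect / weight iteration for one genetic effect vector
#' (direct or social): starting from `D = I`, breeding values are solved from
#' the mixed-model equations with the current single-step kernel, the
#' genotyped animals' solutions are back-solved into SNP effects, weights are
#' recomputed and normalised, `G` (and hence `H^-1`) is rebuilt, and the
#' cycle repeats.  Two iterations are the conventional choice.  Variance
#' components stay fixed (posterior means from a previous [gibbs_fit()], or
#' known values).
#'
#' @param data a [grouped_phenotypes()] object.
#' @param kernel a [relationship_set()] with genotypes.
#' @param components a [variance_components()] object.
#' @param effect_kind `"DGE"` (direct) or `"SGE"` (social) solution vector.
#' @param n_iterations number of back-solve iterations (>= 1).
#' @return final `"snp_effect_set"`, with attribute `"a_g"` holding the last
#'   breeding-value solutions of the genotyped animals.
#' @export
run_ssgwas <- function(data, kernel, components,
                       effect_kind = c("DGE", "SGE"), n_iterations = 2L) {
  effect_kind <- match.arg(effect_kind)
  stopifnot(inherits(kernel, "relationship_set"))
  if (is.null(kernel$genotypes))
    stop("kernel carries no genotypes; ssGWAS needs genotyped animals")
  n_iterations <- as.integer(n_iterations)
  stopifnot(n_iterations >= 1L)
  geno <- kernel$genotypes
  w <- rep(1, ncol(geno$dosage))
  kern <- if (all(kernel$weights == w)) kernel else update_G(kernel, w)
  eff <- NULL
  for (it in seq_len(n_iterations)) {
    if (it > 1L) {
      w <- update_weights(eff$u_hat, geno$p, prev_weights = eff$weights)
      kern <- update_G(kern, w)
    }
    sol <- solve_mme(data, kern, components)
    a_all <- if (effect_kind == "DGE") sol$a_D else sol$a_S
    a_g <- a_all[kern$genotyped_index]
    eff <- backsolve_snp_effects(geno, a_g, weights = w,
                                 effect_kind = effect_kind,
                                 blend_eps = kern$blend_eps,
                                 A22 = kern$A22, q = kern$q)
    eff$iteration <- it
    attr(eff, "a_g") <- a_g
  }
  eff
}
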