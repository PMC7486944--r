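#' Variance components of the social-effects model
#'
#' Container for the eight variances and two covariances of the model, all in
#' squared trait units ((g/day)^2 for daily gain): the 2x2 genetic block
#' (direct variance, social variance, their covariance), pen, group, maternal
#' permanent environment, the 2x2 birth-litter / early-life block, and the
#' residual.  Both 2x2 blocks must be positive definite and all variances
#' strictly positive.
#'
#' @param var_aD,var_aS,cov_aDaS direct/social genetic (co)variances.
#' @param var_c,var_g,var_pe pen, group and dam permanent-environment
#'   variances.
#' @param var_l,var_k,cov_lk birth-litter / early-life (co)variances.
#' @param var_e residual variance.
#' @return object of class `"variance_components"` (a named list).
#' @export
variance_components <- function(var_aD, var_aS, cov_aDaS, var_c, var_g,
                                var_pe, var_l, var_k, cov_lk, var_e) {
  vc <- list(var_aD = var_aD, var_aS = var_aS, cov_aDaS = cov_aDaS,
             var_c = var_c, var_g = var_g, var_pe = var_pe,
             var_l = var_l, var_k = var_k, cov_lk = cov_lk, var_e = var_e)
  vars <- unlist(vc[c("var_aD", "var_aS", "var_c", "var_g", "var_pe",
                      "var_l", "var_k", "var_e")])
  if (any(!is.finite(unlist(vc))) || any(vars <= 0))
    stop("all variances must be finite and > 0")
  if (var_aD * var_aS - cov_aDaS^2 <= 0)
    stop("genetic 2x2 block is not positive definite")
  if (var_l * var_k - cov_lk^2 <= 0)
    stop("litter/early-life 2x2 block is not positive definite")
  structure(vc, class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  v <- unlist(unclass(x))
  print(round(v, 4))
  invisible(x)
}

#' Genetic parameters of the social-effects model
#'
#' Derives, for mean group size `n`:
#' total heritable variance
#' `var_TBV = var_aD + 2 (n - 1) cov_aDaS + (n - 1)^2 var_aS`,
#' phenotypic variance
#' `var_P = var_aD + (n - 1) var_aS + var_c + var_g + var_pe + var_l +
#' (n - 1) var_k + var_e`,
#' classical heritability `h2 = var_aD / var_P`, total heritability
#' `T2 = var_TBV / var_P`, and the direct-social and litter/early-life
#' correlations.
#'
#' @param components a [variance_components()] object.
#' @param mean_group_size scalar mean group size `n`.
#' @return list with `var_TBV`, `var_P`, `h2`, `T2`, `r_aDS`, `r_lk`.
#' @examples
#' vc <- variance_components(2235, 16, 43, 43, 227, 48, 218, 17, 36, 3299)
#' genetic_parameters(vc, 6.8)
#' @export
genetic_parameters <- function(components, mean_group_size) {
  stopifnot(inherits(components, "variance_components"),
            is.finite(mean_group_size), mean_group_size >= 2)
  with(components, {
    nm1 <- mean_group_size - 1
    var_TBV <- var_aD + 2 * nm1 * cov_aDaS + nm1^2 * var_aS
    var_P <- var_aD + nm1 * var_aS + var_c + var_g + var_pe + var_l +
      nm1 * var_k + var_e
    list(var_TBV = var_TBV, var_P = var_P,
         h2 = var_aD / var_P, T2 = var_TBV / var_P,
         r_aDS = cov_aDaS / sqrt(var_aD * var_aS),
         r_lk = cov_lk / sqrt(var_l * var_k))
  })
}

#' Total breeding values
#'
#' `TBV_i = a_D[i] + (n - 1) a_S[i]`: an animal's total heritable impact on
#' the population mean, combining its direct effect on its own record and its
#' social effect on each of its `n - 1` group mates.
#'
#' @param a_D,a_S equal-length vectors of direct and social genetic effects.
#' @param mean_group_size scalar mean group size `n`.
#' @return numeric vector of total breeding values.
#' @export
total_breeding_values <- function(a_D, a_S, mean_group_size) {
  if (length(a_D) != length(a_S))
    stop("a_D and a_S must have equal length")
  a_D + (mean_group_size - 1) * a_S
}
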