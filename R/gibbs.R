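#' Gibbs chain configuration
#'
#' Chain settings and prior hyperparameters for [gibbs_fit()].  The default
#' chain (55,000 rounds, 5,000 burn-in, thinning 5) is a 10-fold reduction of
#' the full-scale analysis settings (550,000 / 50,000 / 50, which retain
#' 10,000 samples); pass those explicitly for a full-scale run.  Priors
#' default to vague choices: inverse-Wishart with minimal degrees of freedom
#' (`nu = 3`, small diagonal scale) for the two 2x2 covariance blocks and
#' flat scaled-inverse-chi-square (`nu = -2`, scale 0) for scalar variances
#' and the residual.
#'
#' @param rounds,burn_in,thin chain length, discarded burn-in, thinning
#'   interval; `(rounds - burn_in)` must be a positive multiple of `thin`.
#' @param seed integer seed governing the whole chain.
#' @param nu_g,S_g inverse-Wishart prior for the genetic 2x2 block; `S_g =
#'   NULL` (default) uses `diag(0.01 * var(y))`, set at fit time.  A scale
#'   on the data scale (rather than numerically zero) is needed to keep the
#'   singular boundary of the covariance block from becoming an absorbing
#'   state of the sampler; it shifts posterior means by only `scale /
#'   n_levels`.
#' @param nu_lk,S_lk inverse-Wishart prior for the litter/early-life block
#'   (same default rule).
#' @param nu_scalar,s_scalar scaled-inverse-chi-square prior for scalar
#'   variances.
#' @param nu_e,s_e scaled-inverse-chi-square prior for the residual.
#' @return object of class `"gibbs_config"`; element `n_retained` gives the
#'   number of retained posterior samples.
#' @export
gibbs_config <- function(rounds = 55000L, burn_in = 5000L, thin = 5L,
                         seed = 20191709L,
                         nu_g = 3, S_g = NULL,
                         nu_lk = 3, S_lk = NULL,
                         nu_scalar = -2, s_scalar = 0,
                         nu_e = -2, s_e = 0) {
  rounds <- as.integer(rounds)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= rounds) stop("burn_in must be smaller than rounds")
  if (burn_in < 0L || thin < 1L) stop("invalid burn_in or thin")
  if ((rounds - burn_in) %% thin != 0L)
    stop("(rounds - burn_in) must be divisible by thin")
  structure(list(rounds = rounds, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed),
                 n_retained = (rounds - burn_in) %/% thin,
                 prior = list(nu_g = nu_g, S_g = S_g, nu_lk = nu_lk,
                              S_lk = S_lk, nu_scalar = nu_scalar,
                              s_scalar = s_scalar, nu_e = nu_e, s_e = s_e)),
            class = "gibbs_config")
}

#' @export
print.gibbs_config <- function(x, ...) {
  cat("gibbs_config:", x$rounds, "rounds, burn-in", x$burn_in, ", thin",
      x$thin, "->", x$n_retained, "retained samples; seed", x$seed, "\n")
  invisible(x)
}

.component_names <- c("var_aD", "var_aS", "cov_aDaS", "var_c", "var_g",
                      "var_pe", "var_l", "var_k", "cov_lk", "var_e")

.default_start <- function(y) {
  vy <- stats::var(y)
  list(var_aD = 0.3 * vy, var_aS = 0.01 * vy, cov_aDaS = 0,
       var_c = 0.05 * vy, var_g = 0.05 * vy, var_pe = 0.05 * vy,
       var_l = 0.05 * vy, var_k = 0.01 * vy, cov_lk = 0, var_e = 0.5 * vy)
}

#' Estimate variance components by Gibbs sampling
#'
#' Fits the social-effects animal model by single-site Gibbs sampling:
#' location effects are drawn from their Gaussian full conditionals given the
#' current (co)variance components, and the components from their conjugate
#' inverse-Wishart (2x2 blocks) and scaled-inverse-chi-square (scalar
#' variances, residual) full conditionals given the current effects.  The
#' genetic kernel is the single-step `H^-1` of the supplied
#' [relationship_set()] (equal to `A^-1` without genotypes).
#'
#' @param data a [grouped_phenotypes()] object.
#' @param kernel a [relationship_set()].
#' @param config a [gibbs_config()].
#' @param random_terms random terms besides the direct genetic effect; the
#'   default fits the full model.  E.g. `character(0)` reduces the model to
#'   animal + residual.
#' @param update_variances if `FALSE`, components stay fixed at `start` and
#'   only location effects are sampled (useful for checking against the
#'   mixed-model-equation solutions).
#' @param start optional named list of starting components (all ten names of
#'   the full parameterisation); defaults are derived from `var(y)`.
#' @return object of class `"posterior_chain"`: `samples` (one row per
#'   retained draw, one column per component; columns of absent terms are
#'   dropped), `solutions` (posterior-mean location effects, as in
#'   [solve_mme()]), `config`, `random_terms`, `mean_group_size`.
#' @export
gibbs_fit <- function(data, kernel, config = gibbs_config(),
                      random_terms = c("sge", "pen", "group", "pe", "litter"),
                      update_variances = TRUE, start = NULL) {
  stopifnot(inherits(config, "gibbs_config"))
  str <- .mme_structures(data, kernel, random_terms)
  if (is.null(start)) start <- .default_start(str$des$y)
  miss <- setdiff(.component_names, names(start))
  if (length(miss)) stop("start misses: ", paste(miss, collapse = ", "))
  prior <- config$prior
  if (is.null(prior$S_g)) prior$S_g <- diag(0.01 * stats::var(str$des$y), 2)
  if (is.null(prior$S_lk)) prior$S_lk <- diag(0.01 * stats::var(str$des$y), 2)

  set.seed(config$seed)
  res <- gibbs_sampler_cpp(str$WtW, str$Wty, str$yty, str$n_records,
                           str$Kinv, as.integer(unname(str$off)),
                           as.integer(unname(str$len)),
                           prior, start,
                           config$rounds, config$burn_in, config$thin,
                           update_variances)
  samples <- as.data.frame(res$samples)
  names(samples) <- .component_names
  samples <- samples[, colSums(is.na(samples)) < nrow(samples), drop = FALSE]
  if (any(!is.finite(as.matrix(samples))))
    stop("divergent chain: non-finite draws recorded")

  sol <- .split_solutions(as.numeric(res$theta_mean), str)
  structure(list(samples = samples, solutions = sol, config = config,
                 random_terms = random_terms,
                 mean_group_size = str$des$mean_group_size,
                 n_records = str$n_records),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat("posterior_chain:", nrow(x$samples), "retained draws of",
      ncol(x$samples), "components\n")
  invisible(x)
}

#' Post-Gibbs summary
#'
#' Posterior means and standard deviations of the variance components and,
#' for a full-model chain, of the derived genetic parameters.  Parameters
#' (total heritable variance, phenotypic variance, h2, T2, correlations) are
#' computed per retained draw and then summarised, so the reported ratios are
#' posterior means of ratios with their own posterior SDs.
#'
#' @param chain a [posterior_chain()] from [gibbs_fit()], or a data frame of
#'   per-draw components (all ten columns) for externally stored chains.
#' @param mean_group_size mean group size; taken from the chain when
#'   available.
#' @return data frame with columns `parameter`, `mean`, `sd`.
#' @export
summarize_chain <- function(chain, mean_group_size = NULL) {
  if (inherits(chain, "posterior_chain")) {
    if (is.null(mean_group_size)) mean_group_size <- chain$mean_group_size
    draws <- chain$samples
  } else {
    draws <- as.data.frame(chain)
  }
  if (nrow(draws) == 0L) stop("no retained draws")
  out <- data.frame(parameter = names(draws),
                    mean = vapply(draws, mean, numeric(1)),
                    sd = vapply(draws, stats::sd, numeric(1)))
  if (all(.component_names %in% names(draws)) && !is.null(mean_group_size)) {
    nm1 <- mean_group_size - 1
    var_TBV <- draws$var_aD + 2 * nm1 * draws$cov_aDaS + nm1^2 * draws$var_aS
    var_P <- draws$var_aD + nm1 * draws$var_aS + draws$var_c + draws$var_g +
      draws$var_pe + draws$var_l + nm1 * draws$var_k + draws$var_e
    derived <- data.frame(var_TBV = var_TBV, var_P = var_P,
                          h2 = draws$var_aD / var_P, T2 = var_TBV / var_P,
                          r_aDS = draws$cov_aDaS /
                            sqrt(draws$var_aD * draws$var_aS),
                          r_lk = draws$cov_lk /
                            sqrt(draws$var_l * draws$var_k))
    out <- rbind(out,
                 data.frame(parameter = names(derived),
                            mean = vapply(derived, mean, numeric(1)),
                            sd = vapply(derived, stats::sd, numeric(1))))
  }
  rownames(out) <- NULL
  out
}

#' Posterior-mean variance components of a full-model chain
#'
#' @param chain a [posterior_chain()] from a full-model [gibbs_fit()].
#' @return a [variance_components()] object.
#' @export
posterior_components <- function(chain) {
  stopifnot(inherits(chain, "posterior_chain"))
  if (!all(.component_names %in% names(chain$samples)))
    stop("chain does not cover the full model")
  do.call(variance_components,
          as.list(colMeans(chain$samples)[.component_names]))
}

#' Central posterior credible intervals
#'
#' @param chain a [posterior_chain()].
#' @param level credible level (default 0.95).
#' @return data frame with `parameter`, `lower`, `upper`.
#' @export
credible_intervals <- function(chain, level = 0.95) {
  stopifnot(inherits(chain, "posterior_chain"))
  a <- (1 - level) / 2
  qs <- t(vapply(chain$samples, stats::quantile, numeric(2),
                 probs = c(a, 1 - a)))
  data.frame(parameter = names(chain$samples),
             lower = qs[, 1], upper = qs[, 2], row.names = NULL)
}
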