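## Independent oracle for gibbs_fit: a dense, jointly-blocked Gibbs sampler
## written against the model's closed-form full conditionals (all location
## effects drawn in one multivariate block via a dense Cholesky; variance
## blocks from their conjugate forms).  Shares no code with the single-site
## C++ sampler.
blocked_gibbs_oracle <- function(data, kernel, n_iter, burn_in,
                                 S0 = NULL, nu0 = 3,
                                 nu_sc = -2, s_sc = 0) {
  str <- sgewas:::.mme_structures(data, kernel)
  WtW <- as.matrix(str$WtW)
  Wty <- str$Wty
  yty <- str$yty
  Kinv <- as.matrix(str$Kinv)
  off <- str$off
  len <- str$len
  idx <- function(s) (off[s] + 1):(off[s] + len[s])
  y <- str$des$y
  if (is.null(S0)) S0 <- diag(0.01 * stats::var(y), 2)

  riwish2 <- function(df, S) {
    L <- t(chol(solve(S)))
    A <- matrix(c(sqrt(stats::rchisq(1, df)), stats::rnorm(1), 0,
                  sqrt(stats::rchisq(1, df - 1))), 2, 2)
    Tt <- L %*% A
    solve(tcrossprod(Tt))
  }

  vy <- stats::var(y)
  Cg <- diag(c(0.3 * vy, 0.01 * vy))
  B <- diag(c(0.05 * vy, 0.01 * vy))
  vc <- vg <- vpe <- 0.05 * vy
  ve <- 0.5 * vy
  p_tot <- length(Wty)
  nG <- len[["aD"]]
  nL <- len[["l"]]
  keep <- matrix(NA_real_, n_iter - burn_in, 10)
  for (it in seq_len(n_iter)) {
    P <- matrix(0, p_tot, p_tot)
    Ci <- solve(Cg)
    P[idx("aD"), idx("aD")] <- Ci[1, 1] * Kinv
    P[idx("aD"), idx("aS")] <- Ci[1, 2] * Kinv
    P[idx("aS"), idx("aD")] <- Ci[1, 2] * Kinv
    P[idx("aS"), idx("aS")] <- Ci[2, 2] * Kinv
    Bi <- solve(B)
    P[idx("l"), idx("l")] <- diag(Bi[1, 1], nL)
    P[idx("l"), idx("k")] <- diag(Bi[1, 2], nL)
    P[idx("k"), idx("l")] <- diag(Bi[1, 2], nL)
    P[idx("k"), idx("k")] <- diag(Bi[2, 2], nL)
    P[idx("c"), idx("c")] <- diag(1 / vc, len[["c"]])
    P[idx("g"), idx("g")] <- diag(1 / vg, len[["g"]])
    P[idx("pe"), idx("pe")] <- diag(1 / vpe, len[["pe"]])
    C <- WtW + ve * P
    U <- chol(C)
    mu <- backsolve(U, backsolve(U, Wty, transpose = TRUE))
    th <- mu + sqrt(ve) * backsolve(U, stats::rnorm(p_tot))
    aD <- th[idx("aD")]
    aS <- th[idx("aS")]
    Sg <- rbind(c(t(aD) %*% Kinv %*% aD, t(aD) %*% Kinv %*% aS),
                c(t(aD) %*% Kinv %*% aS, t(aS) %*% Kinv %*% aS))
    Cg <- riwish2(nu0 + nG, S0 + Sg)
    l <- th[idx("l")]
    k <- th[idx("k")]
    Slk <- rbind(c(sum(l * l), sum(l * k)), c(sum(l * k), sum(k * k)))
    B <- riwish2(nu0 + nL, S0 + Slk)
    vc <- (sum(th[idx("c")]^2) + nu_sc * s_sc) /
      stats::rchisq(1, len[["c"]] + nu_sc)
    vg <- (sum(th[idx("g")]^2) + nu_sc * s_sc) /
      stats::rchisq(1, len[["g"]] + nu_sc)
    vpe <- (sum(th[idx("pe")]^2) + nu_sc * s_sc) /
      stats::rchisq(1, len[["pe"]] + nu_sc)
    ee <- yty - 2 * sum(Wty * th) + t(th) %*% WtW %*% th
    ve <- as.numeric(ee) / stats::rchisq(1, str$n_records - 2)
    if (it > burn_in)
      keep[it - burn_in, ] <- c(Cg[1, 1], Cg[2, 2], Cg[1, 2], vc, vg, vpe,
                                B[1, 1], B[2, 2], B[1, 2], ve)
  }
  colnames(keep) <- c("var_aD", "var_aS", "cov_aDaS", "var_c", "var_g",
                      "var_pe", "var_l", "var_k", "cov_lk", "var_e")
  as.data.frame(keep)
}
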