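#' Decompose additive genetic variance into map windows
#'
#' Tiles each chromosome with non-overlapping windows of `window_bp` base
#' pairs anchored at position 0 (half-open `[start, start + window_bp)`, with
#' 1-based inclusive labels) and computes, for every window, the variance
#' across genotyped animals of its genomic value `sum_j Z_j u_j`, expressed
#' as a percentage of the additive genetic variance `sigma2_a`.  With
#' `sigma2_a = NULL` the denominator is the empirical variance of the total
#' genomic value (self-normalised mode: percentages sum to 100 up to
#' between-window covariances).
#'
#' @param snp_effects a `"snp_effect_set"` from [backsolve_snp_effects()] or
#'   [run_ssgwas()].
#' @param geno the [genotype_matrix()] the effects were solved on.
#' @param sigma2_a additive genetic variance used as denominator (typically
#'   the model's posterior-mean `var_aD` or `var_aS`), or `NULL` for
#'   self-normalisation.
#' @param window_bp window width in base pairs (default 1 Mb).
#' @param keep_values store the per-window genomic values as attribute
#'   `"genomic_values"` (for variance-decomposition audits).
#' @return object of class `"snp_window_result"`: a data frame with one row
#'   per window (`chrom`, `start_bp`, `end_bp`, `label`, `n_snps`,
#'   `pct_var`), windows with no markers reported with `pct_var = 0`.
#' @export
window_variance <- function(snp_effects, geno, sigma2_a = NULL,
                            window_bp = 1e6, keep_values = FALSE) {
  stopifnot(inherits(snp_effects, "snp_effect_set"),
            inherits(geno, "genotype_matrix"))
  map <- geno$map
  if (nrow(map) == 0L) stop("empty genome: no markers in map")
  if (!identical(map$marker, snp_effects$map$marker))
    stop("marker map of effects and genotypes disagree")
  if (!is.null(sigma2_a) && sigma2_a <= 0) stop("sigma2_a must be > 0")

  Z <- center_genotypes(geno)
  u <- snp_effects$u_hat
  widx <- (map$pos - 1) %/% window_bp

  ## full tiling per chromosome, including empty windows
  chroms <- unique(map$chrom)
  tiles <- do.call(rbind, lapply(chroms, function(ch) {
    wmax <- max(widx[map$chrom == ch])
    data.frame(chrom = ch, win = 0:wmax)
  }))
  key <- paste(tiles$chrom, tiles$win)
  marker_key <- paste(map$chrom, widx)

  gv <- matrix(0, nrow(Z), nrow(tiles))
  n_snps <- integer(nrow(tiles))
  for (w in seq_len(nrow(tiles))) {
    idx <- which(marker_key == key[w])
    n_snps[w] <- length(idx)
    if (length(idx))
      gv[, w] <- as.numeric(Z[, idx, drop = FALSE] %*% u[idx])
  }
  total <- rowSums(gv)
  denom <- if (is.null(sigma2_a)) stats::var(total) else sigma2_a
  pct <- apply(gv, 2L, stats::var) / denom * 100

  out <- data.frame(chrom = tiles$chrom,
                    start_bp = tiles$win * window_bp + 1,
                    end_bp = (tiles$win + 1) * window_bp,
                    label = sprintf("%s:%g-%g Mb", tiles$chrom,
                                    tiles$win * window_bp / 1e6,
                                    (tiles$win + 1) * window_bp / 1e6),
                    n_snps = n_snps, pct_var = pct)
  attr(out, "effect_kind") <- snp_effects$effect_kind
  attr(out, "sigma2_a") <- denom
  attr(out, "self_normalized") <- is.null(sigma2_a)
  if (keep_values) attr(out, "genomic_values") <- gv
  class(out) <- c("snp_window_result", "data.frame")
  out
}

#' Flag QTL windows
#'
#' Flags the windows whose share of additive genetic variance meets the
#' threshold (inclusive: a window at exactly the threshold is flagged),
#' sorted by decreasing percentage.
#'
#' @param result a `"snp_window_result"` from [window_variance()].
#' @param threshold_pct calling threshold in percent (default 0.5).
#' @return the flagged rows of `result`, ordered by `pct_var` descending.
#' @export
call_qtl <- function(result, threshold_pct = 0.5) {
  stopifnot(inherits(result, "snp_window_result"))
  hits <- result[result$pct_var >= threshold_pct, , drop = FALSE]
  hits <- hits[order(-hits$pct_var), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- "data.frame"
  hits
}

#' Manhattan-style window plot
#'
#' Plots each window's share of additive genetic variance against its genomic
#' position (window midpoints laid out chromosome by chromosome), with a
#' horizontal line at the QTL-calling threshold.
#'
#' @param result a `"snp_window_result"`.
#' @param threshold_pct threshold line (default 0.5; `NA` suppresses it).
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, the plotted data frame with a cumulative `x` column.
#' @export
plot_windows <- function(result, threshold_pct = 0.5, ...) {
  stopifnot(inherits(result, "snp_window_result"))
  df <- as.data.frame(result)
  chroms <- unique(df$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(df$end_bp[df$chrom == ch]), numeric(1))))
  names(offs) <- c(chroms, "end")
  df$x <- (df$start_bp + df$end_bp) / 2 + offs[as.character(df$chrom)]
  cols <- rep_len(c("grey25", "steelblue"), length(chroms))
  graphics::plot(df$x, df$pct_var, pch = 16, cex = 0.7,
                 col = cols[match(df$chrom, chroms)],
                 xlab = "genome position", xaxt = "n",
                 ylab = "% of additive genetic variance", ...)
  mids <- offs[seq_along(chroms)] + diff(offs) / 2
  graphics::axis(1, at = mids, labels = chroms)
  if (!is.na(threshold_pct))
    graphics::abline(h = threshold_pct, lty = 2, col = "firebrick")
  invisible(df)
}
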