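#' Genotype quality-control thresholds
#'
#' @param maf_min minimum minor allele frequency (0 disables).
#' @param marker_call_rate_min minimum per-marker call rate.
#' @param animal_call_rate_min minimum per-animal call rate.
#' @param hwe_p_min minimum Hardy-Weinberg exact-test p-value (0 disables).
#' @param drop_sex_chromosomes drop markers on sex chromosomes.
#' @param drop_monomorphic drop markers with no variation.
#' @param sex_chroms chromosome labels treated as sex chromosomes.
#' @return object of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(maf_min = 0.05, marker_call_rate_min = 0.90,
                          animal_call_rate_min = 0.90, hwe_p_min = 1e-6,
                          drop_sex_chromosomes = TRUE,
                          drop_monomorphic = TRUE,
                          sex_chroms = c("X", "Y", "XY", "MT")) {
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            marker_call_rate_min >= 0, marker_call_rate_min <= 1,
            animal_call_rate_min >= 0, animal_call_rate_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1)
  structure(list(maf_min = maf_min,
                 marker_call_rate_min = marker_call_rate_min,
                 animal_call_rate_min = animal_call_rate_min,
                 hwe_p_min = hwe_p_min,
                 drop_sex_chromosomes = drop_sex_chromosomes,
                 drop_monomorphic = drop_monomorphic,
                 sex_chroms = as.character(sex_chroms)),
            class = "qc_thresholds")
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test on the genotype counts of a biallelic marker: the
#' p-value is the total probability, under the conditional distribution of
#' the heterozygote count given the allele count, of all outcomes no more
#' probable than the observed one.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return exact p-value.
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n == 0L) return(1)
  nA <- 2L * n_hom1 + n_het
  hs <- seq.int(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
  logp <- vapply(hs, function(h) {
    a <- (nA - h) / 2
    b <- (2 * n - nA - h) / 2
    h * log(2) + lfactorial(n) - lfactorial(a) - lfactorial(h) -
      lfactorial(b)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hs)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

#' Genotype quality control
#'
#' Applies, in this fixed order: animal call rate, marker call rate,
#' monomorphic-marker removal, minor-allele-frequency filter, Hardy-Weinberg
#' exact-test filter, sex-chromosome removal.  Remaining missing dosages are
#' then mean-imputed per marker.  The order is part of the contract (the
#' filters do not commute).
#'
#' @param geno a [genotype_matrix()] (missing dosages allowed).
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `genotypes` (filtered, imputed [genotype_matrix()]) and
#'   `report` (removal counts per rule and final dimensions).
#' @export
qc_genotypes <- function(geno, thresholds = qc_thresholds()) {
  stopifnot(inherits(geno, "genotype_matrix"),
            inherits(thresholds, "qc_thresholds"))
  dos <- geno$dosage
  map <- geno$map
  report <- list()

  cr_animal <- rowMeans(!is.na(dos))
  keep_a <- cr_animal >= thresholds$animal_call_rate_min
  report$animals_low_call_rate <- sum(!keep_a)
  dos <- dos[keep_a, , drop = FALSE]

  drop_marker <- function(bad, rule) {
    report[[rule]] <<- sum(bad)
    dos <<- dos[, !bad, drop = FALSE]
    map <<- map[!bad, , drop = FALSE]
  }

  cr_marker <- colMeans(!is.na(dos))
  drop_marker(cr_marker < thresholds$marker_call_rate_min,
              "markers_low_call_rate")

  p <- colMeans(dos, na.rm = TRUE) / 2
  if (thresholds$drop_monomorphic) {
    mono <- vapply(seq_len(ncol(dos)), function(j) {
      v <- dos[, j]
      length(unique(v[!is.na(v)])) <= 1L
    }, logical(1))
    drop_marker(mono, "markers_monomorphic")
    p <- colMeans(dos, na.rm = TRUE) / 2
  } else report$markers_monomorphic <- 0L

  drop_marker(pmin(p, 1 - p) < thresholds$maf_min, "markers_low_maf")

  if (thresholds$hwe_p_min > 0 && ncol(dos) > 0L) {
    hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
      v <- dos[, j]
      v <- v[!is.na(v)]
      hwe_exact_test(sum(v == 0), sum(v == 1), sum(v == 2))
    }, numeric(1))
    drop_marker(hwe_p < thresholds$hwe_p_min, "markers_hwe")
  } else report$markers_hwe <- 0L

  if (thresholds$drop_sex_chromosomes) {
    drop_marker(as.character(map$chrom) %in% thresholds$sex_chroms,
                "markers_sex_chromosome")
  } else report$markers_sex_chromosome <- 0L

  if (ncol(dos) == 0L) stop("quality control removed every marker")

  ## mean-impute remaining missing dosages per marker
  nmiss <- sum(is.na(dos))
  if (nmiss > 0L) {
    for (j in which(colSums(is.na(dos)) > 0L)) {
      v <- dos[, j]
      dos[is.na(v), j] <- mean(v, na.rm = TRUE)
    }
  }
  report$dosages_imputed <- nmiss
  report$n_animals <- nrow(dos)
  report$n_markers <- ncol(dos)
  list(genotypes = genotype_matrix(dos, map), report = report)
}
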