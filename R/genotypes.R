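#' SNP genotype container
#'
#' Wraps an animals-by-markers allele dosage matrix (counts of the tracked
#' allele, in 0..2, `NA` allowed before quality control) together with a
#' marker map.  Observed allele frequencies `p` are computed from the
#' genotyped sample (the convention for VanRaden method 1 when no
#' base-generation frequencies are available).
#'
#' @param dosage numeric matrix, animals x markers; rownames are animal ids.
#' @param map data frame with columns `marker`, `chrom`, `pos` (bp, 1-based);
#'   sorted by (chrom, pos) on construction, reordering dosage columns to
#'   match.
#' @return object of class `"genotype_matrix"` with elements `dosage`, `map`,
#'   `p` (per-marker frequency of the counted allele).
#' @export
genotype_matrix <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) stop("dosage must have animal ids as rownames")
  stopifnot(is.data.frame(map),
            all(c("marker", "chrom", "pos") %in% names(map)))
  if (nrow(map) != ncol(dosage))
    stop("map rows (", nrow(map), ") != dosage columns (", ncol(dosage), ")")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 2) stop("dosages must lie in [0, 2]")
  map$marker <- as.character(map$marker)
  if (is.null(colnames(dosage))) colnames(dosage) <- map$marker
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  dosage <- dosage[, ord, drop = FALSE]
  p <- colMeans(dosage, na.rm = TRUE) / 2
  structure(list(dosage = dosage, map = map, p = p),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "animals x", ncol(x$dosage),
      "markers on", length(unique(x$map$chrom)), "chromosome(s);",
      sum(is.na(x$dosage)), "missing dosages\n")
  invisible(x)
}

#' Subset a genotype matrix by animal
#'
#' @param geno a [genotype_matrix()].
#' @param ids animal ids to keep (order preserved).
#' @return a new `genotype_matrix`; allele frequencies are recomputed from
#'   the retained animals.
#' @export
subset_genotypes <- function(geno, ids) {
  stopifnot(inherits(geno, "genotype_matrix"))
  miss <- setdiff(ids, rownames(geno$dosage))
  if (length(miss)) stop("ids not genotyped: ", paste(miss, collapse = ", "))
  genotype_matrix(geno$dosage[ids, , drop = FALSE], geno$map)
}

## Centered gene-content matrix Z = dosage - 2p (no missing allowed).
center_genotypes <- function(geno, p = geno$p) {
  if (anyNA(geno$dosage))
    stop("missing dosages; run qc_genotypes() (with imputation) first")
  sweep(geno$dosage, 2L, 2 * p)
}
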