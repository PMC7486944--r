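#' Incidence matrices for the social-effects animal model
#'
#' Builds the sparse design matrices of the model
#' `y = Xb + Z_D a_D + Z_S a_S + Wc + Vg + T pe + Ul + Qk + e`:
#' fixed effects `X` (intercept, birth year-month, sex, group-size class,
#' age covariate), direct genetic incidence `Z_D` (one 1 per row), social
#' genetic incidence `Z_S` (each record's row holds the record's dilution
#' factor at the columns of its group mates, zero on the animal itself),
#' pen `W`, group `V`, dam permanent environment `T`, birth litter `U` and
#' early-life environment `Q` (dilution-weighted incidence on the birth
#' litters of the group mates; weights on a shared litter accumulate).
#'
#' The genetic columns span the whole pedigree, so non-phenotyped ancestors
#' carry effects; litter columns are shared between `U` and `Q`.
#'
#' @param data a [grouped_phenotypes()] object.
#' @param ped the [pedigree()] the genetic effects refer to.
#' @return list of sparse matrices `X`, `Z_D`, `Z_S`, `W`, `V`, `T`, `U`,
#'   `Q`, plus `y`, the per-record dilution `d`, and the level labels of each
#'   term.
#' @export
build_design <- function(data, ped) {
  stopifnot(inherits(data, "grouped_phenotypes"), inherits(ped, "pedigree"))
  rec <- data$records
  n <- nrow(rec)
  nbar <- data$mean_group_size

  ai <- match(rec$animal, ped$id)
  if (anyNA(ai))
    stop("recorded animal(s) absent from pedigree: ",
         paste(rec$animal[is.na(ai)], collapse = ", "))

  sizes <- lengths(data$group_membership)[rec$group]
  d <- dilution(sizes, nbar)

  ## fixed effects: drop factors that collapse to one level
  fx <- rec
  fx$yearmonth <- factor(fx$yearmonth)
  fx$sex <- factor(fx$sex)
  terms <- c("yearmonth", "sex", "gsclass")
  terms <- terms[vapply(terms, function(t) nlevels(fx[[t]]) > 1L, logical(1))]
  fml <- stats::reformulate(c(terms, "age"))
  X <- Matrix::sparse.model.matrix(fml, data = fx)

  Z_D <- Matrix::sparseMatrix(i = seq_len(n), j = ai, x = 1,
                              dims = c(n, length(ped$id)),
                              dimnames = list(NULL, ped$id))

  ## social incidence and early-life (mates' litters), dilution-weighted
  zi <- vector("list", n); zj <- vector("list", n)
  qi <- vector("list", n); qj <- vector("list", n); qx <- vector("list", n)
  litters <- sort(unique(rec$litter))
  lit_of <- stats::setNames(match(rec$litter, litters), rec$animal)
  for (r in seq_len(n)) {
    mates <- setdiff(data$group_membership[[rec$group[r]]], rec$animal[r])
    zi[[r]] <- rep.int(r, length(mates))
    zj[[r]] <- match(mates, ped$id)
    qi[[r]] <- rep.int(r, length(mates))
    qj[[r]] <- lit_of[mates]
    qx[[r]] <- rep.int(d[r], length(mates))
  }
  Z_S <- Matrix::sparseMatrix(i = unlist(zi), j = unlist(zj),
                              x = d[unlist(zi)],
                              dims = c(n, length(ped$id)),
                              dimnames = list(NULL, ped$id))
  Q <- Matrix::sparseMatrix(i = unlist(qi), j = unlist(qj), x = unlist(qx),
                            dims = c(n, length(litters)),
                            dimnames = list(NULL, litters))

  ind <- function(labels) {
    lev <- sort(unique(labels))
    Matrix::sparseMatrix(i = seq_len(n), j = match(labels, lev), x = 1,
                         dims = c(n, length(lev)),
                         dimnames = list(NULL, lev))
  }
  W <- ind(rec$pen)
  V <- ind(rec$group)
  Tm <- ind(rec$dam)
  U <- Matrix::sparseMatrix(i = seq_len(n), j = lit_of[rec$animal], x = 1,
                            dims = c(n, length(litters)),
                            dimnames = list(NULL, litters))

  list(X = X, Z_D = Z_D, Z_S = Z_S, W = W, V = V, T = Tm, U = U, Q = Q,
       y = rec$y, d = d,
       levels = list(fixed = colnames(X), animal = ped$id,
                     pen = colnames(W), group = colnames(V),
                     pe = colnames(Tm), litter = litters),
       mean_group_size = nbar)
}
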