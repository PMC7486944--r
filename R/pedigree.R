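#' Construct a validated pedigree
#'
#' Builds a pedigree object from animal/sire/dam triples.  Unknown parents are
#' coded as `NA`, `0`, `"."` or the empty string and are treated as unrelated,
#' non-inbred founders.  Animals are reordered (with a warning) so that
#' parents always precede their offspring; a pedigree in which an animal is
#' its own ancestor is rejected.
#'
#' @param animal vector of animal ids, or a 3-column data frame
#'   (animal, sire, dam).
#' @param sire,dam parent id vectors, ignored when `animal` is a data frame.
#' @return An object of class `"pedigree"`: a list with `id` (character ids in
#'   parent-first order), `sire` and `dam` (integer indices into `id`, 0 for
#'   unknown).
#' @examples
#' ped <- pedigree(c("A", "B", "C"), c(0, 0, "A"), c(0, 0, "B"))
#' build_A(ped)
#' @export
pedigree <- function(animal, sire = NULL, dam = NULL) {
  if (is.data.frame(animal)) {
    stopifnot(ncol(animal) >= 3L)
    sire <- animal[[2L]]
    dam <- animal[[3L]]
    animal <- animal[[1L]]
  }
  id <- as.character(animal)
  sire <- .clean_parent(sire)
  dam <- .clean_parent(dam)
  n <- length(id)
  if (length(sire) != n || length(dam) != n)
    stop("animal, sire and dam must have equal length")
  if (anyNA(id)) stop("missing animal id")
  if (anyDuplicated(id))
    stop("duplicate animal ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  miss <- setdiff(c(sire[!is.na(sire)], dam[!is.na(dam)]), id)
  if (length(miss))
    stop("parent id(s) not listed as animals: ", paste(miss, collapse = ", "))
  if (any(!is.na(sire) & sire == id) || any(!is.na(dam) & dam == id))
    stop("pedigree contains a cycle: animal is its own parent")

  si <- match(sire, id, nomatch = 0L)
  di <- match(dam, id, nomatch = 0L)

  if (any(si >= seq_len(n)) || any(di >= seq_len(n))) {
    ord <- .topo_order(si, di)
    if (is.null(ord))
      stop("pedigree contains a cycle (an animal is its own ancestor)")
    warning("pedigree reordered so that parents precede offspring")
    id <- id[ord]
    si <- match(sire[ord], id, nomatch = 0L)
    di <- match(dam[ord], id, nomatch = 0L)
  }
  structure(list(id = id, sire = si, dam = di), class = "pedigree")
}

.clean_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x %in% c("0", "", ".", "NA")] <- NA_character_
  x
}

## Kahn's algorithm; returns NULL on a cycle.
.topo_order <- function(si, di) {
  n <- length(si)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, v)
    for (w in kids[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(ord) < n) return(NULL)
  ord
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", length(x$id), "animals,",
      sum(x$sire == 0L & x$dam == 0L), "founders\n")
  invisible(x)
}

#' @export
as.data.frame.pedigree <- function(x, ...) {
  data.frame(animal = x$id,
             sire = ifelse(x$sire > 0L, x$id[x$sire], NA_character_),
             dam = ifelse(x$dam > 0L, x$id[x$dam], NA_character_),
             stringsAsFactors = FALSE)
}

#' Numerator relationship matrix (tabular method)
#'
#' Computes the pedigree-based additive relationship matrix **A** by the
#' tabular recursion: `a_ii = 1 + 0.5 a(sire, dam)` and
#' `a_ij = 0.5 (a(j, sire_i) + a(j, dam_i))` for `j` preceding `i`.
#' Unknown parents contribute 0.  The result is symmetric positive
#' semidefinite with `diag(A) = 1 + F` (F the inbreeding coefficient).
#'
#' @param ped a [pedigree()] object.
#' @return dense symmetric matrix with animal ids as dimnames.
#' @export
build_A <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- length(ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  si <- ped$sire
  di <- ped$dam
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[prev, s] else 0
      ad_ <- if (d > 0L) A[prev, d] else 0
      v <- 0.5 * (as_ + ad_)
      A[prev, i] <- v
      A[i, prev] <- v
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' @param ped a [pedigree()] object.
#' @return named numeric vector of inbreeding coefficients F.
#' @export
inbreeding <- function(ped) {
  diag(build_A(ped)) - 1
}

#' Inverse of the numerator relationship matrix (Henderson's rules)
#'
#' Builds A-inverse directly from the pedigree using Henderson's rules with
#' Mendelian-sampling variances adjusted for parental inbreeding:
#' `d_i = 0.5 - 0.25 (F_s + F_d)` when both parents are known,
#' `0.75 - 0.25 F_p` when one is known, and 1 for founders.
#'
#' @param ped a [pedigree()] object.
#' @param sparse return a `Matrix::dgCMatrix` (default) or a dense matrix.
#' @return sparse (or dense) symmetric matrix; `build_A_inverse(p) %*%
#'   build_A(p)` is the identity up to floating-point error.
#' @export
build_A_inverse <- function(ped, sparse = TRUE) {
  stopifnot(inherits(ped, "pedigree"))
  n <- length(ped$id)
  f <- inbreeding(ped)
  si <- ped$sire
  di <- ped$dam
  ## accumulate in per-animal triplet lists; duplicates are summed on build
  ti <- vector("list", n); tj <- vector("list", n); tx <- vector("list", n)
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    dms <- if (s > 0L && d > 0L) 0.5 - 0.25 * (f[s] + f[d])
           else if (s > 0L) 0.75 - 0.25 * f[s]
           else if (d > 0L) 0.75 - 0.25 * f[d]
           else 1
    a <- 1 / dms
    I <- i; J <- i; X <- a
    for (p in c(s, d)) {
      if (p > 0L) {
        I <- c(I, i, p, p); J <- c(J, p, i, p)
        X <- c(X, -a / 2, -a / 2, a / 4)
      }
    }
    if (s > 0L && d > 0L) {
      I <- c(I, s, d); J <- c(J, d, s); X <- c(X, a / 4, a / 4)
    }
    ti[[i]] <- I; tj[[i]] <- J; tx[[i]] <- X
  }
  Ainv <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                               dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  if (sparse) Ainv else as.matrix(Ainv)
}
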