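## Plain-text readers and writers.  All tables are tab-separated with a
## header; pedigree files are 3 columns (animal, sire, dam; 0/NA = unknown),
## genotypes either a dosage matrix (first column id) plus a 4-column MAP
## (chrom, marker, cM ignored, bp) or a PLINK-style PED/MAP pair.

#' Read a pedigree file
#'
#' @param file 3-column delimited text (animal, sire, dam), header optional;
#'   `0`, `NA`, `.` or empty mean unknown.
#' @return a [pedigree()] (reordered parents-first if needed, with a
#'   warning).
#' @export
read_pedigree <- function(file) {
  dt <- data.table::fread(file, header = "auto", colClasses = "character",
                          data.table = FALSE)
  if (ncol(dt) < 3L) stop("pedigree file needs 3 columns: ", file)
  pedigree(dt[[1L]], dt[[2L]], dt[[3L]])
}

#' Write a pedigree file
#' @param ped a [pedigree()].
#' @param file output path.
#' @export
write_pedigree <- function(ped, file) {
  df <- as.data.frame(ped)
  df[is.na(df)] <- "0"
  data.table::fwrite(df, file, sep = "\t")
  invisible(file)
}

#' Read a phenotype file
#'
#' @param file delimited text with named columns `animal`, `y`, `yearmonth`,
#'   `sex`, `age`, `pen`, `group`, `litter`, `dam`.
#' @return a [grouped_phenotypes()] object.
#' @export
read_phenotypes <- function(file) {
  dt <- data.table::fread(file, data.table = FALSE)
  need <- c("animal", "y", "yearmonth", "sex", "age", "pen", "group",
            "litter", "dam")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("phenotype file ", file, " misses column(s): ",
         paste(miss, collapse = ", "))
  if (!is.numeric(dt$y) || !is.numeric(dt$age))
    stop("columns y and age must be numeric in ", file)
  grouped_phenotypes(dt)
}

#' Write a phenotype file
#' @param data a [grouped_phenotypes()] object.
#' @param file output path.
#' @export
write_phenotypes <- function(data, file) {
  rec <- data$records
  rec$gsclass <- NULL
  data.table::fwrite(rec, file, sep = "\t")
  invisible(file)
}

.read_map <- function(map_file) {
  mp <- data.table::fread(map_file, header = FALSE, data.table = FALSE)
  if (ncol(mp) < 4L)
    stop("MAP file needs 4 columns (chrom, marker, cM, bp): ", map_file)
  data.frame(marker = as.character(mp[[2L]]), chrom = mp[[1L]],
             pos = as.numeric(mp[[4L]]))
}

#' Read SNP genotypes
#'
#' Two on-disk formats are supported: a plain dosage matrix (first column
#' animal id, one numeric column per marker, values 0/1/2 or `NA`) or a
#' PLINK-style PED file (FID, IID, PAT, MAT, SEX, PHENO, then two allele
#' columns per marker, alleles in ACGT with `0` = missing).  Either comes
#' with a 4-column MAP file (chrom, marker, cM ignored, bp).  For PED input
#' the counted allele of each marker is its minor allele (alphabetically
#' first on a frequency tie), so stored dosages and frequencies `p` refer to
#' the minor allele.
#'
#' @param file dosage or PED file path.
#' @param map_file MAP file path.
#' @param format `"dosage"` or `"ped"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(file, map_file, format = c("dosage", "ped")) {
  format <- match.arg(format)
  map <- .read_map(map_file)
  if (format == "dosage") {
    dt <- data.table::fread(file, data.table = FALSE)
    ids <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(apply(dt[, -1L, drop = FALSE], 1L,
                         function(r) anyNA(suppressWarnings(as.numeric(r)) ) &
                           !anyNA(r)))
      stop("non-numeric dosage in ", file, " at data line(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    if (anyDuplicated(ids))
      stop("duplicate animal ids in ", file)
    rownames(m) <- ids
    colnames(m) <- map$marker
    return(genotype_matrix(m, map))
  }
  ## PED
  dt <- data.table::fread(file, header = FALSE, colClasses = "character",
                          data.table = FALSE)
  nm <- nrow(map)
  if (ncol(dt) != 6L + 2L * nm)
    stop("PED file ", file, " has ", ncol(dt),
         " columns; expected ", 6L + 2L * nm, " for ", nm, " markers")
  ids <- dt[[2L]]
  if (anyDuplicated(ids)) stop("duplicate animal ids in ", file)
  dos <- matrix(NA_real_, nrow(dt), nm, dimnames = list(ids, map$marker))
  for (j in seq_len(nm)) {
    a1 <- dt[[6L + 2L * j - 1L]]
    a2 <- dt[[6L + 2L * j]]
    a1[a1 == "0"] <- NA
    a2[a2 == "0"] <- NA
    alleles <- sort(unique(stats::na.omit(c(a1, a2))))
    if (length(alleles) > 2L)
      stop("marker ", map$marker[j], " has more than two alleles")
    if (length(alleles) == 0L) next
    cnt <- vapply(alleles, function(al) sum(a1 == al, na.rm = TRUE) +
                    sum(a2 == al, na.rm = TRUE), numeric(1))
    counted <- alleles[order(cnt, alleles)][1L]  # minor; alphabetical tie
    dos[, j] <- (a1 == counted) + (a2 == counted)
  }
  genotype_matrix(dos, map)
}

#' Write SNP genotypes as dosage matrix + MAP
#'
#' @param geno a [genotype_matrix()].
#' @param file dosage matrix output path.
#' @param map_file MAP output path (chrom, marker, cM = 0, bp).
#' @export
write_genotypes <- function(geno, file, map_file) {
  df <- data.frame(animal = rownames(geno$dosage), geno$dosage,
                   check.names = FALSE)
  data.table::fwrite(df, file, sep = "\t")
  mp <- data.frame(chrom = geno$map$chrom, marker = geno$map$marker,
                   cM = 0, bp = geno$map$pos)
  data.table::fwrite(mp, map_file, sep = "\t", col.names = FALSE)
  invisible(file)
}

#' Write a result table
#'
#' Generic tab-separated writer for chain samples, chain summaries and
#' window tables.
#'
#' @param x data frame (or `posterior_chain`, written as its sample table).
#' @param file output path.
#' @export
write_results <- function(x, file) {
  if (inherits(x, "posterior_chain")) x <- x$samples
  data.table::fwrite(as.data.frame(x), file, sep = "\t")
  invisible(file)
}

#' Read a plain key/value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; values are
#' type-converted (numbers become numeric).
#'
#' @param file config file path.
#' @return named list.
#' @export
read_run_config <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  out <- lapply(vals, function(v) {
    nv <- suppressWarnings(as.numeric(v))
    if (!is.na(nv)) nv else v
  })
  stats::setNames(out, keys)
}
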