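#' Simulation scenario
#'
#' Describes the world the synthetic-data generator draws from.  The
#' defaults emulate the pig performance-test setting the model targets:
#' same-sex groups of 4-13 animals with mean size 6.8, full-sib litters with
#' mean family size 4.12, dams with repeated litters, birth year-month / sex
#' / group-size-class fixed effects plus an age-at-target-weight covariate,
#' a trait mean of 804 g/day, and true variance components of the magnitudes
#' estimated for average daily gain (direct genetic 2235, social 16, their
#' covariance 43, pen 43, group 227, maternal permanent environment 48,
#' litter 218, early-life 17, litter/early-life covariance 36, residual
#' 3299, all (g/day)^2).
#'
#' @param n_phenotyped total phenotyped (non-founder) animals.
#' @param n_founders number of unphenotyped founders.
#' @param n_generations offspring generations (phenotyped animals are split
#'   evenly across them).
#' @param mean_family_size mean full-sib litter size.
#' @param litters_per_dam mean number of litters per breeding dam (dams are
#'   reused across litters, as in a nucleus herd).
#' @param litters_per_sire mean number of litters per breeding sire
#'   (paternal half-sib family structure).
#' @param group_sizes admissible group sizes (a contiguous integer range).
#' @param mean_group_size target mean group size.
#' @param groups_per_pen groups sharing a physical pen.
#' @param n_markers,n_chromosomes,chromosome_bp marker panel layout.
#' @param maf_range founder allele-frequency range (uniform draw).
#' @param genotyped `"last"` (genotype the final generation),
#'   `"phenotyped"` (all recorded animals), `"all"`, `"none"`, or a
#'   character vector of animal ids.
#' @param components true variance components: a [variance_components()]
#'   object or a named list (zeros allowed for degenerate checks).
#' @param n_yearmonth number of birth year-month levels.
#' @param sd_yearmonth,sd_sex,sd_gsclass spread of the fixed-effect levels
#'   (drawn once per level from centred normals).
#' @param age_range,age_slope age covariate range (days) and its regression
#'   slope (g/day per day).
#' @param intercept trait mean (g/day).
#' @param planted_qtl optional data frame with columns `marker` (id, or
#'   `"auto"` to pick the marker with realized frequency closest to 0.5 --
#'   a maximally informative, well-observed variant) and `frac` (fraction
#'   of the direct genetic variance assigned to that marker); fractions
#'   must sum to <= 1.
#' @param seed integer seed for the whole simulation.
#' @return object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(n_phenotyped = 1500L, n_founders = 100L,
                         n_generations = 3L, mean_family_size = 4.12,
                         litters_per_dam = 3.2, litters_per_sire = 8,
                         group_sizes = 4:13, mean_group_size = 6.8,
                         groups_per_pen = 8L,
                         n_markers = 500L, n_chromosomes = 5L,
                         chromosome_bp = 10e6, maf_range = c(0.05, 0.5),
                         genotyped = "last",
                         components = variance_components(
                           var_aD = 2235, var_aS = 16, cov_aDaS = 43,
                           var_c = 43, var_g = 227, var_pe = 48,
                           var_l = 218, var_k = 17, cov_lk = 36,
                           var_e = 3299),
                         n_yearmonth = 12L, sd_yearmonth = 30, sd_sex = 20,
                         sd_gsclass = 10, age_range = c(135, 165),
                         age_slope = -2, intercept = 804,
                         planted_qtl = NULL, seed = 20191709L) {
  stopifnot(n_founders >= 2L, n_generations >= 1L, n_phenotyped >= 4L,
            mean_group_size >= min(group_sizes),
            mean_group_size <= max(group_sizes))
  if (mean_family_size < 1) stop("impossible family size")
  comp <- as.list(components)
  if (!is.null(planted_qtl)) {
    stopifnot(is.data.frame(planted_qtl),
              all(c("marker", "frac") %in% names(planted_qtl)))
    if (sum(planted_qtl$frac) > 1)
      stop("planted QTL fractions must sum to <= 1")
  }
  .check_psd2(comp$var_aD, comp$cov_aDaS, comp$var_aS, "genetic")
  .check_psd2(comp$var_l, comp$cov_lk, comp$var_k, "litter/early-life")
  structure(list(n_phenotyped = as.integer(n_phenotyped),
                 n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 mean_family_size = mean_family_size,
                 litters_per_dam = litters_per_dam,
                 litters_per_sire = litters_per_sire,
                 group_sizes = as.integer(group_sizes),
                 mean_group_size = mean_group_size,
                 groups_per_pen = as.integer(groups_per_pen),
                 n_markers = as.integer(n_markers),
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_bp = chromosome_bp, maf_range = maf_range,
                 genotyped = genotyped, components = comp,
                 n_yearmonth = as.integer(n_yearmonth),
                 sd_yearmonth = sd_yearmonth, sd_sex = sd_sex,
                 sd_gsclass = sd_gsclass, age_range = age_range,
                 age_slope = age_slope, intercept = intercept,
                 planted_qtl = planted_qtl, seed = as.integer(seed)),
            class = "sim_scenario")
}

.check_psd2 <- function(v1, cv, v2, what) {
  if (v1 < 0 || v2 < 0 || v1 * v2 - cv^2 < -1e-12)
    stop(what, " 2x2 block is not positive semidefinite")
}

## lower Cholesky-like factor of a 2x2 PSD matrix (zeros allowed)
.fac2 <- function(v1, cv, v2) {
  if (v1 <= 0 && v2 <= 0) return(matrix(0, 2, 2))
  if (v1 <= 0) return(matrix(c(0, 0, 0, sqrt(v2)), 2, 2))
  l11 <- sqrt(v1)
  l21 <- cv / l11
  l22 <- sqrt(max(v2 - l21^2, 0))
  matrix(c(l11, l21, 0, l22), 2, 2)
}

#' Simulate a pedigree with discrete generations
#'
#' Founders are unrelated; each later generation is produced by random
#' mating (a random sire and dam from the previous generation per litter,
#' dams drawn with replacement so repeated litters per dam occur) with
#' litter sizes Poisson-distributed around the scenario's mean family size.
#'
#' @param scenario a [sim_scenario()].
#' @return list with `ped` (a [pedigree()]) and `meta` (data frame with
#'   `id`, `sex`, `generation`, `litter`, `dam`).
#' @export
simulate_pedigree <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  nf <- scenario$n_founders
  id <- sprintf("A%05d", seq_len(nf))
  sex <- rep_len(c("M", "F"), nf)
  meta <- data.frame(id = id, sire = NA_character_, dam = NA_character_,
                     sex = sex, generation = 0L, litter = NA_character_,
                     stringsAsFactors = FALSE)
  per_gen <- diff(round(seq(0, scenario$n_phenotyped,
                            length.out = scenario$n_generations + 1L)))
  next_id <- nf
  litter_no <- 0L
  for (g in seq_len(scenario$n_generations)) {
    prev <- meta[meta$generation == g - 1L, ]
    sires <- prev$id[prev$sex == "M"]
    dams <- prev$id[prev$sex == "F"]
    if (!length(sires) || !length(dams))
      stop("generation ", g - 1L, " lacks sires or dams")
    need <- per_gen[g]
    ## breeding pools sized so dams and sires are reused across litters,
    ## giving the repeated-parity and paternal half-sib structure of a
    ## nucleus herd
    n_litters <- max(1, round(need / scenario$mean_family_size))
    dam_pool <- sample(dams, min(length(dams), max(
      1L, ceiling(n_litters / scenario$litters_per_dam))))
    sire_pool <- sample(sires, min(length(sires), max(
      1L, ceiling(n_litters / scenario$litters_per_sire))))
    rows <- vector("list", 0L)
    made <- 0L
    while (made < need) {
      litter_no <- litter_no + 1L
      size <- min(max(1L, stats::rpois(1L, scenario$mean_family_size)),
                  need - made)
      s <- sample(sire_pool, 1L)
      d <- sample(dam_pool, 1L)
      ids <- sprintf("A%05d", next_id + seq_len(size))
      next_id <- next_id + size
      rows[[length(rows) + 1L]] <-
        data.frame(id = ids, sire = s, dam = d,
                   sex = sample(c("M", "F"), size, replace = TRUE),
                   generation = g,
                   litter = sprintf("L%05d", litter_no),
                   stringsAsFactors = FALSE)
      made <- made + size
    }
    meta <- rbind(meta, do.call(rbind, rows))
  }
  ped <- pedigree(meta$id, meta$sire, meta$dam)
  list(ped = ped, meta = meta)
}

#' Simulate SNP genotypes by gene dropping
#'
#' Founder genotypes are drawn in Hardy-Weinberg proportions at allele
#' frequencies uniform on the scenario's MAF range; descendants receive one
#' allele from each parent by Mendelian sampling (markers unlinked).  Marker
#' positions are placed uniformly at random along equal-length chromosomes.
#'
#' @param sim output of [simulate_pedigree()] (or any list with `ped`).
#' @param scenario a [sim_scenario()].
#' @return a [genotype_matrix()] covering every pedigree animal.
#' @export
simulate_genotypes <- function(sim, scenario) {
  ped <- sim$ped
  n <- length(ped$id)
  m <- scenario$n_markers
  per_chr <- diff(round(seq(0, m, length.out = scenario$n_chromosomes + 1L)))
  map <- do.call(rbind, lapply(seq_len(scenario$n_chromosomes), function(ch)
    data.frame(marker = character(per_chr[ch]), chrom = ch,
               pos = sort(sample.int(scenario$chromosome_bp, per_chr[ch])))))
  map$marker <- sprintf("snp%05d", seq_len(m))
  p0 <- stats::runif(m, scenario$maf_range[1L], scenario$maf_range[2L])

  dos <- matrix(0L, n, m, dimnames = list(ped$id, map$marker))
  for (i in seq_len(n)) {
    s <- ped$sire[i]
    d <- ped$dam[i]
    a1 <- if (s > 0L) stats::rbinom(m, 1L, dos[s, ] / 2)
          else stats::rbinom(m, 1L, p0)
    a2 <- if (d > 0L) stats::rbinom(m, 1L, dos[d, ] / 2)
          else stats::rbinom(m, 1L, p0)
    dos[i, ] <- a1 + a2
  }
  genotype_matrix(dos, map)
}

## partition a vector of animal ids into groups with sizes drawn from the
## scenario's group-size distribution (shifted binomial, matching the target
## mean); a too-small remainder is folded into the earlier groups
.make_groups <- function(ids, scenario, litter = NULL) {
  lo <- min(scenario$group_sizes)
  hi <- max(scenario$group_sizes)
  pr <- (scenario$mean_group_size - lo) / (hi - lo)
  if (is.null(litter)) {
    ids <- sample(ids)
  } else {
    ## pens fill from a flow of contemporaneous litters: permute litters,
    ## keep littermates adjacent, so each group holds a few full-sib
    ## families (the composition that identifies social genetic variance)
    ids <- unlist(split(ids, litter)[sample(length(unique(litter)))],
                  use.names = FALSE)
  }
  n <- length(ids)
  if (n < 2L) stop("cannot form a group from fewer than 2 animals")
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sizes <- c(sizes, lo + stats::rbinom(1L, hi - lo, pr))
  }
  over <- sum(sizes) - n
  sizes[length(sizes)] <- sizes[length(sizes)] - over
  if (sizes[length(sizes)] < min(lo, n)) {
    rem <- sizes[length(sizes)]
    sizes <- sizes[-length(sizes)]
    if (length(sizes) == 0L) {
      sizes <- rem
    } else {
      add <- rep_len(seq_along(sizes), rem)
      for (a in add) sizes[a] <- sizes[a] + 1L
    }
  }
  split(ids, rep(seq_along(sizes), sizes))
}

#' Simulate phenotypes under the social-effects model
#'
#' Draws every random term of the model -- correlated direct and social
#' genetic effects from `MVN(0, C (x) A)` (optionally with part of the
#' direct variance planted on named markers), correlated litter and
#' early-life effects, pen, group, maternal permanent environment and
#' residual -- assigns animals to same-sex groups, pens, and fixed-effect
#' levels, and assembles the records through the model's own incidence
#' matrices (so the social and early-life contributions are
#' dilution-weighted exactly as the fitted model assumes).
#'
#' @param sim output of [simulate_pedigree()].
#' @param geno a [genotype_matrix()] covering the pedigree (required when
#'   QTLs are planted; otherwise optional).
#' @param scenario a [sim_scenario()].
#' @return list with `data` (a [grouped_phenotypes()]) and `truth` (true
#'   effect vectors, total breeding values, marker effects, components).
#' @export
simulate_phenotypes <- function(sim, geno = NULL, scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  ped <- sim$ped
  meta <- sim$meta
  comp <- scenario$components
  n_ped <- length(ped$id)

  ## genetic effects: planted marker part + polygenic remainder
  frac_planted <- 0
  beta <- NULL
  qtl_part <- 0
  if (!is.null(scenario$planted_qtl)) {
    if (is.null(geno)) stop("planted QTLs require genotypes")
    pq <- scenario$planted_qtl
    pq$marker <- as.character(pq$marker)
    auto <- pq$marker == "auto"
    if (any(auto)) {
      cand <- order(abs(geno$p - 0.5))
      cand <- setdiff(cand, match(pq$marker[!auto], geno$map$marker))
      pq$marker[auto] <- geno$map$marker[cand[seq_len(sum(auto))]]
    }
    mi <- match(pq$marker, geno$map$marker)
    if (anyNA(mi)) stop("planted marker(s) not on the map")
    p_hat <- geno$p[mi]
    if (any(p_hat <= 0 | p_hat >= 1)) stop("planted marker is monomorphic")
    beta <- stats::setNames(
      sqrt(pq$frac * comp$var_aD / (2 * p_hat * (1 - p_hat))),
      geno$map$marker[mi])
    Zq <- sweep(geno$dosage[ped$id, mi, drop = FALSE], 2L, 2 * p_hat)
    qtl_part <- as.numeric(Zq %*% beta)
    frac_planted <- sum(pq$frac)
  }
  var_poly <- comp$var_aD * (1 - frac_planted)
  .check_psd2(var_poly, comp$cov_aDaS, comp$var_aS, "residual-polygenic")
  Sfac <- .fac2(var_poly, comp$cov_aDaS, comp$var_aS)
  if (all(Sfac == 0)) {
    a <- matrix(0, n_ped, 2)
  } else {
    U <- chol(build_A(ped))
    a <- crossprod(U, matrix(stats::rnorm(2 * n_ped), n_ped, 2)) %*% t(Sfac)
  }
  a_D <- stats::setNames(qtl_part + a[, 1L], ped$id)
  a_S <- stats::setNames(a[, 2L], ped$id)

  ## grouping of phenotyped animals, within generation and sex
  ph <- meta[meta$generation > 0L, ]
  grp_list <- list()
  for (g in sort(unique(ph$generation))) {
    for (sx in c("M", "F")) {
      sel <- ph$generation == g & ph$sex == sx
      ids <- ph$id[sel]
      if (length(ids) < 2L) next
      grp_list <- c(grp_list,
                    .make_groups(ids, scenario, litter = ph$litter[sel]))
    }
  }
  names(grp_list) <- sprintf("grp%04d", seq_along(grp_list))
  grp_of <- stats::setNames(rep(names(grp_list), lengths(grp_list)),
                            unlist(grp_list))
  pen_of_grp <- stats::setNames(
    sprintf("pen%03d", ceiling(seq_along(grp_list) / scenario$groups_per_pen)),
    names(grp_list))
  ym_of_grp <- stats::setNames(
    sample(sprintf("ym%03d", seq_len(scenario$n_yearmonth)),
           length(grp_list), replace = TRUE),
    names(grp_list))

  ph <- ph[ph$id %in% names(grp_of), ]
  rec <- data.frame(animal = ph$id, y = 0,
                    yearmonth = ym_of_grp[grp_of[ph$id]],
                    sex = ph$sex,
                    age = stats::runif(nrow(ph), scenario$age_range[1L],
                                       scenario$age_range[2L]),
                    pen = pen_of_grp[grp_of[ph$id]],
                    group = grp_of[ph$id],
                    litter = ph$litter, dam = ph$dam,
                    stringsAsFactors = FALSE)
  data <- grouped_phenotypes(rec)
  des <- build_design(data, ped)

  ## remaining random terms
  draw <- function(labels, v)
    stats::setNames(stats::rnorm(length(labels), 0, sqrt(v)), labels)
  litters <- des$levels$litter
  Bfac <- .fac2(comp$var_l, comp$cov_lk, comp$var_k)
  lk <- matrix(stats::rnorm(2 * length(litters)), ncol = 2) %*% t(Bfac)
  l_eff <- stats::setNames(lk[, 1L], litters)
  k_eff <- stats::setNames(lk[, 2L], litters)
  c_eff <- draw(des$levels$pen, comp$var_c)
  g_eff <- draw(des$levels$group, comp$var_g)
  pe_eff <- draw(des$levels$pe, comp$var_pe)
  e <- stats::rnorm(nrow(rec), 0, sqrt(comp$var_e))

  ## fixed part
  b_ym <- draw(sprintf("ym%03d", seq_len(scenario$n_yearmonth)),
               scenario$sd_yearmonth^2)
  b_sex <- draw(c("F", "M"), scenario$sd_sex^2)
  sizes <- lengths(data$group_membership)
  cls <- sort(unique(sizes))
  b_gs <- draw(as.character(cls), scenario$sd_gsclass^2)
  gs_of_rec <- as.character(sizes[rec$group])
  fix <- scenario$intercept + b_ym[rec$yearmonth] + b_sex[rec$sex] +
    b_gs[gs_of_rec] +
    scenario$age_slope * (rec$age - mean(scenario$age_range))

  y <- as.numeric(fix +
    des$Z_D %*% a_D[des$levels$animal] +
    des$Z_S %*% a_S[des$levels$animal] +
    des$W %*% c_eff[des$levels$pen] +
    des$V %*% g_eff[des$levels$group] +
    des$T %*% pe_eff[des$levels$pe] +
    des$U %*% l_eff[litters] +
    des$Q %*% k_eff[litters] + e)
  rec$y <- y
  data <- grouped_phenotypes(rec)

  truth <- list(a_D = a_D, a_S = a_S, l = l_eff, k = k_eff, c = c_eff,
                g = g_eff, pe = pe_eff, e = e, fixed = fix,
                TBV = total_breeding_values(a_D, a_S,
                                            data$mean_group_size),
                beta = beta, components = comp)
  list(data = data, truth = truth)
}

#' Simulate a complete data set
#'
#' Runs [simulate_pedigree()], [simulate_genotypes()] and
#' [simulate_phenotypes()] under one seed.
#'
#' @param scenario a [sim_scenario()].
#' @return list with `pedigree`, `meta`, `genotypes` (all pedigree animals;
#'   `NULL` when the scenario has no markers), `genotyped_ids` (the subset
#'   treated as genotyped for single-step evaluation), `data`, `truth`,
#'   `scenario`.
#' @export
simulate_sge_data <- function(scenario = sim_scenario()) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  sim <- simulate_pedigree(scenario)
  geno <- if (scenario$n_markers > 0L) simulate_genotypes(sim, scenario)
          else NULL
  phe <- simulate_phenotypes(sim, geno, scenario)
  gsel <- scenario$genotyped
  genotyped_ids <-
    if (is.null(geno) || identical(gsel, "none")) character(0)
    else if (identical(gsel, "all")) sim$meta$id
    else if (identical(gsel, "last"))
      sim$meta$id[sim$meta$generation == max(sim$meta$generation)]
    else if (identical(gsel, "phenotyped")) phe$data$records$animal
    else as.character(gsel)
  genotyped_ids <- intersect(genotyped_ids, phe$data$records$animal)
  list(pedigree = sim$ped, meta = sim$meta, genotypes = geno,
       genotyped_ids = genotyped_ids, data = phe$data, truth = phe$truth,
       scenario = scenario)
}
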