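#' Dilution covariate for variable group sizes
#'
#' Returns `(mean group size - 1) / (group size - 1)`, the covariate that
#' scales social genetic and early-life environmental contributions so that
#' the total social load on a record is independent of its group's size.
#'
#' @param group_size integer vector of group sizes (each >= 2).
#' @param mean_group_size scalar mean group size of the data.
#' @return numeric vector of dilution factors.
#' @export
dilution <- function(group_size, mean_group_size) {
  if (any(group_size < 2))
    stop("group_size < 2: social structure undefined for singleton groups")
  (mean_group_size - 1) / (group_size - 1)
}

#' Grouped phenotype records
#'
#' Validates a table of single-record phenotypes with the grouping structure
#' the social-effects model needs: trait value (g/day), fixed-effect levels
#' (birth year-month, sex, group-size class), an age covariate, and the ids
#' of the physical pen, the social group, the birth litter and the dam.
#'
#' @param records data frame with columns `animal`, `y`, `yearmonth`, `sex`,
#'   `age`, `pen`, `group`, `litter`, `dam`.
#' @return object of class `"grouped_phenotypes"`: the validated records
#'   (plus a derived `gsclass` group-size factor), `group_membership`
#'   (list of animal ids per group) and `mean_group_size`.
#' @export
grouped_phenotypes <- function(records) {
  req <- c("animal", "y", "yearmonth", "sex", "age", "pen", "group",
           "litter", "dam")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  records <- as.data.frame(records)[, req]
  records$animal <- as.character(records$animal)
  for (col in c("yearmonth", "sex", "pen", "group", "litter", "dam"))
    records[[col]] <- as.character(records[[col]])
  if (anyDuplicated(records$animal))
    stop("animals with more than one record / group: ",
         paste(unique(records$animal[duplicated(records$animal)]),
               collapse = ", "))
  bad <- !stats::complete.cases(records[c("litter", "dam")])
  if (any(bad))
    stop("animal(s) missing litter or dam: ",
         paste(records$animal[bad], collapse = ", "))
  drop <- is.na(records$age)
  if (any(drop)) {
    warning(sum(drop), " record(s) dropped for missing age covariate")
    records <- records[!drop, , drop = FALSE]
  }
  membership <- split(records$animal, records$group)
  sizes <- lengths(membership)
  if (any(sizes < 2))
    stop("singleton group(s): ", paste(names(sizes)[sizes < 2], collapse = ", "))
  nbar <- mean(sizes)
  gs <- sizes[records$group]
  records$gsclass <- factor(gs, levels = sort(unique(gs)))
  rownames(records) <- NULL
  structure(list(records = records,
                 group_membership = membership,
                 mean_group_size = nbar),
            class = "grouped_phenotypes")
}

#' @export
print.grouped_phenotypes <- function(x, ...) {
  cat("grouped_phenotypes:", nrow(x$records), "records in",
      length(x$group_membership), "groups (mean size",
      round(x$mean_group_size, 2), ")\n")
  invisible(x)
}
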