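#' High/low prevalence dichotomization
#'
#' Applies the a-priori cutoffs that dichotomize tract sociodemographics:
#' a tract is high-prevalence African American or Hispanic when the share is
#' at least 15%, high-prevalence children when at least 25% of residents are
#' under 18, and high poverty when strictly more than 15.4% of residents are
#' below the poverty level (the baseline state poverty rate; note the strict
#' inequality, unlike the other cutoffs). The same cutoffs are used in both
#' study years.
#'
#' @param pct_aa,pct_hisp,pct_under18,pct_poverty percentages in `[0, 100]`;
#'   `pct_poverty` may be `NA` (the row is then routed to exclusion by
#'   [filter_tracts()], and `high_poverty` is `NA`).
#' @return A data frame with logical columns `high_aa`, `high_hisp`,
#'   `high_children`, `high_poverty`.
#' @examples
#' classify_prevalence(15, 0, 0, 15.4) # high_aa TRUE, high_poverty FALSE
#' @export
classify_prevalence <- function(pct_aa, pct_hisp, pct_under18, pct_poverty) {
  check_pct <- function(x, nm, allow_na = FALSE) {
    bad <- if (allow_na) !is.na(x) & (x < 0 | x > 100) else
      is.na(x) | x < 0 | x > 100
    if (any(bad)) stop(nm, " must lie in [0, 100]; offending rows: ",
                       paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  check_pct(pct_aa, "pct_aa"); check_pct(pct_hisp, "pct_hisp")
  check_pct(pct_under18, "pct_under18")
  check_pct(pct_poverty, "pct_poverty", allow_na = TRUE)
  data.frame(high_aa = pct_aa >= 15,
             high_hisp = pct_hisp >= 15,
             high_children = pct_under18 >= 25,
             high_poverty = pct_poverty > 15.4)
}

#' NCHS county level to urban/suburban/rural
#'
#' Maps the six-level NCHS Urban-Rural Classification Scheme for Counties to
#' the three-level neighborhood type used throughout: level 1 is urban,
#' levels 2-3 suburban, levels 4-6 rural.
#'
#' @param nchs_level integer vector with values in 1..6.
#' @return Factor with levels `urban`, `suburban`, `rural`.
#' @examples
#' classify_rurality(c(1, 3, 6))
#' @export
classify_rurality <- function(nchs_level) {
  if (any(is.na(nchs_level)) || any(!nchs_level %in% 1:6)) {
    stop("nchs_level must be an integer in 1..6")
  }
  out <- ifelse(nchs_level == 1, "urban",
                ifelse(nchs_level <= 3, "suburban", "rural"))
  factor(out, levels = c("urban", "suburban", "rural"))
}

#' Tract exclusion filter
#'
#' Restricts the paired two-year table to analyzable tracts: a tract is
#' dropped (in both years) if in either year its population is zero, below
#' the minimum of 500 residents, or its poverty percentage is missing. One
#' reason is logged per excluded tract with priority
#' zero population > population below minimum > missing poverty.
#' The filter is idempotent.
#'
#' @param table a tract table with both years per tract; must carry
#'   `population`, and `pct_poverty` or `high_poverty` to detect missing
#'   poverty.
#' @param min_population minimum retained population (default 500; a tract
#'   with exactly 500 residents is retained).
#' @return A list with `table` (retained rows) and `exclusions` (data frame
#'   `tract_id`, `reason`).
#' @export
filter_tracts <- function(table, min_population = 500) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) {
    return(list(table = table,
                exclusions = data.frame(tract_id = character(0),
                                        reason = character(0))))
  }
  need <- c("tract_id", "year", "population")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  pov_missing <- if ("pct_poverty" %in% names(table)) {
    is.na(table$pct_poverty)
  } else if ("high_poverty" %in% names(table)) {
    is.na(table$high_poverty)
  } else rep(FALSE, nrow(table))

  per_tract <- split(seq_len(nrow(table)), table$tract_id)
  reasons <- vapply(per_tract, function(idx) {
    pop <- table$population[idx]
    if (any(is.na(pop) | pop == 0)) return("zero_population")
    if (any(pop < min_population)) return("population_below_minimum")
    if (any(pov_missing[idx])) return("missing_poverty")
    ""
  }, character(1))
  excluded <- names(reasons)[reasons != ""]
  keep <- !(table$tract_id %in% excluded)
  list(table = table[keep, , drop = FALSE],
       exclusions = data.frame(tract_id = excluded,
                               reason = unname(reasons[reasons != ""]),
                               stringsAsFactors = FALSE))
}

# Internal column/shape validation for tract tables.
check_tract_table <- function(table, need_counts = TRUE) {
  stopifnot(is.data.frame(table))
  need <- c("tract_id", "year", "population", "high_aa", "high_hisp",
            "high_children", "high_poverty", "rurality")
  if (need_counts) need <- c(need, "retailer_count")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("tract table missing columns: ",
                         paste(miss, collapse = ", "))
  key <- paste(table$tract_id, table$year)
  if (anyDuplicated(key)) {
    stop("duplicated (tract_id, year): ",
         paste(utils::head(unique(key[duplicated(key)]), 3L), collapse = "; "))
  }
  if ("licensing" %in% names(table)) {
    yrs <- sort(unique(table$year))
    if (length(yrs) == 2L && any(table$licensing[table$year == yrs[1L]])) {
      stop("licensing must be FALSE for all baseline-year rows")
    }
  }
  table$tract_id <- as.character(table$tract_id)
  table
}
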