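#' Tobacco retailer density
#'
#' TRD is the number of retailers per 1000 residents in a tract:
#' `1000 * count / population`.
#'
#' @param retailer_count nonnegative counts.
#' @param population positive populations (zero-population tracts must have
#'   been filtered out).
#' @return Numeric TRD values.
#' @examples
#' compute_trd(5, 5000) # 1
#' @export
compute_trd <- function(retailer_count, population) {
  if (any(is.na(population)) || any(population <= 0)) {
    stop("population must be positive; filter tracts first")
  }
  if (any(retailer_count < 0)) stop("retailer_count must be nonnegative")
  1000 * retailer_count / population
}

#' Median TRD by group and year
#'
#' One row per level of a grouping variable per year, with the level's
#' prevalence (percent of tracts) and median TRD. Medians use the midpoint
#' of the two central order statistics for even counts.
#'
#' @param table tract table with counts.
#' @param grouping one of `"high_aa"`, `"high_hisp"`, `"high_children"`,
#'   `"high_poverty"`, `"rurality"`, `"licensing"`.
#' @return Data frame with columns `grouping`, `level`, `year`, `n_tracts`,
#'   `prevalence_pct`, `median_trd`.
#' @export
group_median_trd <- function(table, grouping) {
  table <- check_tract_table(table)
  allowed <- c("high_aa", "high_hisp", "high_children", "high_poverty",
               "rurality", "licensing")
  if (!is.character(grouping) || length(grouping) != 1L ||
      !grouping %in% allowed) {
    stop("unknown grouping; use one of: ", paste(allowed, collapse = ", "))
  }
  if (nrow(table) == 0L) stop("table is empty")
  trd <- compute_trd(table$retailer_count, table$population)
  g <- table[[grouping]]
  if (is.logical(g)) g <- factor(ifelse(g, "high", "low"),
                                 levels = c("high", "low"))
  g <- as.factor(g)
  out <- expand.grid(level = levels(g), year = sort(unique(table$year)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_tracts <- mapply(function(l, y) sum(g == l & table$year == y),
                         out$level, out$year)
  tot <- vapply(out$year, function(y) sum(table$year == y), numeric(1))
  out$prevalence_pct <- 100 * out$n_tracts / tot
  out$median_trd <- mapply(function(l, y) {
    v <- trd[g == l & table$year == y]
    if (!length(v)) NA_real_ else stats::median(v)
  }, out$level, out$year)
  cbind(grouping = grouping, out)
}

#' Percent change
#'
#' `100 * (new - old) / old`; undefined (NA, with a message attribute) when
#' the old value is zero, mirroring the "N/A" convention for ratios with an
#' empty base. Values are carried unrounded; round only for display.
#'
#' @param old_value,new_value numeric, same units.
#' @return Percent change (possibly NA).
#' @export
percent_change <- function(old_value, new_value) {
  out <- ifelse(old_value == 0, NA_real_,
                100 * (new_value - old_value) / old_value)
  out
}

#' Disparity and equitable-decline flags
#'
#' For a two-level grouping (divested vs reference), a TRD disparity in a
#' year means the divested level's median TRD exceeds the reference's; an
#' equitable decline means the divested level's percent change in median TRD
#' from the first to the second year is smaller (more negative, i.e. a
#' greater decline) than the reference's.
#'
#' @param summary rows from [group_median_trd()] for one grouping with
#'   exactly two levels.
#' @param divested_level the level regarded as divested (e.g. `"high"`).
#' @return List with `disparity` (named logical per year) and
#'   `equitable_decline` (logical).
#' @export
disparity_flags <- function(summary, divested_level) {
  lev <- unique(summary$level)
  if (length(lev) != 2L) {
    stop("disparity_flags needs exactly two levels; got ",
         length(lev), " (compare rurality pairwise)")
  }
  if (!divested_level %in% lev) stop("unknown divested_level")
  ref_level <- setdiff(lev, divested_level)
  years <- sort(unique(summary$year))
  med <- function(l, y) summary$median_trd[summary$level == l &
                                             summary$year == y]
  disparity <- vapply(years, function(y) med(divested_level, y) >
                        med(ref_level, y), logical(1))
  names(disparity) <- years
  pc <- function(l) percent_change(med(l, years[1L]), med(l, years[length(years)]))
  equitable <- isTRUE(pc(divested_level) < pc(ref_level))
  list(disparity = disparity, equitable_decline = equitable)
}

#' Tract-level TRD change summary
#'
#' Per-tract change in TRD between the two years: the fractions of tracts
#' that increased, decreased, and were unchanged; the mean increase and mean
#' decrease among changed tracts (both reported as positive magnitudes, in
#' retailers per 1000); and the overall statewide percent change computed
#' from aggregate counts and populations per year (a ratio of totals, not a
#' mean of tract-level changes).
#'
#' @param table tract table with counts, both years per tract.
#' @return List of class `trd_change_summary`.
#' @export
change_summary <- function(table) {
  table <- check_tract_table(table)
  years <- sort(unique(table$year))
  if (length(years) != 2L) stop("table must contain exactly two years")
  t1 <- table[table$year == years[1L], ]
  t2 <- table[table$year == years[2L], ]
  t2 <- t2[match(t1$tract_id, t2$tract_id), ]
  if (anyNA(t2$tract_id)) stop("every tract must be present in both years")
  d <- compute_trd(t2$retailer_count, t2$population) -
    compute_trd(t1$retailer_count, t1$population)
  n <- length(d)
  inc <- d > 0; dec <- d < 0
  agg_trd <- function(tt) 1000 * sum(tt$retailer_count) / sum(tt$population)
  out <- list(
    n_tracts = n,
    fraction_increased = mean(inc),
    fraction_decreased = mean(dec),
    fraction_unchanged = mean(!inc & !dec),
    mean_increase = if (any(inc)) mean(d[inc]) else NA_real_,
    mean_decrease = if (any(dec)) mean(-d[dec]) else NA_real_,
    overall_pct_change = percent_change(agg_trd(t1), agg_trd(t2)),
    years = years)
  class(out) <- "trd_change_summary"
  out
}

#' @export
print.trd_change_summary <- function(x, ...) {
  cat(sprintf("TRD change %d-%d over %d tracts\n",
              x$years[1], x$years[2], x$n_tracts))
  cat(sprintf("  increased: %.1f%% (mean +%.2f per 1000)\n",
              100 * x$fraction_increased, x$mean_increase))
  cat(sprintf("  decreased: %.1f%% (mean -%.2f per 1000)\n",
              100 * x$fraction_decreased, x$mean_decrease))
  cat(sprintf("  unchanged: %.1f%%\n", 100 * x$fraction_unchanged))
  cat(sprintf("  overall statewide change: %+.2f%%\n", x$overall_pct_change))
  invisible(x)
}

#' Descriptive disparity table
#'
#' Convenience layer: [group_median_trd()] for every grouping variable
#' (African American, Hispanic, under-18, poverty, neighborhood type,
#' licensing), with percent changes in prevalence and median TRD attached.
#'
#' @param table tract table with counts.
#' @return Data frame in long-by-year layout with per-level `% change`
#'   columns (`prev_change_pct`, `trd_change_pct`) repeated on each year row.
#' @export
describe_trd <- function(table) {
  groupings <- c("high_aa", "high_hisp", "high_children", "high_poverty",
                 "rurality", "licensing")
  groupings <- intersect(groupings, c(names(table), "rurality"))
  res <- do.call(rbind, lapply(groupings, group_median_trd, table = table))
  years <- sort(unique(res$year))
  key <- paste(res$grouping, res$level)
  for (k in unique(key)) {
    i1 <- which(key == k & res$year == years[1L])
    i2 <- which(key == k & res$year == years[length(years)])
    res$prev_change_pct[key == k] <-
      percent_change(res$prevalence_pct[i1], res$prevalence_pct[i2])
    res$trd_change_pct[key == k] <-
      percent_change(res$median_trd[i1], res$median_trd[i2])
  }
  res
}
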