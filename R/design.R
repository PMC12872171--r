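#' Model terms for the marginal TRD model
#'
#' The fixed covariate layout of the two-year marginal model: an intercept,
#' the four high-prevalence indicators, suburban/rural contrasts against
#' urban, and the poverty-by-children product term, each entering with a
#' separate coefficient per year. An optional licensing indicator applies to
#' the later year only (no licensing policy existed at baseline).
#'
#' @param licensing logical; include the year-2022 licensing indicator.
#' @param interactions character vector of retained product terms, each
#'   written `"a:b"` over the flag columns (default the poverty-by-children
#'   term). May be empty.
#' @param main main-effect term list; override only for reduced diagnostic
#'   layouts (e.g. `"intercept"`), the default is the full study layout.
#' @return A list of class `trd_terms` with elements `main`, `interactions`,
#'   `terms` (full per-year term list) and `licensing`.
#' @export
trd_terms <- function(licensing = FALSE,
                      interactions = "high_poverty:high_children",
                      main = c("intercept", "high_aa", "high_hisp",
                               "suburban", "rural", "high_children",
                               "high_poverty")) {
  interactions <- as.character(interactions)
  structure(list(main = main,
                 interactions = interactions,
                 terms = c(main, interactions),
                 licensing = isTRUE(licensing)),
            class = "trd_terms")
}

#' @export
print.trd_terms <- function(x, ...) {
  cat("trd_terms:", length(x$terms), "terms per year",
      if (x$licensing) "+ licensing (2022 only)" else "", "\n")
  cat("  interactions:",
      if (length(x$interactions)) paste(x$interactions, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

term_column <- function(tab, term) {
  if (term == "intercept") return(rep(1, nrow(tab)))
  if (term == "suburban") return(as.numeric(tab$rurality == "suburban"))
  if (term == "rural") return(as.numeric(tab$rurality == "rural"))
  if (grepl(":", term, fixed = TRUE)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1L]]
    out <- rep(1, nrow(tab))
    for (p in parts) out <- out * term_column(tab, p)
    return(out)
  }
  if (!term %in% names(tab)) stop("missing flag column: ", term)
  as.numeric(tab[[term]])
}

#' Build the stacked two-year design
#'
#' Stacks the tract table time-major (all tracts in year 2017, then the same
#' tracts in the same order for 2022) and expands every model term into a
#' pair of year-specific columns (`<term>_2017`, `<term>_2022`), each active
#' only in its own year's rows. The offset is `log(population / 1000)`, so
#' coefficients live on the log retailers-per-1000 (log TRD) scale; the
#' response is the raw retailer count.
#'
#' @param table a tract table with both years per tract (see
#'   [read_tract_table()] for the column contract).
#' @param spec a [trd_terms()] layout.
#' @return A list with `X` (design matrix), `offset`, `y` (counts, `NULL` if
#'   absent), `tract_id`, `year`, and `spec`.
#' @export
build_design <- function(table, spec = trd_terms()) {
  stopifnot(inherits(spec, "trd_terms"))
  table <- check_tract_table(table, need_counts = FALSE)
  years <- sort(unique(table$year))
  if (length(years) != 2L) stop("table must contain exactly two years")
  t1 <- table[table$year == years[1L], , drop = FALSE]
  t2 <- table[table$year == years[2L], , drop = FALSE]
  t1 <- t1[order(t1$tract_id), , drop = FALSE]
  t2 <- t2[order(t2$tract_id), , drop = FALSE]
  if (!identical(t1$tract_id, t2$tract_id)) {
    stop("every tract must be present in both years")
  }
  n <- nrow(t1)
  blocks <- list(t1, t2)
  p_year <- length(spec$terms)
  ncols <- 2L * p_year + as.integer(spec$licensing)
  X <- matrix(0, 2L * n, ncols)
  cn <- c(paste0(spec$terms, "_", years[1L]),
          paste0(spec$terms, "_", years[2L]))
  for (b in 1:2) {
    rows <- seq_len(n) + (b - 1L) * n
    cols <- seq_len(p_year) + (b - 1L) * p_year
    for (j in seq_len(p_year)) {
      X[rows, cols[j]] <- term_column(blocks[[b]], spec$terms[j])
    }
  }
  if (spec$licensing) {
    if (!"licensing" %in% names(t2)) stop("missing flag column: licensing")
    X[n + seq_len(n), ncols] <- as.numeric(t2$licensing)
    cn <- c(cn, paste0("licensing_", years[2L]))
  }
  colnames(X) <- cn
  pop <- c(t1$population, t2$population)
  if (any(pop <= 0)) stop("populations must be positive (filter first)")
  y <- NULL
  if ("retailer_count" %in% names(table)) {
    y <- c(t1$retailer_count, t2$retailer_count)
  }
  list(X = X, offset = log(pop / 1000), y = y,
       tract_id = t1$tract_id, year = rep(years, each = n),
       years = years, n_tracts = n, spec = spec)
}

# Columns belonging to one term across the two years (+ licensing).
term_columns <- function(design, term) {
  if (term == "licensing") {
    return(grep("^licensing_", colnames(design$X)))
  }
  which(colnames(design$X) %in%
          paste0(term, "_", design$years))
}
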