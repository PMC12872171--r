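#' Sample spatially clustered tract covariates
#'
#' Draws the covariate layer of a synthetic tract system. Each dichotomous
#' flag (high African American, Hispanic, children, poverty) is obtained by
#' thresholding a graph-smoothed Gaussian field at its target quantile, so
#' neighboring tracts are positively associated and the empirical prevalence
#' matches the target to rounding. Rurality is cut from one further smoothed
#' field into urban / suburban / rural shares; populations are log-normal
#' around the configured median and identical across the two years.
#' Percentage columns consistent with the flags (and an NCHS level
#' consistent with rurality) are synthesized so the preparation rules can be
#' audited on generator output.
#'
#' @param n_tracts number of tracts; at most `lattice_rows * lattice_cols`
#'   (the lattice is truncated row-major when smaller).
#' @param config a [sim_config()].
#' @param graph optional [tract_graph()] with `n_tracts` nodes; by default
#'   the config lattice (truncated to `n_tracts`).
#' @return A list with `table` (tract-year data frame, both years, counts
#'   unset) and `graph`.
#' @export
sample_covariates <- function(n_tracts, config, graph = NULL) {
  validate_sim_config(config)
  if (n_tracts < 1) stop("n_tracts must be positive")
  if (is.null(graph)) {
    graph <- make_lattice(config$lattice_rows, config$lattice_cols)
    if (graph$n < n_tracts) {
      stop("lattice smaller than n_tracts; enlarge lattice_rows/lattice_cols")
    }
    if (graph$n > n_tracts) graph <- graph_subset(graph, seq_len(n_tracts))
  }
  if (graph$n != n_tracts) stop("graph must have n_tracts nodes")
  set.seed(config$seed)
  n <- graph$n
  W <- graph_adjacency(graph)
  d <- as.numeric(graph_degree(graph))
  smooth_field <- function() {
    z <- stats::rnorm(n)
    (z + as.numeric(W %*% z)) / (1 + d)
  }
  # top round(n * p) ranks of a smoothed field -> TRUE
  cut_top <- function(s, p) {
    k <- round(n * p)
    if (k <= 0) return(rep(FALSE, n))
    if (k >= n) return(rep(TRUE, n))
    rank(-s, ties.method = "first") <= k
  }
  pt <- config$prevalence_targets
  f_aa <- smooth_field(); f_hi <- smooth_field()
  f_ch <- smooth_field(); f_po <- smooth_field()
  f_ru <- smooth_field()
  high_aa <- cut_top(f_aa, pt[["high_aa"]])
  high_hisp <- cut_top(f_hi, pt[["high_hisp"]])
  high_children <- cut_top(f_ch, pt[["high_children"]])
  high_poverty <- cut_top(f_po, pt[["high_poverty"]])
  urban <- cut_top(f_ru, pt[["urban"]])
  rural <- cut_top(-f_ru, pt[["rural"]]) & !urban
  rurality <- factor(ifelse(urban, "urban",
                            ifelse(rural, "rural", "suburban")),
                     levels = c("urban", "suburban", "rural"))
  # percentages consistent with the flags: rank within group mapped into the
  # admissible interval for that side of the cutoff
  pct_from <- function(field, flag, cutoff, strict, cap = 90) {
    p <- numeric(n)
    hi <- which(flag); lo <- which(!flag)
    lo_top <- if (strict) cutoff else cutoff - 0.1
    hi_bot <- if (strict) cutoff + 0.01 else cutoff
    if (length(hi)) {
      r <- rank(field[hi], ties.method = "first") / (length(hi) + 1)
      p[hi] <- hi_bot + r * (cap - hi_bot)
    }
    if (length(lo)) {
      r <- rank(field[lo], ties.method = "first") / (length(lo) + 1)
      p[lo] <- r * lo_top
    }
    round(p, 2)
  }
  nchs <- integer(n)
  nchs[rurality == "urban"] <- 1L
  nchs[rurality == "suburban"] <- sample(2:3, sum(rurality == "suburban"),
                                         replace = TRUE)
  nchs[rurality == "rural"] <- sample(4:6, sum(rurality == "rural"),
                                      replace = TRUE)
  population <- pmax(1, round(stats::rlnorm(
    n, meanlog = log(config$population_median),
    sdlog = config$population_sdlog)))
  one_year <- data.frame(
    tract_id = graph$ids,
    population = population,
    pct_african_american = pct_from(f_aa, high_aa, 15, strict = FALSE),
    pct_hispanic = pct_from(f_hi, high_hisp, 15, strict = FALSE),
    pct_under18 = pct_from(f_ch, high_children, 25, strict = FALSE, cap = 60),
    pct_poverty = pct_from(f_po, high_poverty, 15.4, strict = TRUE),
    nchs_level = nchs,
    high_aa = high_aa, high_hisp = high_hisp,
    high_children = high_children, high_poverty = high_poverty,
    rurality = rurality,
    licensing = FALSE,
    stringsAsFactors = FALSE)
  table <- rbind(cbind(year = 2017L, one_year), cbind(year = 2022L, one_year))
  table <- table[, c("tract_id", "year",
                     setdiff(names(table), c("tract_id", "year")))]
  rownames(table) <- NULL
  list(table = table, graph = graph)
}

#' Grow contiguous licensing cities
#'
#' Flags a target fraction of tracts as covered by a local tobacco retailer
#' licensing policy, organized as `n_cities` contiguous patches grown from
#' random seeds in urban or suburban tracts (licensing localities were urban
#' and suburban; rural tracts are never flagged). Licensing applies to the
#' 2022 rows only: no local licensing policy existed at baseline. If the
#' target coverage cannot be reached within the urban/suburban tracts a
#' warning reports the achieved coverage.
#'
#' @param table tract table with rurality assigned (both years).
#' @param graph matching [tract_graph()].
#' @param config a [sim_config()]; uses `licensing_coverage` and `n_cities`.
#' @return The table with its `licensing` column set for the later year;
#'   the per-tract patch assignment is attached as attribute `city_id`
#'   (`NA` for unflagged tracts).
#' @export
assign_cities <- function(table, graph, config) {
  validate_sim_config(config)
  tab1 <- table[table$year == min(table$year), , drop = FALSE]
  tab1 <- tab1[match(graph$ids, tab1$tract_id), , drop = FALSE]
  if (anyNA(tab1$tract_id)) stop("graph ids must match table tracts")
  set.seed(config$seed + 2L)
  n <- graph$n
  eligible <- tab1$rurality %in% c("urban", "suburban")
  target <- round(config$licensing_coverage * n)
  city <- rep(NA_integer_, n)
  if (target > 0) {
    n_seeds <- min(config$n_cities, sum(eligible), target)
    if (n_seeds == 0L) {
      warning("no urban/suburban tracts available; achieved coverage 0")
    } else {
      nb <- graph_neighbors(graph)
      seeds <- sample(which(eligible), n_seeds)
      city[seeds] <- seq_len(n_seeds)
      frontier <- lapply(seq_len(n_seeds), function(k) {
        setdiff(nb[[seeds[k]]][eligible[nb[[seeds[k]]]]], seeds)
      })
      flagged <- n_seeds
      while (flagged < target) {
        grew <- FALSE
        for (k in seq_len(n_seeds)) {
          if (flagged >= target) break
          fr <- frontier[[k]]
          fr <- fr[is.na(city[fr])]
          if (!length(fr)) { frontier[[k]] <- fr; next }
          pick <- if (length(fr) == 1L) fr else sample(fr, 1L)
          city[pick] <- k
          flagged <- flagged + 1L
          grew <- TRUE
          newfr <- nb[[pick]]
          newfr <- newfr[eligible[newfr] & is.na(city[newfr])]
          frontier[[k]] <- unique(c(setdiff(fr, pick), newfr))
        }
        if (!grew) break
      }
      if (flagged < target) {
        warning(sprintf(
          "licensing coverage %.3f unreachable; achieved %.3f",
          config$licensing_coverage, flagged / n))
      }
    }
  }
  lic_tracts <- graph$ids[!is.na(city)]
  table$licensing <- table$year == max(table$year) &
    table$tract_id %in% lic_tracts
  attr(table, "city_id") <- stats::setNames(city, graph$ids)
  table
}

#' Simulate retailer counts with NB margins and CAR x AR correlation
#'
#' Fills retailer counts for both years via a Gaussian copula: a zero-mean
#' Gaussian vector with separable correlation `R_AR(phi) %x% R_space(gamma)`
#' is drawn, pushed through the standard normal CDF, and each margin is
#' inverted through the negative-binomial CDF with mean
#' `mu = (population/1000) * exp(x' beta_year)` and variance
#' `mu (1 + alpha mu)`. At `alpha = 0` the margin degenerates continuously
#' to Poisson.
#'
#' @param table tract table with covariates (and licensing, if the config's
#'   `beta_2022` carries a licensing effect) for both years.
#' @param graph matching [tract_graph()].
#' @param config a [sim_config()].
#' @param struct optional precomputed `car_setup(graph)` to reuse across
#'   replicates.
#' @return The table with `retailer_count` filled; the latent Gaussian
#'   vector is attached as attribute `latent` (design order: baseline year
#'   first) for diagnostics.
#' @export
simulate_counts <- function(table, graph, config, struct = NULL) {
  validate_sim_config(config)
  if (abs(config$gamma_spatial) >= 1 || abs(config$phi_temporal) >= 1) {
    stop("singular correlation: |gamma| and |phi| must be < 1")
  }
  lic_effect <- "licensing" %in% names(config$beta_2022)
  spec <- trd_terms(licensing = lic_effect)
  des <- build_design(table, spec)
  if (!setequal(des$tract_id, graph$ids) || des$n_tracts != graph$n) {
    stop("graph nodes must match table tracts")
  }
  ord <- match(des$tract_id, graph$ids)
  beta <- c(config$beta_2017, config$beta_2022)
  mu <- exp(des$offset + as.numeric(des$X %*% beta))
  set.seed(config$seed + 1L)
  n <- graph$n
  if (config$gamma_spatial == 0) {
    Z <- matrix(stats::rnorm(2L * n), n, 2L)
  } else {
    if (is.null(struct)) struct <- car_setup(graph)
    Z <- car_sample(struct, config$gamma_spatial, 2L)
  }
  Z <- Z[ord, , drop = FALSE]   # graph order -> design (sorted id) order
  phi <- config$phi_temporal
  lat <- c(Z[, 1L], phi * Z[, 1L] + sqrt(1 - phi^2) * Z[, 2L])
  u <- pmin(pmax(stats::pnorm(lat), 1e-12), 1 - 1e-12)
  alpha <- config$dispersion
  counts <- if (alpha <= 1e-10) {
    stats::qpois(u, lambda = mu)
  } else {
    stats::qnbinom(u, size = 1 / alpha, mu = mu)
  }
  key <- paste(table$tract_id, table$year)
  dkey <- paste(rep(des$tract_id, 2L), des$year)
  table$retailer_count <- counts[match(key, dkey)]
  attr(table, "latent") <- lat
  attr(table, "mu") <- stats::setNames(mu, dkey)
  table
}

#' Generate a complete synthetic tract system
#'
#' Convenience wrapper chaining [sample_covariates()], [assign_cities()] and
#' [simulate_counts()]: one call yields an analysis-ready tract table with
#' covariates, licensing cities, and correlated negative-binomial retailer
#' counts, plus the adjacency graph. Fully reproducible from the config.
#'
#' @param config a [sim_config()].
#' @param n_tracts number of tracts (default: the full config lattice).
#' @param struct optional precomputed `car_setup` for the (possibly
#'   truncated) graph.
#' @return A list with `table`, `graph`, and `config`.
#' @export
simulate_state <- function(config, n_tracts = NULL, struct = NULL) {
  validate_sim_config(config)
  if (is.null(n_tracts)) n_tracts <- config$lattice_rows * config$lattice_cols
  cov <- sample_covariates(n_tracts, config)
  tab <- assign_cities(cov$table, cov$graph, config)
  tab <- simulate_counts(tab, cov$graph, config, struct = struct)
  list(table = tab, graph = cov$graph, config = config)
}
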