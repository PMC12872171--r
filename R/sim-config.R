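#' Synthetic-state configuration
#'
#' Bundles every knob of the synthetic tract-system generator: lattice
#' dimensions, target covariate prevalences, true year-specific regression
#' coefficients on the log-TRD scale, spatial (CAR) and temporal (AR)
#' correlation, negative-binomial overdispersion, licensing coverage, and a
#' seed. The defaults emulate the Ohio study frame: ~3149 tracts with median
#' population ~3535, published group prevalences, licensing covering 13.7%
#' of tracts in 13 clustered cities, and count means following the fitted
#' two-year marginal model.
#'
#' @param lattice_rows,lattice_cols lattice dimensions (rook contiguity).
#' @param prevalence_targets named fractions in `[0,1]` for
#'   `high_aa`, `high_hisp`, `high_children`, `high_poverty`,
#'   `urban`, `suburban`, `rural` (the last three must sum to 1).
#' @param beta_2017,beta_2022 named coefficient vectors on the log
#'   retailers-per-1000 scale, one entry per design term (see
#'   [trd_terms()]); `beta_2022` may carry an extra `licensing` entry.
#' @param gamma_spatial CAR dependence parameter, strictly in (-1, 1).
#' @param phi_temporal AR(1) cross-year correlation, strictly in (-1, 1).
#' @param dispersion nonnegative NB overdispersion alpha in
#'   `Var(Y) = mu (1 + alpha mu)`.
#' @param licensing_coverage target fraction of tracts licensed in the later
#'   year, in `[0,1]`.
#' @param n_cities number of contiguous licensing patches to grow.
#' @param population_median median tract population (log-normal draw).
#' @param population_sdlog log-scale standard deviation of population.
#' @param seed integer seed; every generator draw is reproducible from it.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(lattice_rows = 10, lattice_cols = 10, seed = 1)
#' @export
sim_config <- function(lattice_rows = 57L,
                       lattice_cols = 56L,
                       prevalence_targets = c(high_aa = 0.267,
                                              high_hisp = 0.041,
                                              high_children = 0.317,
                                              high_poverty = 0.429,
                                              urban = 0.310,
                                              suburban = 0.451,
                                              rural = 0.239),
                       beta_2017 = c(intercept = -0.244,
                                     high_aa = 0.138,
                                     high_hisp = 0.221,
                                     suburban = 0.070,
                                     rural = 0.264,
                                     high_children = -0.325,
                                     high_poverty = 0.443,
                                     "high_poverty:high_children" = 0.165),
                       beta_2022 = c(intercept = -0.233,
                                     high_aa = 0.101,
                                     high_hisp = 0.175,
                                     suburban = 0.092,
                                     rural = 0.306,
                                     high_children = -0.355,
                                     high_poverty = 0.376,
                                     "high_poverty:high_children" = 0.248),
                       gamma_spatial = 0.3,
                       phi_temporal = 0.4,
                       dispersion = 0.3,
                       licensing_coverage = 0.137,
                       n_cities = 13L,
                       population_median = 3535,
                       population_sdlog = 0.45,
                       seed = 1L) {
  cfg <- list(lattice_rows = as.integer(lattice_rows),
              lattice_cols = as.integer(lattice_cols),
              prevalence_targets = prevalence_targets,
              beta_2017 = beta_2017, beta_2022 = beta_2022,
              gamma_spatial = gamma_spatial, phi_temporal = phi_temporal,
              dispersion = dispersion,
              licensing_coverage = licensing_coverage,
              n_cities = as.integer(n_cities),
              population_median = population_median,
              population_sdlog = population_sdlog,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$lattice_rows < 1L || cfg$lattice_cols < 1L) {
    stop("lattice dimensions must be positive")
  }
  if (abs(cfg$gamma_spatial) >= 1 || abs(cfg$phi_temporal) >= 1) {
    stop("gamma_spatial and phi_temporal must lie strictly inside (-1, 1)")
  }
  pt <- cfg$prevalence_targets
  need <- c("high_aa", "high_hisp", "high_children", "high_poverty",
            "urban", "suburban", "rural")
  if (!all(need %in% names(pt))) {
    stop("prevalence_targets must name: ", paste(need, collapse = ", "))
  }
  if (any(pt < 0) || any(pt > 1)) {
    stop("prevalence targets must lie in [0, 1]")
  }
  rur <- sum(pt[c("urban", "suburban", "rural")])
  if (abs(rur - 1) > 1e-6) stop("urban + suburban + rural targets must sum to 1")
  if (cfg$licensing_coverage < 0 || cfg$licensing_coverage > 1) {
    stop("licensing_coverage must lie in [0, 1]")
  }
  if (cfg$dispersion < 0) stop("dispersion must be nonnegative")
  if (cfg$population_median <= 0) stop("population_median must be positive")
  terms <- names(cfg$beta_2017)
  need_terms <- trd_terms()$terms
  if (!identical(terms, need_terms)) {
    stop("beta_2017 must have one named entry per design term: ",
         paste(need_terms, collapse = ", "))
  }
  t22 <- names(cfg$beta_2022)
  if (!identical(t22, need_terms) &&
      !identical(t22, c(need_terms, "licensing"))) {
    stop("beta_2022 must match the design terms, optionally plus 'licensing'")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$lattice_rows, "x", x$lattice_cols, "lattice,",
      "gamma =", x$gamma_spatial, ", phi =", x$phi_temporal,
      ", alpha =", x$dispersion, "\n")
  cat("  licensing coverage", x$licensing_coverage, "in", x$n_cities,
      "cities; median population", x$population_median, "\n")
  invisible(x)
}
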