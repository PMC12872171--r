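test_that("rook lattice has the expected nodes, edges, and symmetry", {
  cases <- list(c(1, 1, 0), c(2, 2, 4), c(3, 3, 12), c(4, 7, 45))
  for (cs in cases) {
    g <- make_lattice(cs[1], cs[2])
    expect_equal(g$n, cs[1] * cs[2])
    expect_equal(nrow(g$edges), 2 * cs[1] * cs[2] - cs[1] - cs[2])
    expect_true(all(g$edges[, 1] < g$edges[, 2]))     # no self-loops
  }
  # enumeration oracle for 3x3: all cell pairs at Manhattan distance 1
  g <- make_lattice(3, 3)
  coords <- expand.grid(col = 1:3, row = 1:3)
  manh <- as.matrix(dist(coords[, c("row", "col")], method = "manhattan"))
  expect_equal(sum(manh == 1) / 2, nrow(g$edges))
  expect_error(make_lattice(0, 3), "positive")
  expect_error(make_lattice(2, -1), "positive")
})

test_that("covariate prevalences hit their targets and cluster spatially", {
  cfg <- sim_config(seed = 42)
  cov <- sample_covariates(3149, cfg)
  t1 <- cov$table[cov$table$year == 2017, ]
  expect_equal(nrow(t1), 3149)
  pt <- cfg$prevalence_targets
  for (flag in c("high_aa", "high_hisp", "high_children", "high_poverty")) {
    expect_lt(abs(mean(t1[[flag]]) - pt[[flag]]), 0.02)
  }
  rur <- prop.table(table(t1$rurality))
  expect_lt(abs(rur[["urban"]] - pt[["urban"]]), 0.02)
  expect_lt(abs(rur[["suburban"]] - pt[["suburban"]]), 0.02)
  expect_lt(abs(rur[["rural"]] - pt[["rural"]]), 0.02)
  # neighbors positively associated: Moran's I of each flag clearly positive
  for (flag in c("high_aa", "high_poverty")) {
    expect_gt(moran_i(as.numeric(t1[[flag]]), cov$graph), 0.2)
  }
  # populations around the configured median
  expect_lt(abs(median(t1$population) / cfg$population_median - 1), 0.05)
})

test_that("zero prevalence targets yield all-low flags", {
  cfg <- sim_config(lattice_rows = 8, lattice_cols = 8, seed = 5,
                    prevalence_targets = c(high_aa = 0, high_hisp = 0,
                                           high_children = 0,
                                           high_poverty = 0, urban = 0.3,
                                           suburban = 0.5, rural = 0.2))
  t1 <- sample_covariates(64, cfg)$table
  expect_false(any(t1$high_aa | t1$high_hisp | t1$high_children |
                     t1$high_poverty))
})

test_that("generator output is reproducible from (config, seed)", {
  a <- simulate_state(sim_config(lattice_rows = 8, lattice_cols = 9,
                                 seed = 99))
  b <- simulate_state(sim_config(lattice_rows = 8, lattice_cols = 9,
                                 seed = 99))
  expect_identical(a$table, b$table)
  c2 <- simulate_state(sim_config(lattice_rows = 8, lattice_cols = 9,
                                  seed = 100))
  expect_false(identical(a$table$retailer_count, c2$table$retailer_count))
})

test_that("degenerate copula (alpha=gamma=phi=0) gives independent Poisson", {
  cfg <- sim_config(lattice_rows = 100, lattice_cols = 100, seed = 21,
                    gamma_spatial = 0, phi_temporal = 0, dispersion = 0,
                    population_median = 1000, population_sdlog = 0,
                    prevalence_targets = c(high_aa = 0, high_hisp = 0,
                                           high_children = 0,
                                           high_poverty = 0, urban = 1,
                                           suburban = 0, rural = 0),
                    beta_2017 = replace(sim_config()$beta_2017, 1:8, 0),
                    beta_2022 = replace(sim_config()$beta_2022, 1:8, 0))
  st <- simulate_state(cfg)
  y <- st$table$retailer_count[st$table$year == 2017]
  expect_lt(abs(mean(y) - 1), 3 / sqrt(length(y)))       # 3 MC SEs of 1
  expect_lt(abs(var(y) - 1), 5 / sqrt(length(y)))
  # cross-year counts essentially uncorrelated
  y2 <- st$table$retailer_count[st$table$year == 2022]
  expect_lt(abs(cor(y, y2)), 0.03)
})

test_that("copula temporal correlation matches its specification", {
  cfg <- sim_config(lattice_rows = 100, lattice_cols = 50, seed = 31,
                    gamma_spatial = 0, phi_temporal = 0.6, dispersion = 0)
  st <- simulate_state(cfg)
  lat <- attr(st$table, "latent")
  n <- st$graph$n
  expect_equal(length(lat), 2 * n)
  expect_lt(abs(cor(lat[1:n], lat[n + 1:n]) - 0.6), 0.05)
})

test_that("count moments follow mu and mu(1 + alpha mu)", {
  cfg <- sim_config(lattice_rows = 100, lattice_cols = 100, seed = 13,
                    gamma_spatial = 0, phi_temporal = 0, dispersion = 0.4)
  st <- simulate_state(cfg)
  key <- paste(st$table$tract_id, st$table$year)
  mu <- attr(st$table, "mu")[key]
  y <- st$table$retailer_count
  expect_lt(abs(sum(y) / sum(mu) - 1), 0.02)
  z <- (y - mu) / sqrt(mu * (1 + cfg$dispersion * mu))
  expect_lt(abs(mean(z^2) - 1), 0.05)
})

test_that("residual Moran's I increases with the CAR dependence", {
  g <- make_lattice(20, 20)
  stc <- trdcar:::car_setup(g)
  mean_moran <- function(gamma) {
    vals <- vapply(1:20, function(r) {
      cfg <- sim_config(lattice_rows = 20, lattice_cols = 20,
                        seed = 1000 + r, gamma_spatial = gamma,
                        phi_temporal = 0, dispersion = 0.2)
      st <- simulate_state(cfg, struct = stc)
      t1 <- st$table$year == 2017
      key <- paste(st$table$tract_id[t1], 2017)
      mu <- attr(st$table, "mu")[key]
      pear <- (st$table$retailer_count[t1] - mu) / sqrt(mu)
      ord <- match(st$graph$ids, st$table$tract_id[t1])
      moran_i(pear[ord], st$graph)
    }, numeric(1))
    mean(vals)
  }
  m <- vapply(c(0, 0.3, 0.6), mean_moran, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("licensing cities are contiguous, urban/suburban, calibrated", {
  cfg <- sim_config(seed = 8)
  st <- sample_covariates(3149, cfg)
  tab <- assign_cities(st$table, st$graph, cfg)
  lic22 <- tab$licensing[tab$year == 2022]
  frac <- mean(lic22)
  expect_gte(frac, 0.122); expect_lte(frac, 0.152)
  expect_false(any(tab$licensing[tab$year == 2017]))
  t1 <- tab[tab$year == 2017, ]
  lic_ids <- tab$tract_id[tab$year == 2022 & tab$licensing]
  expect_false(any(t1$rurality[t1$tract_id %in% lic_ids] == "rural"))
  # each city patch is connected in the graph
  city <- attr(tab, "city_id")
  nb <- trdcar:::graph_neighbors(st$graph)
  for (k in unique(stats::na.omit(city))) {
    members <- which(!is.na(city) & city == k)
    seen <- members[1]; frontier <- members[1]
    while (length(frontier)) {
      nxt <- setdiff(intersect(unlist(nb[frontier]), members), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    expect_setequal(unname(seen), unname(members))
  }
})

test_that("licensing coverage degenerate cases behave", {
  cfg0 <- sim_config(lattice_rows = 8, lattice_cols = 8, seed = 3,
                     licensing_coverage = 0)
  st <- sample_covariates(64, cfg0)
  tab <- assign_cities(st$table, st$graph, cfg0)
  expect_false(any(tab$licensing))
  # full coverage is capped at the urban + suburban share, with a warning
  cfg1 <- sim_config(lattice_rows = 8, lattice_cols = 8, seed = 3,
                     licensing_coverage = 1, n_cities = 2L)
  expect_warning(tab1 <- assign_cities(st$table, st$graph, cfg1),
                 "unreachable")
  t1 <- tab1[tab1$year == 2017, ]
  achieved <- mean(tab1$licensing[tab1$year == 2022])
  expect_equal(achieved, mean(t1$rurality != "rural"))
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(gamma_spatial = 1), "inside")
  expect_error(sim_config(phi_temporal = -1.2), "inside")
  expect_error(sim_config(licensing_coverage = 1.3), "\\[0, 1\\]")
  expect_error(sim_config(prevalence_targets = c(high_aa = 1.4,
                                                 high_hisp = 0,
                                                 high_children = 0,
                                                 high_poverty = 0,
                                                 urban = 1, suburban = 0,
                                                 rural = 0)), "\\[0, 1\\]")
  expect_error(sim_config(beta_2017 = c(intercept = 0)), "design term")
})
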