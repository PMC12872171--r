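test_that("design stacking, year-specific columns, and offset convention", {
  tab <- toy_table(n = 3, population = c(1000, 2000, 500),
                   retailer_count = list(c(1, 2, 3), c(4, 5, 6)))
  tab$high_poverty <- rep(c(TRUE, FALSE, TRUE), 2)
  tab$high_children <- rep(c(TRUE, FALSE, FALSE), 2)
  d <- build_design(tab)
  expect_equal(nrow(d$X), 6)
  expect_equal(d$year, rep(c(2017, 2022), each = 3))
  # reference tract (urban, all low): only its year intercept column is set
  ref17 <- d$X[2, ]
  expect_equal(unname(ref17["intercept_2017"]), 1)
  expect_equal(sum(ref17 != 0), 1)
  # product term set exactly when both flags are set, in the row's year
  expect_equal(unname(d$X[1, "high_poverty:high_children_2017"]), 1)
  expect_equal(unname(d$X[3, "high_poverty:high_children_2017"]), 0)
  expect_equal(unname(d$X[4, "high_poverty:high_children_2022"]), 1)
  expect_equal(unname(d$X[1, "high_poverty:high_children_2022"]), 0)
  # offset log(pop/1000): 0 at 1000
  expect_equal(d$offset[1], 0)
  expect_equal(d$offset[2], log(2))
  expect_equal(d$y, c(1, 2, 3, 4, 5, 6))
  # 2017 columns are inactive in 2022 rows and vice versa
  expect_true(all(d$X[4:6, grep("_2017$", colnames(d$X))] == 0))
})

test_that("CAR correlation matches closed forms and dense inversion", {
  g2 <- make_lattice(1, 2)
  expect_equal(car_correlation(g2, 0), diag(2))
  expect_equal(car_correlation(g2, 0.5)[1, 2], 0.5)
  expect_equal(car_correlation(g2, -0.7)[2, 1], -0.7)
  # 3-node path at gamma = 0.5: oracle is direct inversion of Q = D - gW
  g3 <- make_lattice(1, 3)
  Q <- matrix(c(1, -0.5, 0, -0.5, 2, -0.5, 0, -0.5, 1), 3, 3)
  oracle <- cov2cor(solve(Q))
  R <- car_correlation(g3, 0.5)
  expect_equal(R, unname(oracle), tolerance = 1e-12)
  expect_equal(round(R[1, 2], 3), 0.378)
  expect_equal(round(R[1, 3], 3), 0.143)
  expect_error(car_correlation(g3, 1), "inside")
  # isolated node: unit variance, zero correlation
  giso <- tract_graph(c("a", "b", "c"), rbind(c(1, 2)))
  Riso <- car_correlation(giso, 0.6)
  expect_equal(Riso[3, 3], 1)
  expect_equal(Riso[1, 3], 0)
})

test_that("CAR correlation stays unit-diagonal positive definite", {
  for (dims in list(c(5, 8), c(20, 20), c(40, 40))) {
    g <- make_lattice(dims[1], dims[2])
    R <- car_correlation(g, 0.95)
    expect_equal(max(abs(diag(R) - 1)), 0)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("space-time correlation is the Kronecker AR x CAR product", {
  g <- make_lattice(2, 2)
  R <- car_correlation(g, 0.5)
  # phi = 0: block diagonal
  J0 <- spacetime_correlation(R, 0)
  expect_equal(J0[1:4, 5:8], matrix(0, 4, 4))
  expect_equal(J0[5:8, 5:8], R)
  # identity space: pure within-tract temporal correlation
  Ji <- spacetime_correlation(diag(3), 0.7)
  expect_equal(Ji[1, 4], 0.7)
  expect_equal(Ji[1, 5], 0)
  # entry product rule against the dense kronecker oracle
  g2 <- make_lattice(1, 2)
  R2 <- car_correlation(g2, 0.5)
  J <- spacetime_correlation(R2, 0.4)
  expect_equal(J, kronecker(matrix(c(1, .4, .4, 1), 2), R2))
  expect_equal(J[1, 4], 0.5 * 0.4)
  expect_error(spacetime_correlation(R2, 1.2), "inside")
  expect_error(spacetime_correlation(matrix(2, 2, 2), 0.2), "unit diagonal")
})

test_that("dispersion moment estimator: exact null, Poisson, recovery", {
  mu <- c(1, 2, 5, 0.5)
  expect_equal(estimate_dispersion(mu, mu), 0)
  set.seed(101)
  mu2 <- rep(exp(rnorm(100, 0.5, 0.4)), 100)
  y_pois <- rpois(length(mu2), mu2)
  expect_lt(abs(estimate_dispersion(y_pois, mu2, 2)), 0.02)
  y_nb <- rnbinom(length(mu2), size = 1 / 0.5, mu = mu2)
  expect_lt(abs(estimate_dispersion(y_nb, mu2, 2) - 0.5), 0.1)
  expect_error(estimate_dispersion(1, 0), "positive")
})

test_that("independence Poisson limit reproduces the IRLS oracle", {
  st <- tiny_state(seed = 3, rows = 15, cols = 15)
  fit <- fit_trd(st$table, st$graph, fix = list(gamma = 0, phi = 0,
                                                alpha = 0))
  d <- build_design(st$table)
  oracle <- glm.fit(d$X, d$y, offset = d$offset, family = poisson())
  expect_lt(max(abs(coef(fit) - oracle$coefficients)), 1e-8)
  expect_equal(fit$gamma_spatial, 0)
  expect_equal(fit$dispersion_alpha, 0)
})

test_that("intercept-only independence fit solves the score in closed form", {
  tab <- toy_table(n = 3, population = c(1000, 2000, 1000),
                   retailer_count = list(c(2, 0, 4), c(2, 0, 4)))
  g <- make_lattice(1, 3)
  spec <- trd_terms(main = "intercept", interactions = character(0))
  fit <- fit_trd(tab, g, spec, fix = list(gamma = 0, phi = 0, alpha = 0))
  expect_equal(unname(coef(fit)), rep(log(6 / 4), 2), tolerance = 1e-10)
})

test_that("Wald machinery: z arithmetic, joint tests, error handling", {
  w <- wald_z(0.138, 0.045)
  expect_equal(round(w$z, 2), 3.07)
  expect_true(w$significant)
  w2 <- wald_z(-0.104, 0.060)
  expect_equal(round(w2$z, 2), -1.73)
  expect_false(w2$significant)
  w0 <- wald_z(0, 0.1)
  expect_equal(w0$z, 0)
  expect_equal(w0$p_value, 1)
  expect_false(w0$significant)
  # wald_test on a fit agrees with wald_z for one coefficient
  st <- tiny_state(seed = 12, rows = 10, cols = 10)
  fit <- fit_trd(st$table, st$graph, fix = list(gamma = 0, phi = 0))
  j <- which(names(coef(fit)) == "high_poverty_2017")
  wt <- wald_test(fit, "high_poverty_2017")
  se <- sqrt(vcov(fit)[j, j])
  expect_equal(wt$z, unname(coef(fit)[j] / se), tolerance = 1e-12)
  expect_equal(wt$statistic, unname((coef(fit)[j] / se)^2),
               tolerance = 1e-12)
  # joint 2-df test has df 2 and nonnegative statistic
  wt2 <- wald_test(fit, c("high_poverty_2017", "high_poverty_2022"))
  expect_equal(wt2$df, 2)
  expect_gte(wt2$statistic, 0)
  expect_error(wald_test(fit, "nope_2017"), "unknown coefficient")
  expect_error(wald_test(fit, rbind(rep(1, 16), rep(1, 16))),
               "rank-deficient")
})

test_that("rate ratios exponentiate with 95% intervals", {
  rr <- rate_ratio(c(0.138, 0, 0.306), c(0.045, 0.1, 0.05))
  expect_equal(round(rr$rate_ratio, 2), c(1.15, 1.00, 1.36))
  expect_equal(rr$lower, exp(c(0.138, 0, 0.306) -
                               qnorm(0.975) * c(0.045, 0.1, 0.05)))
  expect_true(all(rr$lower <= rr$rate_ratio & rr$rate_ratio <= rr$upper))
  expect_error(rate_ratio(1, -0.1), "nonnegative")
})

test_that("group predictions: reference case, ordering, change flag", {
  st <- tiny_state(seed = 6, rows = 15, cols = 15)
  fit <- fit_trd(st$table, st$graph)
  # reference combo reduces to exp(intercept) with its own SE
  pr <- predict_groups(fit, data.frame(rurality = "urban"))
  i17 <- which(names(coef(fit)) == "intercept_2017")
  expect_equal(pr$predicted_trd[pr$year == 2017],
               exp(coef(fit)[[i17]]))
  se <- sqrt(vcov(fit)[i17, i17])
  expect_equal(pr$lower[pr$year == 2017],
               exp(coef(fit)[[i17]] - qnorm(0.975) * se))
  expect_true(all(pr$lower <= pr$predicted_trd &
                    pr$predicted_trd <= pr$upper))
  expect_true(all(pr$predicted_trd > 0))
  # poverty coefficient is positive in the generator: high-poverty combos
  # predict more retailers in both years
  pr2 <- predict_groups(fit, data.frame(high_poverty = c(FALSE, TRUE),
                                        rurality = "suburban"))
  for (y in c(2017, 2022)) {
    v <- pr2$predicted_trd[pr2$year == y]
    expect_gt(v[2], v[1])
  }
  expect_error(predict_groups(fit, data.frame(licensing = TRUE)),
               "no such term")
  expect_error(predict_groups(fit, data.frame(rurality = "exurban")),
               "unknown rurality")
  # predict method wraps predict_groups
  expect_equal(predict(fit)$predicted_trd, pr$predicted_trd)
})

test_that("backward elimination keeps the real interaction, drops the null", {
  cfg <- sim_config(lattice_rows = 30, lattice_cols = 30, seed = 14)
  st <- simulate_state(cfg)
  full <- trd_terms(interactions = c("high_poverty:high_children",
                                     "high_aa:high_children"))
  stc <- trdcar:::car_setup(st$graph)
  simplified <- simplify_model(st$table, st$graph, full, struct = stc)
  expect_equal(simplified$interactions, "high_poverty:high_children")
  tr <- attr(simplified, "trace")
  expect_equal(tr$dropped, "high_aa:high_children")
  # empty candidate set: spec unchanged
  none <- trd_terms(interactions = character(0))
  out <- simplify_model(st$table, st$graph, none, struct = stc)
  expect_equal(out$interactions, character(0))
})

test_that("fit recovers generating coefficients on one seeded replicate", {
  cfg <- sim_config(lattice_rows = 30, lattice_cols = 30, seed = 11)
  g <- make_lattice(30, 30)
  stc <- trdcar:::car_setup(g)
  st <- simulate_state(cfg, struct = stc)
  fit <- fit_trd(st$table, st$graph, struct = stc)
  expect_true(fit$converged)
  truth <- c(cfg$beta_2017, cfg$beta_2022)
  # all but the rare high-Hispanic indicator estimated tightly
  loose <- grep("high_hisp", names(truth))
  expect_lt(max(abs(coef(fit) - truth)[-loose]), 0.2)
  expect_lt(max(abs(coef(fit) - truth)), 0.35)
  # working parameters in their admissible ranges, spatial signal found
  expect_gt(fit$gamma_spatial, 0)
  expect_gt(fit$phi_temporal, 0)
  expect_gt(fit$dispersion_alpha, 0)
  expect_lt(abs(fit$gamma_spatial), 1)
  # covariance is symmetric positive semidefinite
  ev <- eigen(vcov(fit), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
})
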