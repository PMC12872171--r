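#' Moment estimator of NB overdispersion
#'
#' Estimates `alpha` in the quadratic negative-binomial variance
#' `Var(Y) = mu (1 + alpha mu)` by the moment equation
#' `alpha_hat = max(0, sum(((y - mu)^2 - mu) / mu^2) / (N - p))`,
#' floored at zero (Poisson).
#'
#' @param y observed counts.
#' @param mu fitted means (strictly positive).
#' @param n_params number of regression coefficients `p` consumed.
#' @return Nonnegative scalar `alpha` estimate.
#' @export
estimate_dispersion <- function(y, mu, n_params = 0L) {
  if (any(mu <= 0)) stop("means must be strictly positive")
  if (length(y) != length(mu)) stop("y and mu lengths differ")
  max(0, sum(((y - mu)^2 - mu) / mu^2) / (length(y) - n_params))
}

# Working-correlation application machinery. Vectors live in design order
# (sorted tract ids, baseline year first); `ord` maps design row -> graph
# node so the sparse spatial inverse (graph order) can be applied.
rinv_ops <- function(struct, gamma, phi, ord, n) {
  if (gamma == 0) {
    Rs_inv <- Matrix::Diagonal(n)
    logdet_s <- 0
  } else {
    ci <- car_corr_inv(struct, gamma)
    Rs_inv <- ci$Rinv
    logdet_s <- ci$logdetR
  }
  Ainv <- ar2_inv(phi)
  to_graph <- function(v) { g <- numeric(n); g[ord] <- v; g }
  apply_mat <- function(M) {         # M: n x 2, design order
    Mg <- matrix(0, n, 2L)
    Mg[ord, ] <- M
    Ng <- as.matrix(Rs_inv %*% Mg) %*% Ainv
    Ng[ord, , drop = FALSE]
  }
  list(
    logdet = 2 * logdet_s + n * log(1 - phi^2),
    quad = function(M) {             # t(vec(M)) R^{-1} vec(M)
      Mg <- matrix(0, n, 2L); Mg[ord, ] <- M
      sum(Ainv * crossprod(Mg, as.matrix(Rs_inv %*% Mg)))
    },
    apply = function(v) as.numeric(apply_mat(matrix(v, n, 2L))))
}

# Profiled Gaussian pseudo-log-likelihood of Pearson residuals, up to
# constants: -(log|R| + 2n log(r' R^{-1} r)) / 2; maximized over (gamma, phi).
estimate_correlation <- function(struct, resid_mat, ord, n, start = c(0, 0),
                                 bound = 0.99) {
  nll <- function(par) {
    ops <- rinv_ops(struct, par[1L], par[2L], ord, n)
    q <- ops$quad(resid_mat)
    if (!is.finite(q) || q <= 0) return(1e10)
    ops$logdet + 2 * n * log(q)
  }
  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(-bound, -bound), upper = c(bound, bound),
                      control = list(factr = 1e9))
  opt$par
}

#' Fit the marginal NB model with CAR x AR working correlation
#'
#' Fits tract-year retailer counts by iterated estimating equations under a
#' marginal specification: log-linear mean
#' `mu = (population/1000) exp(x' beta_year)` with year-specific
#' coefficients, quadratic NB variance `mu (1 + alpha mu)`, and separable
#' working correlation `R_AR(phi) %x% R_CAR(gamma)` over the two study
#' years and the tract adjacency graph. The scheme: (1) initialize `beta`
#' by an independence Poisson fit; (2) update `alpha` by moments and
#' `(gamma, phi)` by maximizing the profiled Gaussian pseudo-likelihood of
#' the Pearson residuals over a bounded square; (3) update `beta` by Fisher
#' scoring on the weighted estimating equation with working covariance
#' `V = A^{1/2} R A^{1/2}`, `A = diag(mu (1 + alpha mu))`; repeat until the
#' relative change in `beta` falls below `tol`.
#'
#' The default coefficient covariance is `scale * H^{-1}` with
#' `H = D' V^{-1} D` and the profiled Pearson scale; with the whole state a
#' single correlated cluster this is the robust form with the
#' moment-estimated structured covariance as middle matrix (see the methods
#' vignette). `cov_type = "model"` drops the scale factor.
#'
#' @param table filtered tract table with counts, both years per tract.
#' @param graph [tract_graph()] over the same tracts.
#' @param spec a [trd_terms()] layout (set `licensing = TRUE` for the
#'   licensing model).
#' @param fix optional named list fixing any of `gamma`, `phi`, `alpha`
#'   instead of estimating them (e.g. `list(gamma = 0, phi = 0, alpha = 0)`
#'   for an independence Poisson fit).
#' @param cov_type `"robust"` (scaled, default) or `"model"`.
#' @param tol relative beta-change convergence tolerance.
#' @param max_iter maximum outer iterations.
#' @param struct optional precomputed `car_setup(graph)` to reuse across
#'   fits on the same graph.
#' @return An object of class `trd_fit`.
#' @seealso [summary.trd_fit()], [predict.trd_fit()], [wald_test()],
#'   [rate_ratio()], [simplify_model()]
#' @export
fit_trd <- function(table, graph, spec = trd_terms(), fix = list(),
                    cov_type = c("robust", "model"),
                    tol = 1e-6, max_iter = 100L, struct = NULL) {
  cov_type <- match.arg(cov_type)
  stopifnot(inherits(graph, "tract_graph"))
  des <- build_design(table, spec)
  if (is.null(des$y)) stop("table must carry retailer counts")
  if (!setequal(des$tract_id, graph$ids) || des$n_tracts != graph$n) {
    stop("graph nodes must match table tracts")
  }
  n <- graph$n
  ord <- match(des$tract_id, graph$ids)
  X <- des$X; y <- des$y; off <- des$offset
  p <- ncol(X)

  fix_gamma <- fix$gamma; fix_phi <- fix$phi; fix_alpha <- fix$alpha
  for (v in c(fix_gamma, fix_phi)) {
    if (!is.null(v) && abs(v) >= 1) stop("fixed |gamma|, |phi| must be < 1")
  }
  need_struct <- is.null(fix_gamma) || fix_gamma != 0
  if (need_struct && is.null(struct)) struct <- car_setup(graph)

  beta <- stats::glm.fit(X, y, offset = off,
                         family = stats::poisson())$coefficients
  if (anyNA(beta)) stop("singular design: ",
                        paste(colnames(X)[is.na(beta)], collapse = ", "))
  alpha <- if (is.null(fix_alpha)) 0 else fix_alpha
  gamma <- if (is.null(fix_gamma)) 0 else fix_gamma
  phi <- if (is.null(fix_phi)) 0 else fix_phi
  est_corr <- is.null(fix_gamma) || is.null(fix_phi)

  converged <- FALSE
  iter <- 0L
  H <- NULL; scale <- 1
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- exp(off + as.numeric(X %*% beta))
    if (is.null(fix_alpha)) alpha <- estimate_dispersion(y, mu, p)
    a <- mu * (1 + alpha * mu)
    r <- (y - mu) / sqrt(a)
    if (est_corr) {
      par <- estimate_correlation(struct, matrix(r, n, 2L), ord, n,
                                  start = c(gamma, phi))
      if (is.null(fix_gamma)) gamma <- par[1L]
      if (is.null(fix_phi)) phi <- par[2L]
    }
    ops <- rinv_ops(if (gamma == 0) NULL else struct, gamma, phi, ord, n)
    sa <- sqrt(a)
    vinv_apply <- function(v) ops$apply(v / sa) / sa
    D <- mu * X
    VD <- vapply(seq_len(p), function(j) vinv_apply(D[, j]),
                 numeric(2L * n))
    H <- crossprod(D, VD)
    u <- as.numeric(crossprod(VD, y - mu))
    step <- tryCatch(solve(H, u), error = function(e)
      stop("singular working covariance in the beta update: ",
           conditionMessage(e)))
    beta_new <- beta + step
    rel <- max(abs(beta_new - beta)) / max(1, max(abs(beta)))
    beta <- beta_new
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("estimating equations did not converge in ",
                          max_iter, " iterations")
  mu <- exp(off + as.numeric(X %*% beta))
  a <- mu * (1 + alpha * mu)
  r <- (y - mu) / sqrt(a)
  ops <- rinv_ops(if (gamma == 0) NULL else struct, gamma, phi, ord, n)
  scale <- ops$quad(matrix(r, n, 2L)) / (2 * n - p)
  Hinv <- solve(H)
  vc <- if (cov_type == "robust") scale * Hinv else Hinv
  vc <- (vc + t(vc)) / 2
  dimnames(vc) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  p_year <- length(spec$terms)
  out <- list(coefficients = beta,
              beta_2017 = beta[seq_len(p_year)],
              beta_2022 = beta[p_year + seq_len(p - p_year)],
              vcov = vc,
              dispersion_alpha = alpha,
              gamma_spatial = gamma,
              phi_temporal = phi,
              scale = scale,
              cov_type = cov_type,
              fixed = fix,
              n_iterations = iter,
              converged = converged,
              fitted = mu,
              residuals_pearson = r,
              y = y, offset = off,
              design = list(colnames = colnames(X), years = des$years,
                            spec = spec, n_tracts = n,
                            tract_id = des$tract_id, year = des$year),
              call = match.call())
  class(out) <- "trd_fit"
  out
}

#' @export
print.trd_fit <- function(x, digits = 3, ...) {
  cat("Marginal NB model with CAR x AR working correlation\n")
  cat(sprintf("  %d tracts x 2 years; %s after %d iterations\n",
              x$design$n_tracts,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  cat(sprintf("  alpha = %.3f, gamma = %.3f, phi = %.3f, scale = %.3f\n",
              x$dispersion_alpha, x$gamma_spatial, x$phi_temporal, x$scale))
  cat("Coefficients (log TRD-per-1000 scale):\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.trd_fit <- function(object, ...) object$coefficients

#' @export
vcov.trd_fit <- function(object, ...) object$vcov

#' @export
fitted.trd_fit <- function(object, ...) object$fitted

#' @export
residuals.trd_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  if (type == "pearson") object$residuals_pearson
  else object$y - object$fitted
}

#' Coefficient table for a fitted marginal TRD model
#'
#' Per-term, per-year coefficients with standard errors, Wald z, p-values
#' and 0.05 significance flags, plus the correlation and dispersion
#' estimates — the shape of a published parameter-estimate table.
#'
#' @param object a [fit_trd()] result.
#' @param ... unused.
#' @return An object of class `summary.trd_fit` with a `coefficients`
#'   data frame (`term`, `year`, `estimate`, `se`, `z`, `p_value`,
#'   `significant`).
#' @export
summary.trd_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  cn <- object$design$colnames
  term <- sub("_(\\d{4})$", "", cn)
  year <- as.integer(sub("^.*_(\\d{4})$", "\\1", cn))
  z <- object$coefficients / se
  tab <- data.frame(term = term, year = year,
                    estimate = unname(object$coefficients),
                    se = unname(se), z = unname(z),
                    p_value = unname(2 * stats::pnorm(-abs(z))),
                    significant = unname(abs(z) > stats::qnorm(0.975)))
  out <- list(coefficients = tab,
              dispersion_alpha = object$dispersion_alpha,
              gamma_spatial = object$gamma_spatial,
              phi_temporal = object$phi_temporal,
              scale = object$scale,
              converged = object$converged,
              n_iterations = object$n_iterations,
              n_tracts = object$design$n_tracts)
  class(out) <- "summary.trd_fit"
  out
}

#' @export
print.summary.trd_fit <- function(x, digits = 3, ...) {
  cat("Marginal NB model: parameter estimates by year\n")
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$z <- round(tab$z, 2)
  tab$p_value <- signif(tab$p_value, 2)
  print(tab, row.names = FALSE)
  cat(sprintf(
    "alpha = %.3f, gamma = %.3f, phi = %.3f (n = %d tracts, %s)\n",
    x$dispersion_alpha, x$gamma_spatial, x$phi_temporal, x$n_tracts,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}
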