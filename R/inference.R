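#' Wald tests on fitted coefficients
#'
#' Tests `C beta = 0` with `C` a contrast matrix (or single vector, or a
#' character vector of coefficient names for a joint test of those
#' coefficients): statistic `(C beta)' (C Cov C')^{-1} (C beta)`, referred
#' to a chi-square with `nrow(C)` degrees of freedom. The single-df case
#' also reports `z = estimate / SE`.
#'
#' @param fit a [fit_trd()] result.
#' @param contrast numeric vector (one contrast), numeric matrix (rows are
#'   contrasts), or character names of coefficients.
#' @param level significance level (default 0.05).
#' @return List of class `trd_wald`: `statistic`, `df`, `p_value`,
#'   `significant`, and `z` when `df == 1`.
#' @export
wald_test <- function(fit, contrast, level = 0.05) {
  stopifnot(inherits(fit, "trd_fit"))
  beta <- fit$coefficients
  if (is.character(contrast)) {
    idx <- match(contrast, names(beta))
    if (anyNA(idx)) stop("unknown coefficient name(s): ",
                         paste(contrast[is.na(idx)], collapse = ", "))
    C <- matrix(0, length(idx), length(beta))
    C[cbind(seq_along(idx), idx)] <- 1
  } else if (is.null(dim(contrast))) {
    C <- matrix(contrast, nrow = 1L)
  } else C <- as.matrix(contrast)
  if (ncol(C) != length(beta)) stop("contrast dimension mismatch")
  cb <- as.numeric(C %*% beta)
  V <- C %*% fit$vcov %*% t(C)
  Vi <- tryCatch(solve(V), error = function(e)
    stop("rank-deficient contrast covariance"))
  stat <- as.numeric(t(cb) %*% Vi %*% cb)
  df <- nrow(C)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  out <- list(statistic = stat, df = df, p_value = p,
              significant = p < level)
  if (df == 1L) out$z <- cb / sqrt(V[1L, 1L])
  class(out) <- "trd_wald"
  out
}

#' @export
print.trd_wald <- function(x, ...) {
  cat(sprintf("Wald chi-square = %.3f on %d df, p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Wald z from an estimate and standard error
#'
#' Convenience for auditing printed coefficient tables: `z = estimate / se`,
#' two-sided normal p-value, significance at `level`.
#'
#' @param estimate,se coefficient estimate and its standard error
#'   (`se >= 0`).
#' @param level significance level (default 0.05).
#' @return Data frame with `z`, `p_value`, `significant` (vectorized).
#' @examples
#' wald_z(0.138, 0.045) # z = 3.07, significant
#' @export
wald_z <- function(estimate, se, level = 0.05) {
  if (any(se < 0)) stop("se must be nonnegative")
  z <- ifelse(estimate == 0, 0, estimate / se)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(z = z, p_value = p,
             significant = abs(z) > stats::qnorm(1 - level / 2))
}

#' Rate ratios from log-scale coefficients
#'
#' Exponentiates a coefficient on the log TRD scale into a multiplicative
#' rate ratio with a 95% Wald interval, `exp(estimate +/- 1.96 se)`.
#' Conventionally reported to 2 decimals; values are returned unrounded.
#'
#' @param coefficient log-scale estimate(s).
#' @param se standard error(s), `>= 0` (0 gives a degenerate interval).
#' @return Data frame with `rate_ratio`, `lower`, `upper`.
#' @examples
#' round(rate_ratio(0.138, 0.045)$rate_ratio, 2) # 1.15
#' @export
rate_ratio <- function(coefficient, se = 0) {
  if (any(se < 0)) stop("se must be nonnegative")
  zc <- stats::qnorm(0.975)
  data.frame(rate_ratio = exp(coefficient),
             lower = exp(coefficient - zc * se),
             upper = exp(coefficient + zc * se))
}

#' Backward elimination of interaction terms
#'
#' Simplifies the candidate interaction set by backward elimination: fit the
#' model with all candidates, Wald-test each interaction jointly across its
#' two year-specific columns (2 df), drop the least significant candidate
#' whose p-value exceeds `level` (ties broken by term name), refit, and
#' repeat until every retained interaction is significant. Main effects are
#' never dropped.
#'
#' @param table,graph as in [fit_trd()].
#' @param full_spec a [trd_terms()] whose `interactions` lists candidates.
#' @param level retention threshold (default 0.05).
#' @param ... passed to [fit_trd()] (e.g. `fix`, `struct`).
#' @return The simplified [trd_terms()]; the elimination trace (term,
#'   p-value per step) is attached as attribute `trace`.
#' @export
simplify_model <- function(table, graph, full_spec = trd_terms(),
                           level = 0.05, ...) {
  stopifnot(inherits(full_spec, "trd_terms"))
  current <- sort(full_spec$interactions)
  trace <- data.frame(dropped = character(0), p_value = numeric(0))
  repeat {
    if (!length(current)) break
    spec <- trd_terms(licensing = full_spec$licensing,
                      interactions = current)
    fit <- fit_trd(table, graph, spec, ...)
    pvals <- vapply(current, function(term) {
      cols <- paste0(term, "_", fit$design$years)
      wald_test(fit, cols)$p_value
    }, numeric(1))
    worst <- which(pvals > level)
    if (!length(worst)) break
    drop_idx <- worst[which.max(pvals[worst])]
    trace <- rbind(trace, data.frame(dropped = current[drop_idx],
                                     p_value = pvals[drop_idx]))
    current <- current[-drop_idx]
  }
  out <- trd_terms(licensing = full_spec$licensing, interactions = current)
  attr(out, "trace") <- trace
  out
}

# design row (one year) for one covariate combination
combo_x <- function(combo, spec, year, years, colnames_all) {
  tab <- data.frame(high_aa = as.logical(combo$high_aa %||% FALSE),
                    high_hisp = as.logical(combo$high_hisp %||% FALSE),
                    high_children = as.logical(combo$high_children %||% FALSE),
                    high_poverty = as.logical(combo$high_poverty %||% FALSE),
                    rurality = as.character(combo$rurality %||% "urban"))
  if (!tab$rurality %in% c("urban", "suburban", "rural")) {
    stop("unknown rurality level: ", tab$rurality)
  }
  x <- stats::setNames(numeric(length(colnames_all)), colnames_all)
  for (term in spec$terms) {
    x[paste0(term, "_", year)] <- term_column(tab, term)
  }
  if (spec$licensing && year == max(years)) {
    lic <- as.logical(combo$licensing %||% FALSE)
    x[paste0("licensing_", year)] <- as.numeric(lic)
  } else if (!spec$licensing && isTRUE(as.logical(combo$licensing))) {
    stop("combo requests licensing but the fitted model has no such term")
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Model-predicted TRD for covariate combinations
#'
#' Predicted TRD (retailers per 1000, i.e. `exp(x' beta_year)` at the
#' reference population offset) for each covariate combination and year,
#' with 95% delta-method intervals on the log scale, and a Wald flag for
#' whether the tract type's change between the two years is significant
#' (using the joint coefficient covariance).
#'
#' @param fit a [fit_trd()] result.
#' @param combos data frame, one row per combination; recognised columns
#'   `high_aa`, `high_hisp`, `high_children`, `high_poverty`, `rurality`,
#'   `licensing` (missing columns default to the reference level).
#' @return Data frame with one row per combination x year: `year`,
#'   `predicted_trd`, `lower`, `upper`, `change_significant`.
#' @export
predict_groups <- function(fit, combos) {
  stopifnot(inherits(fit, "trd_fit"), is.data.frame(combos))
  spec <- fit$design$spec
  years <- fit$design$years
  cn <- fit$design$colnames
  zc <- stats::qnorm(0.975)
  out <- list()
  for (i in seq_len(nrow(combos))) {
    combo <- combos[i, , drop = FALSE]
    xs <- lapply(years, function(y) combo_x(combo, spec, y, years, cn))
    d <- xs[[2L]] - xs[[1L]]
    vd <- as.numeric(t(d) %*% fit$vcov %*% d)
    chg <- if (vd <= 0) FALSE else {
      abs(sum(d * fit$coefficients) / sqrt(vd)) > zc
    }
    for (k in seq_along(years)) {
      x <- xs[[k]]
      eta <- sum(x * fit$coefficients)
      se <- sqrt(as.numeric(t(x) %*% fit$vcov %*% x))
      out[[length(out) + 1L]] <- cbind(
        combo, data.frame(year = years[k],
                          predicted_trd = exp(eta),
                          lower = exp(eta - zc * se),
                          upper = exp(eta + zc * se),
                          change_significant = chg))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @describeIn predict_groups `predict` method; `newdata` is the combos
#'   data frame (default: the reference combination).
#' @param object a `trd_fit`.
#' @param newdata combos data frame.
#' @param ... unused.
#' @export
predict.trd_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- data.frame(rurality = "urban")
  predict_groups(object, newdata)
}

#' Plot model-predicted group TRD
#'
#' Dumbbell-style base-graphics display of [predict_groups()] output: one
#' line per covariate combination across the two years with 95% error bars;
#' combinations with a significant between-year change are drawn in black,
#' others in grey.
#'
#' @param x a `trd_fit`.
#' @param combos combos data frame (default: the eight poverty x
#'   race/ethnicity x licensing profiles at low prevalence of children).
#' @param ... passed to `plot`.
#' @export
plot.trd_fit <- function(x, combos = NULL, ...) {
  if (is.null(combos)) {
    combos <- expand.grid(high_poverty = c(FALSE, TRUE),
                          high_aa = c(FALSE, TRUE),
                          licensing = if (x$design$spec$licensing)
                            c(FALSE, TRUE) else FALSE)
    combos$high_hisp <- combos$high_aa
    combos$rurality <- "suburban"
  }
  pr <- predict_groups(x, combos)
  years <- sort(unique(pr$year))
  ng <- nrow(pr) / 2L
  xpos <- rep(seq_len(ng), each = 2L) + rep(c(-0.15, 0.15), ng)
  ord <- order(rep(seq_len(ng), each = 2L), pr$year)
  pr <- pr[ord, ]
  graphics::plot(xpos, pr$predicted_trd,
                 ylim = range(pr$lower, pr$upper),
                 xlab = "covariate combination", xaxt = "n",
                 ylab = "predicted TRD (retailers per 1000)",
                 pch = 19, col = ifelse(pr$change_significant,
                                        "black", "grey50"), ...)
  graphics::axis(1, at = seq_len(ng), labels = seq_len(ng))
  graphics::arrows(xpos, pr$lower, xpos, pr$upper, angle = 90, code = 3,
                   length = 0.03,
                   col = ifelse(pr$change_significant, "black", "grey50"))
  for (g in seq_len(ng)) {
    idx <- (2L * g - 1L):(2L * g)
    graphics::lines(xpos[idx], pr$predicted_trd[idx],
                    col = if (pr$change_significant[idx[1L]]) "black"
                    else "grey50")
  }
  invisible(pr)
}
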