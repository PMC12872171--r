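#' CAR spatial correlation over a tract graph
#'
#' Builds the proper conditional-autoregressive correlation matrix implied by
#' the precision `Q = D - gamma * W`, where `W` is the 0/1 adjacency of the
#' tract graph and `D` its diagonal degree matrix, then rescales the inverse
#' to unit diagonal. `Q` is positive definite for all `|gamma| < 1`; isolated
#' tracts (degree 0) get unit variance and zero correlation with the rest.
#'
#' @param graph a [tract_graph()].
#' @param gamma CAR dependence parameter, strictly in (-1, 1).
#' @return A dense symmetric correlation matrix (`n` by `n`, unit diagonal).
#' @examples
#' g <- make_lattice(1, 2)
#' car_correlation(g, 0.5)[1, 2] # exactly 0.5 for a single-edge pair
#' @export
car_correlation <- function(graph, gamma) {
  stopifnot(inherits(graph, "tract_graph"))
  if (length(gamma) != 1L || !is.finite(gamma) || abs(gamma) >= 1) {
    stop("gamma must lie strictly inside (-1, 1)")
  }
  st <- car_setup(graph)
  v <- car_diag_inv(st, gamma)          # diag of Q^{-1}
  Qi <- car_inverse(st, gamma)          # dense Q^{-1}
  s <- 1 / sqrt(v)
  R <- Qi * tcrossprod(s)
  diag(R) <- 1
  (R + t(R)) / 2
}

# Spectral machinery for the CAR family on a fixed graph. Degree-0 nodes are
# given unit self-precision so Q stays invertible; they decouple exactly.
# With B = D^{-1/2} W D^{-1/2} = U diag(lam) U', we have
#   Q(gamma)^{-1} = D^{-1/2} U diag(1/(1 - gamma*lam)) U' D^{-1/2},
# so the diagonal of Q^{-1} and log|Q| are O(n^2)/O(n) per gamma after one
# symmetric eigendecomposition.
car_setup <- function(graph) {
  if (!is.null(attr(graph, "car_setup"))) return(attr(graph, "car_setup"))
  d <- as.numeric(graph_degree(graph))
  dd <- ifelse(d == 0, 1, d)
  W <- graph_adjacency(graph)
  s <- 1 / sqrt(dd)
  B <- as.matrix(W * tcrossprod(s))
  eig <- eigen(B, symmetric = TRUE)
  U2 <- eig$vectors^2
  list(graph = graph, n = graph$n, d = d, dd = dd, s = s,
       W = W, U = eig$vectors, lam = eig$values, U2 = U2,
       Q = function(gamma) {
         Matrix::Diagonal(x = dd) - gamma * W
       })
}

# diag(Q(gamma)^{-1})
car_diag_inv <- function(st, gamma) {
  w <- 1 / (1 - gamma * st$lam)
  as.numeric(st$U2 %*% w) * st$s^2
}

# dense Q(gamma)^{-1}
car_inverse <- function(st, gamma) {
  w <- 1 / (1 - gamma * st$lam)
  M <- st$U %*% (w * t(st$U))
  M * tcrossprod(st$s)
}

# log|Q(gamma)|
car_logdet <- function(st, gamma) {
  sum(log(st$dd)) + sum(log1p(-gamma * st$lam))
}

# Sparse inverse spatial correlation R_space^{-1} = V^{1/2} Q V^{1/2},
# with V = diag(diag(Q^{-1})). Returned with its log-determinant.
car_corr_inv <- function(st, gamma) {
  v <- car_diag_inv(st, gamma)
  sv <- sqrt(v)
  Q <- st$Q(gamma)
  Rinv <- Matrix::Diagonal(x = sv) %*% Q %*% Matrix::Diagonal(x = sv)
  list(Rinv = Rinv, logdetR = -car_logdet(st, gamma) - sum(log(v)), v = v)
}

# Draw k independent spatial fields with correlation R_space(gamma).
car_sample <- function(st, gamma, k = 1L) {
  w <- 1 / sqrt(1 - gamma * st$lam)
  eps <- matrix(stats::rnorm(st$n * k), st$n, k)
  X <- st$U %*% (w * eps) * st$s       # covariance Q^{-1}
  v <- car_diag_inv(st, gamma)
  X / sqrt(v)
}

#' Separable space-time working correlation
#'
#' Kronecker product of an AR(1) correlation over timepoints with a spatial
#' correlation over tracts: the entry for (tract i, time t) vs (tract j,
#' time s) is `R_space[i, j] * phi^|t - s|`. Rows are stacked time-major
#' (all tracts at the first timepoint, then all at the second), matching
#' [build_design()].
#'
#' @param R_space spatial correlation matrix (unit diagonal).
#' @param phi AR(1) lag-one correlation, strictly in (-1, 1).
#' @param n_times number of timepoints (default 2: the two study years).
#' @return A dense `(n_times * n)` square correlation matrix.
#' @export
spacetime_correlation <- function(R_space, phi, n_times = 2L) {
  R_space <- as.matrix(R_space)
  if (nrow(R_space) != ncol(R_space) ||
      max(abs(diag(R_space) - 1)) > 1e-8) {
    stop("R_space must be a square correlation matrix with unit diagonal")
  }
  if (length(phi) != 1L || !is.finite(phi) || abs(phi) >= 1) {
    stop("phi must lie strictly inside (-1, 1)")
  }
  if (n_times < 1L) stop("n_times must be positive")
  R_ar <- phi^abs(outer(seq_len(n_times), seq_len(n_times), "-"))
  kronecker(R_ar, R_space)
}

# AR(1) correlation and inverse for two timepoints.
ar2_corr <- function(phi) matrix(c(1, phi, phi, 1), 2, 2)
ar2_inv <- function(phi) matrix(c(1, -phi, -phi, 1), 2, 2) / (1 - phi^2)
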