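#' Tract adjacency graphs
#'
#' A `tract_graph` is a symmetric, self-loop-free neighbor structure over a
#' set of tract identifiers. It backs the CAR working correlation, the
#' spatially clustered covariate generator, and Moran's I diagnostics.
#'
#' @param ids character vector of tract identifiers (unique).
#' @param edges two-column matrix (integer indices into `ids`, or character
#'   ids) listing undirected edges; duplicates and orientation are collapsed.
#' @return An object of class `tract_graph`: a list with elements `ids`,
#'   `edges` (two-column integer matrix, `from < to`), and `n`.
#' @examples
#' g <- tract_graph(c("a", "b", "c"), rbind(c(1, 2), c(2, 3)))
#' graph_degree(g)
#' @export
tract_graph <- function(ids, edges) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("tract ids must be unique")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns")
    if (is.character(edges)) {
      idx <- match(edges, ids)
      if (anyNA(idx)) {
        stop("edge names absent tracts: ",
             paste(unique(edges[is.na(idx)]), collapse = ", "))
      }
      edges <- matrix(idx, ncol = 2L)
    }
    storage.mode(edges) <- "integer"
    if (any(edges < 1L) || any(edges > length(ids))) {
      stop("edge indices out of range")
    }
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  structure(list(ids = ids, edges = edges, n = length(ids)),
            class = "tract_graph")
}

#' @export
print.tract_graph <- function(x, ...) {
  cat("tract_graph:", x$n, "tracts,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' @rdname tract_graph
#' @param graph a `tract_graph`.
#' @export
graph_degree <- function(graph) {
  stopifnot(inherits(graph, "tract_graph"))
  d <- integer(graph$n)
  if (nrow(graph$edges)) {
    t1 <- tabulate(graph$edges[, 1L], graph$n)
    t2 <- tabulate(graph$edges[, 2L], graph$n)
    d <- t1 + t2
  }
  names(d) <- graph$ids
  d
}

# Symmetric 0/1 adjacency as a sparse Matrix.
graph_adjacency <- function(graph) {
  e <- graph$edges
  Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
                       x = 1, dims = c(graph$n, graph$n),
                       dimnames = list(graph$ids, graph$ids))
}

# Neighbor index list (for BFS growth and field smoothing).
graph_neighbors <- function(graph) {
  nb <- vector("list", graph$n)
  e <- graph$edges
  if (nrow(e)) {
    for (k in seq_len(nrow(e))) {
      i <- e[k, 1L]; j <- e[k, 2L]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

# Induced subgraph on the first k ids (used when a lattice is truncated).
graph_subset <- function(graph, keep) {
  keep <- sort(keep)
  idx <- match(seq_len(graph$n), keep)
  e <- graph$edges
  ok <- !is.na(idx[e[, 1L]]) & !is.na(idx[e[, 2L]])
  tract_graph(graph$ids[keep], cbind(idx[e[ok, 1L]], idx[e[ok, 2L]]))
}

#' Rook-contiguity lattice
#'
#' Builds the rook-neighbor graph on a `rows` by `cols` grid of cells, the
#' stand-in for a census-tract adjacency structure. Cells are labelled
#' `t0001`, `t0002`, ... in row-major order; the edge count is
#' `2*rows*cols - rows - cols`.
#'
#' @param rows,cols positive integers, the lattice dimensions.
#' @return A [tract_graph()].
#' @examples
#' make_lattice(3, 3) # 9 nodes, 12 edges
#' @export
make_lattice <- function(rows, cols) {
  if (length(rows) != 1L || length(cols) != 1L ||
      !is.finite(rows) || !is.finite(cols) ||
      rows < 1 || cols < 1 || rows != floor(rows) || cols != floor(cols)) {
    stop("rows and cols must be positive integers")
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  n <- rows * cols
  cell <- function(r, c) (r - 1L) * cols + c
  from <- to <- integer(0)
  if (cols > 1L) {
    r <- rep(seq_len(rows), each = cols - 1L)
    c <- rep(seq_len(cols - 1L), times = rows)
    from <- c(from, cell(r, c)); to <- c(to, cell(r, c + 1L))
  }
  if (rows > 1L) {
    r <- rep(seq_len(rows - 1L), each = cols)
    c <- rep(seq_len(cols), times = rows - 1L)
    from <- c(from, cell(r, c)); to <- c(to, cell(r + 1L, c))
  }
  ids <- sprintf("t%04d", seq_len(n))
  g <- tract_graph(ids, cbind(from, to))
  g$rows <- rows
  g$cols <- cols
  g
}

#' Moran's I spatial autocorrelation
#'
#' Computes Moran's I for a tract-indexed numeric vector against the binary
#' rook/queen adjacency of `graph`. Used as a residual diagnostic for the
#' spatial working correlation.
#'
#' @param x numeric vector, one value per tract in `graph` order.
#' @param graph a [tract_graph()].
#' @return Moran's I (scalar).
#' @export
moran_i <- function(x, graph) {
  stopifnot(inherits(graph, "tract_graph"), length(x) == graph$n)
  if (nrow(graph$edges) == 0L) return(NA_real_)
  z <- x - mean(x)
  e <- graph$edges
  cross <- 2 * sum(z[e[, 1L]] * z[e[, 2L]])
  s0 <- 2 * nrow(e)
  (graph$n / s0) * cross / sum(z^2)
}
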