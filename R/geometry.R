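#' Planar polygon sets
#'
#' Minimal planar geometry for tract/city assignment rules: polygons are
#' single closed rings in planar coordinates. Intersection areas are exact
#' for axis-aligned rectilinear polygons (the synthetic geometry) via a grid
#' overlay, and computed by convex clipping otherwise.
#'
#' @param polygons named list; each element a two-column numeric matrix of
#'   ring vertices (the closing vertex may be repeated or omitted).
#' @return An object of class `polygon_set`.
#' @export
polygon_set <- function(polygons) {
  if (is.null(names(polygons)) || anyDuplicated(names(polygons))) {
    stop("polygons must be uniquely named")
  }
  polys <- lapply(names(polygons), function(id) {
    ring <- as.matrix(polygons[[id]])
    if (ncol(ring) != 2L || nrow(ring) < 3L) {
      stop("polygon '", id, "' must be a ring of at least 3 (x, y) vertices")
    }
    if (all(ring[1L, ] == ring[nrow(ring), ])) {
      ring <- ring[-nrow(ring), , drop = FALSE]
    }
    if (nrow(ring) < 3L || abs(shoelace(ring)) <= 0) {
      stop("polygon '", id, "' has zero area")
    }
    ring
  })
  names(polys) <- names(polygons)
  structure(polys, class = "polygon_set")
}

#' @export
print.polygon_set <- function(x, ...) {
  cat("polygon_set:", length(x), "polygons\n")
  invisible(x)
}

# signed shoelace area (positive = counter-clockwise)
shoelace <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polygon_area <- function(ring) abs(shoelace(ring))

# point location: 1 inside, 0 on boundary, -1 outside (even-odd rule)
point_in_ring <- function(px, py, ring, tol = 1e-12) {
  n <- nrow(ring)
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  # boundary: point on any segment
  dx <- xn - x; dy <- yn - y
  len2 <- dx^2 + dy^2
  t <- pmin(1, pmax(0, ((px - x) * dx + (py - y) * dy) / pmax(len2, tol)))
  d2 <- (x + t * dx - px)^2 + (y + t * dy - py)^2
  if (any(d2 <= tol)) return(0L)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((y[i] > py) != (y[j] > py)) {
      xint <- x[i] + (py - y[i]) / (y[j] - y[i]) * (x[j] - x[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  if (inside) 1L else -1L
}

is_rectilinear <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  all(x == xn | y == yn)
}

is_convex <- function(ring) {
  if (shoelace(ring) < 0) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  n <- nrow(ring)
  a <- ring[c(2:n, 1L), ] - ring
  cr <- a[, 1L] * a[c(2:n, 1L), 2L] - a[, 2L] * a[c(2:n, 1L), 1L]
  all(cr >= -1e-12)
}

# exact intersection area of two rectilinear rings via grid overlay
rectilinear_intersection <- function(a, b) {
  xs <- sort(unique(c(a[, 1L], b[, 1L])))
  ys <- sort(unique(c(a[, 2L], b[, 2L])))
  if (length(xs) < 2L || length(ys) < 2L) return(0)
  total <- 0
  for (i in seq_len(length(xs) - 1L)) {
    mx <- (xs[i] + xs[i + 1L]) / 2
    w <- xs[i + 1L] - xs[i]
    for (j in seq_len(length(ys) - 1L)) {
      my <- (ys[j] + ys[j + 1L]) / 2
      if (point_in_ring(mx, my, a) >= 0L && point_in_ring(mx, my, b) >= 0L) {
        total <- total + w * (ys[j + 1L] - ys[j])
      }
    }
  }
  total
}

# Sutherland-Hodgman: clip `subject` by convex ring `clip`
convex_clip <- function(subject, clip) {
  if (shoelace(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0L) return(out)
    A <- clip[e, ]; B <- clip[if (e == nc) 1L else e + 1L, ]
    side <- function(p) (B[1L] - A[1L]) * (p[2L] - A[2L]) -
      (B[2L] - A[2L]) * (p[1L] - A[1L])
    inp <- out
    out <- matrix(numeric(0), 0L, 2L)
    m <- nrow(inp)
    for (i in seq_len(m)) {
      P <- inp[i, ]; Qp <- inp[if (i == m) 1L else i + 1L, ]
      sP <- side(P); sQ <- side(Qp)
      if (sP >= 0) out <- rbind(out, P)
      if ((sP > 0 && sQ < 0) || (sP < 0 && sQ > 0)) {
        t <- sP / (sP - sQ)
        out <- rbind(out, P + t * (Qp - P))
      }
    }
  }
  out
}

polygon_intersection_area <- function(a, b) {
  if (is_rectilinear(a) && is_rectilinear(b)) {
    return(rectilinear_intersection(a, b))
  }
  if (is_convex(b)) return(polygon_area_or_zero(convex_clip(a, b)))
  if (is_convex(a)) return(polygon_area_or_zero(convex_clip(b, a)))
  stop("intersection area needs rectilinear or convex polygons")
}

polygon_area_or_zero <- function(ring) {
  if (is.null(ring) || nrow(ring) < 3L) 0 else polygon_area(ring)
}

#' Tally points into tract polygons
#'
#' Assigns each point to the unique tract polygon containing it. A point on
#' a shared boundary is assigned deterministically to the lowest tract id
#' among the touching polygons; a point strictly inside more than one
#' polygon reveals overlapping tracts and raises an error. Points contained
#' by no polygon are counted as unassigned, never silently dropped.
#'
#' @param points two-column matrix of planar coordinates.
#' @param tracts a [polygon_set()] of tract rings.
#' @return List with `counts` (named integer per tract) and `n_unassigned`.
#' @export
count_points_in_tracts <- function(points, tracts) {
  stopifnot(inherits(tracts, "polygon_set"))
  ids <- names(tracts)
  counts <- stats::setNames(integer(length(ids)), ids)
  if (is.null(points) || NROW(points) == 0L) {
    return(list(counts = counts, n_unassigned = 0L))
  }
  points <- matrix(as.numeric(as.matrix(points)), ncol = 2L)
  if (any(!is.finite(points))) stop("points must be finite coordinates")
  unassigned <- 0L
  ids_sorted <- sort(ids)
  for (k in seq_len(nrow(points))) {
    loc <- vapply(tracts, function(ring)
      point_in_ring(points[k, 1L], points[k, 2L], ring), integer(1))
    inside <- names(loc)[loc == 1L]
    touch <- names(loc)[loc == 0L]
    if (length(inside) > 1L) {
      stop("overlapping tract polygons: ", paste(inside, collapse = ", "))
    }
    target <- if (length(inside) == 1L) inside
    else if (length(touch)) sort(touch)[1L]
    else NA_character_
    if (is.na(target)) unassigned <- unassigned + 1L
    else counts[target] <- counts[target] + 1L
  }
  list(counts = counts, n_unassigned = unassigned)
}

#' Licensing assignment by city overlap
#'
#' A tract is covered by a licensing city when it is fully contained in a
#' city polygon, or at least 50% of its area (inclusive) intersects one.
#' Areas are exact for axis-aligned rectilinear geometry; other shapes are
#' handled by convex clipping.
#'
#' @param tracts,cities [polygon_set()] objects.
#' @return Named logical vector, one entry per tract.
#' @export
assign_licensing <- function(tracts, cities) {
  stopifnot(inherits(tracts, "polygon_set"), inherits(cities, "polygon_set"))
  vapply(names(tracts), function(id) {
    ring <- tracts[[id]]
    a <- polygon_area(ring)
    if (a <= 0) stop("degenerate zero-area tract: ", id)
    for (city in cities) {
      frac <- polygon_intersection_area(ring, city) / a
      if (frac >= 0.5 - 1e-12) return(TRUE)
    }
    FALSE
  }, logical(1))
}
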