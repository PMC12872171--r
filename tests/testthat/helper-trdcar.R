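# Shared fixtures: all synthetic, built in code.

# small fully-specified tract table: one row per tract-year
toy_table <- function(n = 4, years = c(2017L, 2022L),
                      population = 1000, retailer_count = NULL,
                      rurality = "urban",
                      high_aa = FALSE, high_hisp = FALSE,
                      high_children = FALSE, high_poverty = FALSE) {
  ids <- sprintf("t%04d", seq_len(n))
  per_year <- function(y, k) {
    data.frame(tract_id = ids, year = y,
               population = rep_len(population, n),
               high_aa = rep_len(high_aa, n),
               high_hisp = rep_len(high_hisp, n),
               high_children = rep_len(high_children, n),
               high_poverty = rep_len(high_poverty, n),
               rurality = factor(rep_len(rurality, n),
                                 levels = c("urban", "suburban", "rural")),
               licensing = FALSE,
               retailer_count = if (is.null(retailer_count)) 0L
               else rep_len(retailer_count[[k]], n),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_along(years),
                        function(k) per_year(years[k], k)))
}

# quick seeded synthetic state
tiny_state <- function(seed = 1, rows = 10, cols = 10, ...) {
  cfg <- sim_config(lattice_rows = rows, lattice_cols = cols,
                    seed = seed, ...)
  simulate_state(cfg)
}

# unit-square tract grid as a polygon_set: cell (i, j) covers
# [j-1, j] x [i-1, i]
square_tracts <- function(rows, cols, prefix = "t") {
  polys <- list()
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    polys[[sprintf("%s%02d%02d", prefix, i, j)]] <-
      rbind(c(j - 1, i - 1), c(j, i - 1), c(j, i), c(j - 1, i))
  }
  polygon_set(polys)
}

rect_ring <- function(x0, y0, x1, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
}
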