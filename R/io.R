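#' Tract table and adjacency file I/O
#'
#' Tables and graphs travel as UTF-8 comma-delimited text with a header row;
#' metadata (package version, seed, config digest) is carried in leading
#' `#`-prefixed comment lines so files remain plain `read.csv`-able.
#'
#' @param table tract table data frame.
#' @param path output file path.
#' @param meta named list written as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_tract_table <- function(table, path, meta = list()) {
  write_with_meta(table, path, meta)
}

write_with_meta <- function(df, path, meta = list()) {
  meta <- c(list(package = paste0("trdcar ",
                                  as.character(utils::packageVersion("trdcar"))),
                 written = "trdcar delimited text v1"), meta)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "# ")]
  out <- list()
  for (l in lines) {
    kv <- sub("^# ", "", l)
    i <- regexpr(": ", kv, fixed = TRUE)
    if (i > 0) out[[substr(kv, 1, i - 1)]] <- substr(kv, i + 2, nchar(kv))
  }
  out
}

#' @rdname write_tract_table
#' @param mapping optional named character vector renaming file columns to
#'   the package's column contract, e.g.
#'   `c(tract_id = "GEOID", population = "pop")`.
#' @export
read_tract_table <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (ours in names(mapping)) {
      theirs <- mapping[[ours]]
      if (!theirs %in% names(df)) {
        stop("mapped column absent from file: ", theirs)
      }
      names(df)[names(df) == theirs] <- ours
    }
  }
  need <- c("tract_id", "year", "population")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df$tract_id <- as.character(df$tract_id)
  key <- paste(df$tract_id, df$year)
  if (anyDuplicated(key)) {
    dup <- unique(df$tract_id[duplicated(key)])
    stop("duplicated (tract_id, year) for tract(s): ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  for (col in intersect(c("pct_african_american", "pct_hispanic",
                          "pct_under18", "pct_poverty"), names(df))) {
    bad <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 100))
    if (length(bad)) {
      stop(col, " outside [0, 100] at row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  if (any(!is.na(df$population) & df$population < 0)) {
    stop("negative population")
  }
  for (col in intersect(c("high_aa", "high_hisp", "high_children",
                          "high_poverty", "licensing"), names(df))) {
    df[[col]] <- as.logical(df[[col]])
  }
  if ("rurality" %in% names(df)) {
    bad <- which(!df$rurality %in% c("urban", "suburban", "rural"))
    if (length(bad)) stop("unknown rurality at row(s): ",
                          paste(utils::head(bad, 5L), collapse = ", "))
    df$rurality <- factor(df$rurality,
                          levels = c("urban", "suburban", "rural"))
  }
  if ("retailer_count" %in% names(df) &&
      any(!is.na(df$retailer_count) & df$retailer_count < 0)) {
    stop("negative retailer_count")
  }
  df
}

#' @rdname write_tract_table
#' @param graph a [tract_graph()].
#' @export
write_adjacency <- function(graph, path, meta = list()) {
  stopifnot(inherits(graph, "tract_graph"))
  e <- graph$edges
  df <- data.frame(from = graph$ids[e[, 1L]], to = graph$ids[e[, 2L]])
  write_with_meta(df, path, c(list(id_space = "tract_id",
                                   n_tracts = graph$n), meta))
}

#' @rdname write_tract_table
#' @param ids optional tract id vector the edges must draw from (edges
#'   naming absent tracts are a structural error); default: the ids seen.
#' @export
read_adjacency <- function(path, ids = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(df))) {
    stop("adjacency file needs columns 'from' and 'to'")
  }
  df$from <- as.character(df$from); df$to <- as.character(df$to)
  if (is.null(ids)) {
    ids <- sort(unique(c(df$from, df$to)))
    meta <- read_meta(path)
    if (!is.null(meta$n_tracts) &&
        as.integer(meta$n_tracts) > length(ids)) {
      # isolated tracts carry no edges; trust the recorded node count only
      # when an id list is supplied
      warning("edge list names fewer tracts than its header records; ",
              "pass `ids` to restore isolated tracts")
    }
  }
  tract_graph(ids, cbind(df$from, df$to))
}

# digest of an R object via serialization + md5 (config fingerprinting)
config_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
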