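#' Run the TRD analysis pipeline
#'
#' Chains the stages simulate -> prep -> describe -> fit -> predict (any
#' subset) into one reproducible run. Every output file carries the package
#' version, the seed, and a digest of the configuration in its comment
#' header; the run report records per-stage row counts and exclusions.
#' Outputs are fully determined by (inputs, config, seed).
#'
#' @param config named list:
#'   \describe{
#'     \item{stages}{subset of `c("simulate", "prep", "describe", "fit",
#'       "predict")` (default all).}
#'     \item{out_dir}{output directory (created).}
#'     \item{seed}{integer seed.}
#'     \item{sim}{arguments forwarded to [sim_config()].}
#'     \item{n_tracts}{tract count for the simulated state (default: full
#'       lattice).}
#'     \item{table_file, graph_file}{inputs for runs without `simulate`.}
#'     \item{column_mapping}{forwarded to [read_tract_table()].}
#'     \item{model}{`"model1"` (default) or `"model2"` (adds the 2022
#'       licensing indicator).}
#'     \item{combos}{data frame for the predict stage (default: the eight
#'       low-children poverty x race/ethnicity x licensing profiles).}
#'     \item{verbose}{emit stage-tagged progress to standard error.}
#'   }
#' @return Run report (list), invisibly: files written, row counts,
#'   exclusion log, fit convergence.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  stages <- config$stages %||% c("simulate", "prep", "describe", "fit",
                                 "predict")
  bad <- setdiff(stages, c("simulate", "prep", "describe", "fit", "predict"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  verbose <- isTRUE(config$verbose)
  say <- function(stage, ...) if (verbose) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }
  digest <- config_digest(config[setdiff(names(config),
                                         c("out_dir", "verbose"))])
  meta <- list(seed = seed, config_digest = digest)
  paths <- character(0)
  report <- list(seed = seed, config_digest = digest, stages = stages)

  table <- NULL; graph <- NULL
  if ("simulate" %in% stages) {
    cfg <- do.call(sim_config, c(config$sim %||% list(), list(seed = seed)))
    state <- simulate_state(cfg, n_tracts = config$n_tracts)
    table <- state$table; graph <- state$graph
    p_tab <- file.path(out_dir, "tract_table.csv")
    p_gr <- file.path(out_dir, "adjacency.csv")
    write_tract_table(table, p_tab, meta)
    write_adjacency(graph, p_gr, meta)
    paths <- c(paths, p_tab, p_gr)
    report$simulate <- list(n_tracts = graph$n, n_rows = nrow(table))
    say("simulate", graph$n, " tracts, ", nrow(table), " rows")
  } else {
    if (!is.null(config$table_file)) {
      table <- read_tract_table(config$table_file, config$column_mapping)
    }
    if (!is.null(config$graph_file)) {
      graph <- read_adjacency(config$graph_file,
                              ids = unique(table$tract_id))
    }
  }

  if ("prep" %in% stages) {
    if (is.null(table)) stop("prep stage needs a table (simulate or table_file)")
    if (all(c("pct_african_american", "pct_hispanic", "pct_under18",
              "pct_poverty") %in% names(table))) {
      flags <- classify_prevalence(table$pct_african_american,
                                   table$pct_hispanic,
                                   table$pct_under18, table$pct_poverty)
      for (col in names(flags)) {
        if (col %in% names(table) &&
            any(table[[col]] != flags[[col]], na.rm = TRUE)) {
          stop("stored flags inconsistent with percentages: ", col)
        }
        table[[col]] <- flags[[col]]
      }
    }
    if ("nchs_level" %in% names(table)) {
      table$rurality <- classify_rurality(table$nchs_level)
    }
    fl <- filter_tracts(table)
    table <- fl$table
    if (!is.null(graph) && nrow(fl$exclusions)) {
      keep <- which(graph$ids %in% unique(table$tract_id))
      graph <- graph_subset(graph, keep)
    }
    p_exc <- file.path(out_dir, "exclusions.csv")
    write_with_meta(fl$exclusions, p_exc, meta)
    p_prep <- file.path(out_dir, "prepared_table.csv")
    write_tract_table(table, p_prep, meta)
    paths <- c(paths, p_exc, p_prep)
    report$prep <- list(n_rows = nrow(table),
                        n_excluded = nrow(fl$exclusions),
                        exclusions = fl$exclusions)
    say("prep", nrow(table), " rows retained, ",
        nrow(fl$exclusions), " tracts excluded")
  }

  if ("describe" %in% stages) {
    if (is.null(table)) stop("describe stage needs a table")
    gs <- describe_trd(table)
    cs <- change_summary(table)
    p_gs <- file.path(out_dir, "group_summary.csv")
    write_with_meta(gs, p_gs, meta)
    cs_df <- data.frame(measure = c("fraction_increased",
                                    "fraction_decreased",
                                    "fraction_unchanged", "mean_increase",
                                    "mean_decrease", "overall_pct_change"),
                        value = c(cs$fraction_increased,
                                  cs$fraction_decreased,
                                  cs$fraction_unchanged, cs$mean_increase,
                                  cs$mean_decrease, cs$overall_pct_change))
    p_cs <- file.path(out_dir, "change_summary.csv")
    write_with_meta(cs_df, p_cs, meta)
    paths <- c(paths, p_gs, p_cs)
    report$describe <- list(n_group_rows = nrow(gs), change = cs)
    say("describe", nrow(gs), " group-summary rows")
  }

  fit <- NULL
  if ("fit" %in% stages) {
    if (is.null(table) || is.null(graph)) {
      stop("fit stage needs a table and a graph")
    }
    spec <- trd_terms(licensing = identical(config$model, "model2"))
    fit <- fit_trd(table, graph, spec, fix = config$fix %||% list())
    sm <- summary(fit)
    p_fit <- file.path(out_dir, "fit_coefficients.csv")
    write_with_meta(sm$coefficients, p_fit, meta)
    p_cor <- file.path(out_dir, "fit_parameters.csv")
    write_with_meta(data.frame(
      parameter = c("dispersion_alpha", "gamma_spatial", "phi_temporal",
                    "scale", "n_iterations", "converged"),
      value = c(fit$dispersion_alpha, fit$gamma_spatial, fit$phi_temporal,
                fit$scale, fit$n_iterations, as.numeric(fit$converged))),
      p_cor, meta)
    paths <- c(paths, p_fit, p_cor)
    report$fit <- list(converged = fit$converged,
                       n_iterations = fit$n_iterations,
                       gamma = fit$gamma_spatial, phi = fit$phi_temporal,
                       alpha = fit$dispersion_alpha)
    say("fit", "converged = ", fit$converged, " in ",
        fit$n_iterations, " iterations")
  }

  if ("predict" %in% stages) {
    if (is.null(fit)) stop("predict stage needs the fit stage")
    combos <- config$combos %||% {
      cb <- expand.grid(high_poverty = c(FALSE, TRUE),
                        high_aa = c(FALSE, TRUE),
                        licensing = if (fit$design$spec$licensing)
                          c(FALSE, TRUE) else FALSE)
      cb$high_hisp <- cb$high_aa
      cb$high_children <- FALSE
      cb$rurality <- "suburban"
      cb
    }
    pr <- predict_groups(fit, combos)
    p_pr <- file.path(out_dir, "predictions.csv")
    write_with_meta(pr, p_pr, meta)
    paths <- c(paths, p_pr)
    report$predict <- list(n_rows = nrow(pr))
    say("predict", nrow(pr), " prediction rows")
  }

  report$files <- paths
  invisible(report)
}

#' @rdname run_pipeline
#' @param path YAML run-configuration file.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package")
  }
  cfg <- yaml::yaml.load_file(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  cfg
}
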