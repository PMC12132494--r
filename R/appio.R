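#' Analysis configuration
#'
#' Validated configuration for a CSV-driven two-group conditional covariance
#' comparison. A configuration can also be read from JSON with
#' [read_config()].
#'
#' @param data path to the input CSV (header row; missing values empty or
#'   `NA`).
#' @param group_column name of the binary group column.
#' @param group_levels ordered pair `c(reference, comparison)`.
#' @param response_columns at least two response column names.
#' @param continuous_covariates continuous covariate column name(s).
#' @param categorical_covariates optional factor covariate column name(s).
#' @param grid list with `start`, `stop`, `step` per continuous covariate
#'   (a single list for one covariate), or `NULL` for an automatic grid.
#' @param methods subset of
#'   `c("tracy_widom", "forkman", "permutation")`.
#' @param B resampling size.
#' @param alpha significance level in (0, 1).
#' @param log_transform logical flag(s), one per response (recycled),
#'   requesting a natural-log transform before standardization.
#' @param seed integer seed.
#' @param bandwidths `"cv"` (leave-one-out selection, the default) or a list
#'   with numeric entries `h0`, `h1` (and optionally `mean_h0`, `mean_h1`).
#' @param lambda Aitchison-Aitken weight for categorical covariates.
#' @param min_level_count minimum per-group count required for a factor
#'   level to be analyzed (default 30).
#' @return an object of class `"analysis_config"`.
#' @export
analysis_config <- function(data, group_column, group_levels,
                            response_columns, continuous_covariates,
                            categorical_covariates = character(),
                            grid = NULL,
                            methods = c("tracy_widom", "forkman",
                                        "permutation"),
                            B = 1000L, alpha = 0.05, log_transform = FALSE,
                            seed = 1L, bandwidths = "cv", lambda = 1,
                            min_level_count = 30L) {
  if (length(response_columns) < 2L) {
    stop_covtrace("need at least 2 response columns", "config")
  }
  if (length(group_levels) != 2L) {
    stop_covtrace("group_levels must name the reference and comparison level",
                  "config")
  }
  if (alpha <= 0 || alpha >= 1) {
    stop_covtrace("alpha must lie in (0, 1)", "config")
  }
  if (!is.null(grid)) {
    if (!is.null(grid$start)) grid <- list(grid)
    for (g in grid) {
      if (!all(c("start", "stop", "step") %in% names(g)) || g$step <= 0) {
        stop_covtrace("each grid needs start, stop and step > 0", "config")
      }
    }
  }
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(
    data = data, group_column = group_column,
    group_levels = as.character(group_levels),
    response_columns = response_columns,
    continuous_covariates = continuous_covariates,
    categorical_covariates = categorical_covariates,
    grid = grid, methods = methods, B = as.integer(B), alpha = alpha,
    log_transform = rep_len(as.logical(log_transform),
                            length(response_columns)),
    seed = as.integer(seed), bandwidths = bandwidths, lambda = lambda,
    min_level_count = as.integer(min_level_count)),
    class = "analysis_config")
}

#' Read an analysis configuration from JSON
#'
#' @param path path to a JSON file whose fields mirror the arguments of
#'   [analysis_config()].
#' @return an object of class `"analysis_config"`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$grid)) {
    g <- raw$grid
    if (is.data.frame(g)) {
      raw$grid <- lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    }
  }
  do.call(analysis_config, raw)
}

#' Load a CSV and preprocess it into two group samples
#'
#' Drops rows with missing values in any configured column (the count is
#' reported as an attribute and a message), applies the optional natural-log
#' transform per response, and standardizes each response column to zero
#' mean and unit variance *within each group*. Covariates are left
#' untouched.
#'
#' @param csv_path path to the CSV; defaults to `config$data`.
#' @param config an [analysis_config()].
#' @return a list with [group_sample()]s `group0` (reference level) and
#'   `group1`, and `dropped`, the number of incomplete rows removed.
#' @export
load_and_preprocess <- function(csv_path = NULL, config) {
  if (is.null(csv_path)) csv_path <- config$data
  df <- utils::read.csv(csv_path, na.strings = c("", "NA"),
                        stringsAsFactors = FALSE)
  cols <- c(config$group_column, config$response_columns,
            config$continuous_covariates, config$categorical_covariates)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    stop_covtrace(paste("configured columns absent from CSV:",
                        paste(missing_cols, collapse = ", ")), "config")
  }
  df <- df[, cols, drop = FALSE]
  keep <- stats::complete.cases(df)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("dropped %d row(s) with missing configured fields",
                    dropped))
  }
  df <- df[keep, , drop = FALSE]
  for (j in which(config$log_transform)) {
    col <- config$response_columns[j]
    bad <- which(df[[col]] <= 0)
    if (length(bad) > 0L) {
      stop_covtrace(
        sprintf("log transform of '%s' undefined at row %d (value %g <= 0)",
                col, bad[1L], df[[col]][bad[1L]]), "data")
    }
    df[[col]] <- log(df[[col]])
  }
  cat_levels <- lapply(config$categorical_covariates,
                       function(cc) sort(unique(as.character(df[[cc]]))))
  make_group <- function(level) {
    sub <- df[as.character(df[[config$group_column]]) == level, ,
              drop = FALSE]
    if (nrow(sub) == 0L) {
      stop_covtrace(sprintf("group level '%s' has no rows after filtering",
                            level), "config")
    }
    x <- as.matrix(sub[, config$response_columns, drop = FALSE])
    x <- scale(x)                      # per-group standardization
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
    ucat <- NULL
    if (length(config$categorical_covariates) > 0L) {
      ucat <- as.data.frame(lapply(seq_along(config$categorical_covariates),
        function(k) factor(sub[[config$categorical_covariates[k]]],
                           levels = cat_levels[[k]])))
      names(ucat) <- config$categorical_covariates
    }
    group_sample(x,
                 as.matrix(sub[, config$continuous_covariates,
                               drop = FALSE]),
                 ucat)
  }
  out <- list(group0 = make_group(config$group_levels[1L]),
              group1 = make_group(config$group_levels[2L]),
              dropped = dropped)
  out
}

#' Run a configured two-group analysis
#'
#' Loads and preprocesses the data, fits the conditional covariance function
#' for each group (bandwidths by leave-one-out selection when
#' `config$bandwidths == "cv"`), and produces a significance trace on the
#' configured covariate grid, clipped to the intersection of the two groups'
#' observed ranges. With categorical covariates the trace is produced
#' separately per factor level, skipping levels below the configured minimum
#' per-group count.
#'
#' @param config an [analysis_config()].
#' @param csv_path optional path overriding `config$data`.
#' @return a list of class `"covtrace_analysis"`: `table` (the
#'   significance-trace data.frame) and `manifest` (config, selected
#'   bandwidths, seed, package version — everything needed to reproduce the
#'   table).
#' @export
run_analysis <- function(config, csv_path = NULL) {
  groups <- load_and_preprocess(csv_path, config)
  g0 <- groups$group0; g1 <- groups$group1
  if (identical(config$bandwidths, "cv")) {
    fit0 <- condcov(sample = g0, lambda = config$lambda)
    fit1 <- condcov(sample = g1, lambda = config$lambda)
  } else {
    bwl <- config$bandwidths
    fit0 <- condcov(sample = g0, bandwidth = bwl$h0,
                    mean_bandwidth = bwl$mean_h0, lambda = config$lambda)
    fit1 <- condcov(sample = g1, bandwidth = bwl$h1,
                    mean_bandwidth = bwl$mean_h1, lambda = config$lambda)
  }
  grid_u <- .config_grid(config, g0, g1)
  levels_to_run <- list(NULL)
  if (length(config$categorical_covariates) > 0L) {
    lev_grid <- expand.grid(lapply(g0$ucat, levels),
                            stringsAsFactors = FALSE)
    levels_to_run <- lapply(seq_len(nrow(lev_grid)), function(i) {
      as.list(lev_grid[i, , drop = FALSE])
    })
    counts_ok <- vapply(levels_to_run, function(lv) {
      min(sum(.cat_weights(g0$ucat, lv, 1) > 0),
          sum(.cat_weights(g1$ucat, lv, 1) > 0)) >= config$min_level_count
    }, logical(1))
    levels_to_run <- levels_to_run[counts_ok]
    if (length(levels_to_run) == 0L) {
      stop_covtrace("no factor level meets the minimum per-group count",
                    "config")
    }
  }
  tabs <- lapply(seq_along(levels_to_run), function(i) {
    significance_trace(fit0, fit1, grid_u = grid_u,
                       methods = config$methods, B = config$B,
                       seed = sub_seed(config$seed, i * 100000),
                       level = levels_to_run[[i]])
  })
  table <- do.call(rbind, tabs)
  class(table) <- c("significance_trace", "data.frame")
  manifest <- list(
    config = unclass(config),
    dropped_rows = groups$dropped,
    n0 = g0$n, n1 = g1$n,
    bandwidths = list(h0 = fit0$bandwidth$h, mean_h0 = fit0$bandwidth$mean_h,
                      h1 = fit1$bandwidth$h, mean_h1 = fit1$bandwidth$mean_h),
    package_version = as.character(utils::packageVersion("covtrace")))
  structure(list(table = table, manifest = manifest, fit0 = fit0,
                 fit1 = fit1),
            class = "covtrace_analysis")
}

.config_grid <- function(config, g0, g1) {
  q <- g0$q
  lo <- pmax(apply(g0$u, 2L, min), apply(g1$u, 2L, min))
  hi <- pmin(apply(g0$u, 2L, max), apply(g1$u, 2L, max))
  axes <- lapply(seq_len(q), function(j) {
    if (!is.null(config$grid)) {
      g <- config$grid[[min(j, length(config$grid))]]
      ax <- seq(g$start, g$stop, by = g$step)
      ax[ax >= lo[j] & ax <= hi[j]]           # clip to observed range
    } else {
      seq(lo[j], hi[j], length.out = 30L)
    }
  })
  if (any(lengths(axes) == 0L)) {
    stop_covtrace("configured grid lies outside the shared covariate range",
                  "config")
  }
  if (q == 1L) return(axes[[1L]])
  pts <- expand.grid(axes)
  lapply(seq_len(nrow(pts)), function(i) as.numeric(pts[i, ]))
}

#' @export
print.covtrace_analysis <- function(x, ...) {
  cat("covtrace analysis:", nrow(x$table), "trace rows,",
      sum(x$table$flag != "ok"), "flagged\n")
  cat("selected bandwidths: h0 =",
      paste(format(x$manifest$bandwidths$h0, digits = 4), collapse = ", "),
      "| h1 =",
      paste(format(x$manifest$bandwidths$h1, digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write analysis results and manifest
#'
#' Writes the significance-trace table as CSV (full precision, so a
#' write/read round trip preserves every value) and the manifest as JSON.
#'
#' @param analysis a [run_analysis()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_results <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "results.csv")
  man <- file.path(dir, "manifest.json")
  tab <- analysis$table
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                   csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(analysis$manifest, man, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(csv, man))
}
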