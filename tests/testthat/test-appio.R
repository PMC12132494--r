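# fixtures are small CSVs generated in code under tempdir()

make_toy_csv <- function(n = 120, seed = 42, missing_cell = FALSE,
                         zero_value = FALSE) {
  set.seed(seed)
  df <- data.frame(
    outcome = rep(c("neg", "pos"), each = n / 2),
    b1 = exp(rnorm(n, 1)), b2 = exp(rnorm(n, 2)),
    age = runif(n, 55, 90))
  if (missing_cell) df$b1[3] <- NA
  if (zero_value) df$b2[5] <- 0
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

toy_config <- function(path, ...) {
  analysis_config(
    data = path, group_column = "outcome",
    group_levels = c("neg", "pos"),
    response_columns = c("b1", "b2"),
    continuous_covariates = "age",
    grid = list(start = 60, stop = 85, step = 5),
    methods = "tracy_widom", B = 50, seed = 3,
    bandwidths = list(h0 = 8, h1 = 8, mean_h0 = 10, mean_h1 = 10), ...)
}

test_that("preprocessing standardizes per group and logs drops", {
  path <- make_toy_csv()
  cfg <- toy_config(path, log_transform = TRUE)
  gs <- load_and_preprocess(config = cfg)
  expect_equal(gs$dropped, 0L)
  for (g in list(gs$group0, gs$group1)) {
    expect_lt(max(abs(colMeans(g$x))), 1e-10)
    expect_lt(max(abs(apply(g$x, 2, var) - 1)), 1e-10)
  }
  # one missing cell: that row is dropped and counted
  path2 <- make_toy_csv(missing_cell = TRUE)
  cfg2 <- toy_config(path2)
  expect_message(gs2 <- load_and_preprocess(config = cfg2), "dropped 1")
  expect_equal(gs2$dropped, 1L)
  expect_equal(gs2$group0$n + gs2$group1$n, 119L)
  # nonpositive value under a log flag is a fatal data error naming the row
  path3 <- make_toy_csv(zero_value = TRUE)
  cfg3 <- toy_config(path3, log_transform = TRUE)
  expect_error(load_and_preprocess(config = cfg3), class = "covtrace_data")
  # absent configured column is a fatal config error
  cfg4 <- toy_config(path)
  cfg4$response_columns <- c("b1", "nope")
  expect_error(load_and_preprocess(config = cfg4), class = "covtrace_config")
})

test_that("configured analysis is deterministic and row-accounted", {
  # simlab-generated CSV under the null
  g1 <- simulate_group_1d(150, 0.5, seed = 21)
  g2 <- simulate_group_1d(150, 0.5, seed = 22)
  df <- rbind(data.frame(grp = "a", y1 = g1$x[, 1], y2 = g1$x[, 2],
                         u = g1$u[, 1]),
              data.frame(grp = "b", y1 = g2$x[, 1], y2 = g2$x[, 2],
                         u = g2$u[, 1]))
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  cfg <- analysis_config(
    data = path, group_column = "grp", group_levels = c("a", "b"),
    response_columns = c("y1", "y2"), continuous_covariates = "u",
    grid = list(start = -0.8, stop = 0.8, step = 0.2),
    methods = "permutation", B = 60, seed = 5,
    bandwidths = list(h0 = 0.7, h1 = 0.7, mean_h0 = 0.7, mean_h1 = 0.7))
  res <- run_analysis(cfg)
  res2 <- run_analysis(cfg)
  expect_identical(res$table, res2$table)    # same config + seed -> same table
  expect_equal(nrow(res$table), 9L)          # one method x 9 grid points
  expect_true(all(res$table$flag == "ok"))
  # null data: the fraction of p < alpha rows should be small
  expect_lt(mean(res$table$p_value < 0.05), 0.4)
  # round trip: writing then reading the results CSV preserves all values
  out <- write_results(res, tempfile())
  back <- read.csv(out[1])
  expect_equal(back$p_value, res$table$p_value, tolerance = 0)
  expect_equal(back$statistic, res$table$statistic, tolerance = 0)
  # manifest records what a rerun needs
  expect_equal(res$manifest$bandwidths$h0, 0.7)
  expect_equal(res$manifest$config$seed, 5L)
})

test_that("JSON config round trip preserves the analysis definition", {
  path <- make_toy_csv()
  cfg <- toy_config(path)
  jf <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), jf, auto_unbox = TRUE, digits = NA)
  cfg2 <- read_config(jf)
  expect_equal(cfg2$response_columns, cfg$response_columns)
  expect_equal(cfg2$grid, cfg$grid)
  expect_equal(cfg2$B, cfg$B)
})

test_that("categorical covariates produce per-level traces with count checks", {
  set.seed(8)
  n <- 200
  mk <- function(seed) {
    g <- simulate_group_1d(n, 0.5, seed = seed)
    data.frame(y1 = g$x[, 1], y2 = g$x[, 2], u = g$u[, 1],
               sex = sample(c("F", "M"), n, TRUE))
  }
  df <- rbind(cbind(grp = "a", mk(31)), cbind(grp = "b", mk(32)))
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  cfg <- analysis_config(
    data = path, group_column = "grp", group_levels = c("a", "b"),
    response_columns = c("y1", "y2"), continuous_covariates = "u",
    categorical_covariates = "sex",
    grid = list(start = -0.5, stop = 0.5, step = 0.5),
    methods = "tracy_widom", B = 10, seed = 9,
    bandwidths = list(h0 = 0.8, h1 = 0.8, mean_h0 = 0.8, mean_h1 = 0.8),
    min_level_count = 30)
  res <- run_analysis(cfg)
  expect_setequal(unique(res$table$level), c("F", "M"))
  expect_equal(nrow(res$table), 2 * 3)
})
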