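test_that("infinite-bandwidth NW covariance equals pooled residual covariance", {
  set.seed(21)
  for (rep in 1:3) {
    n <- 60
    g <- simulate_group_1d(n, 0.6)
    h_big <- 1e6 * diff(range(g$u))
    bw <- bandwidth_spec(h_big, mean_h = 0.5)
    E <- residuals(condcov(sample = g, bandwidth = h_big,
                           mean_bandwidth = 0.5))
    got <- nw_cond_cov(g, 0.1, bw)$sigma
    expect_lt(max(abs(got - naive_wcov(E, rep(1, n)))), 1e-8)
  }
})

test_that("a structurally zero response column yields zero rows and columns", {
  set.seed(3)
  u <- runif(50, -1, 1)
  g <- group_sample(cbind(rnorm(50), 0, rnorm(50)), u)
  bw <- bandwidth_spec(0.4, mean_h = 0.4)
  for (u0 in c(-0.5, 0, 0.5)) {
    S <- nw_cond_cov(g, u0, bw)$sigma
    expect_equal(unname(S[2, ]), rep(0, 3))
    expect_equal(unname(S[, 2]), rep(0, 3))
  }
})

test_that("lambda = 1 estimation equals stratified estimation exactly", {
  set.seed(9)
  n <- 80
  u <- runif(n, -1, 1)
  sex <- factor(sample(c("F", "M"), n, replace = TRUE))
  x <- matrix(rnorm(2 * n), n, 2)
  g <- group_sample(x, u, data.frame(sex = sex))
  bw <- bandwidth_spec(0.5, mean_h = 0.6, lambda = 1)
  for (lev in c("F", "M")) {
    sub <- group_sample(x[sex == lev, ], u[sex == lev])
    bw1 <- bandwidth_spec(0.5, mean_h = 0.6)
    for (u0 in c(-0.3, 0.2)) {
      mixed <- nw_cond_cov(g, u0, bw, level = list(sex = lev))
      strat <- nw_cond_cov(sub, u0, bw1)
      expect_equal(mixed$sigma, strat$sigma, tolerance = 1e-12)
    }
  }
})

test_that("estimated conditional covariances are symmetric PSD", {
  set.seed(31)
  for (rep in 1:5) {
    g <- simulate_group_1d(70, runif(1))
    bw <- bandwidth_spec(runif(1, 0.2, 1), mean_h = 0.5)
    S <- nw_cond_cov(g, runif(1, -0.8, 0.8), bw)$sigma
    expect_equal(S, t(S), tolerance = 1e-12)
    expect_gte(min(eigen(S, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("covariance bandwidth CV matches a naive recomputation of the criterion", {
  g <- simulate_group_1d(100, 0.5, seed = 77)
  grid <- c(0.3, 0.6, 1.0, 1.6)
  bw <- cv_cov_bandwidth(g, grid, mean_h = 0.6)
  E <- g$x - fitted(condcov(sample = g, bandwidth = 1, mean_bandwidth = 0.6))
  naive <- vapply(grid, function(h) naive_cv_criterion(g, h, E), numeric(1))
  expect_equal(bw$h, grid[which.min(naive)])
  # reported criterion values agree with the naive double loop
  cvtab <- attr(bw, "cv")
  expect_equal(cvtab$score, naive, tolerance = 1e-8)
  # duplicate grid entries do not change the answer
  bw2 <- cv_cov_bandwidth(g, c(grid, rev(grid)), mean_h = 0.6)
  expect_equal(bw2$h, bw$h)
  # singleton grid returns that element
  expect_equal(cv_cov_bandwidth(g, 0.8, mean_h = 0.6)$h, 0.8)
})

test_that("cond_cov_curve matches pointwise calls and flags out-of-range points", {
  g <- simulate_group_1d(90, 0.5, seed = 12)
  bw <- bandwidth_spec(0.5, mean_h = 0.5)
  curve <- cond_cov_curve(g, c(-0.5, 0, 0.5), bw)
  expect_length(curve, 3L)
  for (k in 1:3) {
    direct <- nw_cond_cov(g, c(-0.5, 0, 0.5)[k], bw)
    expect_equal(curve[[k]]$sigma, direct$sigma)
    expect_true(curve[[k]]$ok)
  }
  far <- cond_cov_curve(g, c(500, 900), bw)
  expect_false(any(vapply(far, `[[`, logical(1), "ok")))
  expect_error(cond_cov_curve(g, numeric(0), bw),
               class = "covtrace_invalid_parameter")
})

test_that("off-diagonal estimate is consistent for the 1-D design", {
  # theta = 0.5 at u = 0.5: true off-diagonal 0.25
  est <- vapply(1:10, function(r) {
    g <- simulate_group_1d(5000, 0.5, seed = 100 + r)
    bw <- bandwidth_spec(0.2, mean_h = 0.5)
    nw_cond_cov(g, 0.5, bw)$sigma[1, 2]
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.25), 3 * mc_se + 1e-12)
})

test_that("condcov fit object exposes coherent methods", {
  g <- simulate_group_1d(120, 0.5, seed = 8)
  fit <- condcov(sample = g, bandwidth = 0.6, mean_bandwidth = 0.6)
  expect_s3_class(fit, "condcov")
  expect_equal(dim(residuals(fit)), c(120L, 2L))
  expect_equal(fitted(fit) + residuals(fit), g$x)
  cc <- predict(fit, 0.3)
  expect_s3_class(cc, "cond_cov")
  expect_equal(dim(cc$sigma), c(2L, 2L))
  expect_gt(cc$ess, 0)
  expect_lte(cc$ess, 120)
  expect_output(print(fit), "Nadaraya-Watson")
  # formula interface builds the same fit
  df <- data.frame(y1 = g$x[, 1], y2 = g$x[, 2], age = g$u[, 1])
  fit2 <- condcov(cbind(y1, y2) ~ age, data = df, bandwidth = 0.6,
                  mean_bandwidth = 0.6)
  expect_equal(predict(fit2, 0.3)$sigma, cc$sigma, ignore_attr = TRUE)
})
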