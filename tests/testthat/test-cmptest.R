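test_that("combined matrix eigenvalues match closed forms and the naive route", {
  S <- random_spd(3)
  # equal covariances, equal sizes: every eigenvalue 1/2
  ce <- combined_matrix(S, S, 50, 50)
  expect_equal(ce$eigenvalues, rep(0.5, 3), tolerance = 1e-10)
  # equal covariances, n1 = 3 n0: all eigenvalues 3/4
  expect_equal(combined_matrix(S, S, 10, 30)$eigenvalues, rep(0.75, 3),
               tolerance = 1e-10)
  # S0 = I, S1 = diag(2, 1): eigenvalues 2/3 and 1/2
  ce2 <- combined_matrix(diag(2), diag(c(2, 1)), 7, 7)
  expect_equal(ce2$eigenvalues, c(2 / 3, 1 / 2), tolerance = 1e-12)
  # trace identity and [0, 1] range on random fixtures; agreement with the
  # explicit-inverse oracle
  set.seed(14)
  for (p in c(2, 3)) {
    for (rep in 1:4) {
      S0 <- random_spd(p); S1 <- random_spd(p)
      n0 <- sample(5:50, 1); n1 <- sample(5:50, 1)
      ce <- combined_matrix(S0, S1, n0, n1)
      expect_equal(sum(ce$eigenvalues), sum(diag(ce$Z)), tolerance = 1e-10)
      expect_true(all(ce$eigenvalues >= 0 & ce$eigenvalues <= 1))
      expect_equal(ce$eigenvalues, naive_combined_eigen(S0, S1, n0, n1),
                   tolerance = 1e-10)
    }
  }
})

test_that("Tracy-Widom centering/scaling follows the arcsin relations", {
  p <- 2; n0 <- 500; n1 <- 500
  tp <- tw_centering_scaling(p, n0, n1)
  N <- n0 + n1 - 1
  gamma <- 2 * asin(sqrt((min(p, n1) - 0.5) / N))
  phi <- 2 * asin(sqrt((max(p, n1) - 0.5) / N))
  expect_equal(tp$gamma, gamma, tolerance = 1e-14)
  expect_equal(tp$phi, phi, tolerance = 1e-14)
  expect_equal(tp$mu, 2 * log(tan((gamma + phi) / 2)), tolerance = 1e-14)
  expect_equal(tp$sigma^3,
               16 / N^2 / (sin(gamma + phi)^2 * sin(gamma) * sin(phi)),
               tolerance = 1e-12)
  # sigma strictly decreases as the total size grows with p fixed
  sig <- vapply(c(50, 100, 200, 400, 800, 1600),
                function(n) tw_centering_scaling(2, n, n)$sigma, numeric(1))
  expect_true(all(diff(sig) < 0))
  # equal sizes: swapping the group labels leaves (mu, sigma) unchanged
  tp_sw <- tw_centering_scaling(p, n1, n0)
  expect_equal(c(tp$mu, tp$sigma), c(tp_sw$mu, tp_sw$sigma))
  expect_error(tw_centering_scaling(10, 4, 5),
               class = "covtrace_invalid_parameter")
})

test_that("TW1 shifted-gamma approximation matches published quantiles", {
  # 0.95 quantile of TW1 is 0.9793 (to 1e-3); check CDF limits and shape
  expect_equal(qtw1(0.95), 0.9793, tolerance = 1e-3)
  expect_equal(ptw1(qtw1(0.5)), 0.5, tolerance = 1e-12)
  expect_equal(ptw1(-1e6), 0)
  expect_equal(ptw1(1e6), 1)
  tgrid <- seq(-5, 4, by = 0.5)
  expect_true(all(diff(ptw1(tgrid)) > 0))  # p-value monotone in t
})

test_that("Tracy-Widom test is calibrated on plain Gaussian covariances", {
  n <- 500; p <- 2
  rej <- vapply(1:200, function(r) {
    set.seed(4000 + r)
    X0 <- matrix(rnorm(n * p), n, p); X1 <- matrix(rnorm(n * p), n, p)
    S0 <- crossprod(scale(X0, scale = FALSE)) / n
    S1 <- crossprod(scale(X1, scale = FALSE)) / n
    tracy_widom_test(S0, S1, n, n)$p_value < 0.05
  }, logical(1))
  # exact binomial 95% interval around 0.05 for 200 draws: [4, 17] successes
  expect_gte(sum(rej), qbinom(0.025, 200, 0.05))
  expect_lte(sum(rej), qbinom(0.975, 200, 0.05))
})

test_that("Forkman test statistic and p-value honor their lattice and bounds", {
  S <- random_spd(2)
  # equal inputs, equal n: statistic exactly 1/2
  r <- forkman_test(S, S, 40, 40, B = 25, seed = 1)
  expect_equal(r$statistic, 0.5)
  expect_true(r$statistic >= 1 / 2 && r$statistic <= 1)
  expect_equal(r$p_value * 25, round(r$p_value * 25))  # 1/B lattice
  # bit-exact reproducibility under a fixed seed
  set.seed(101)
  S0 <- random_spd(2); S1 <- random_spd(2)
  a <- forkman_test(S0, S1, 60, 50, B = 500, seed = 9)
  b <- forkman_test(S0, S1, 60, 50, B = 500, seed = 9)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$t_null, b$t_null)
  expect_true(all(a$t_null >= 0.5 - 1e-12 & a$t_null <= 1 + 1e-12))
  expect_error(forkman_test(S0, S1, 60, 50, B = 0),
               class = "covtrace_invalid_parameter")
})

test_that("permutation test: lattice, determinism and label-swap symmetry", {
  g1 <- simulate_group_1d(80, 0.5, seed = 2)
  g2 <- simulate_group_1d(80, 0.5, seed = 3)
  f1 <- condcov(sample = g1, bandwidth = 0.7, mean_bandwidth = 0.7)
  f2 <- condcov(sample = g2, bandwidth = 0.7, mean_bandwidth = 0.7)
  r1 <- permutation_test(f1, f2, 0.2, B = 1, seed = 4)
  expect_true(r1$p_value %in% c(0, 1))
  a <- permutation_test(f1, f2, 0.2, B = 60, seed = 5)
  b <- permutation_test(f1, f2, 0.2, B = 60, seed = 5)
  expect_identical(a$t_null, b$t_null)
  # relabeled call under the same seed: same null multiset (equal sizes and
  # bandwidths make the pseudo-group partition identical)
  sw <- permutation_test(f2, f1, 0.2, B = 60, seed = 5)
  expect_equal(sort(sw$t_null), sort(a$t_null), tolerance = 1e-12)
})

test_that("null largest eigenvalue is inflated above 1/2 on average", {
  lam <- vapply(1:10, function(r) {
    ga <- simulate_group_1d(300, 0.5, seed = 600 + 2 * r)
    gb <- simulate_group_1d(300, 0.5, seed = 601 + 2 * r)
    bw <- bandwidth_spec(0.8, mean_h = 0.8)
    combined_matrix(nw_cond_cov(ga, 0, bw)$sigma,
                    nw_cond_cov(gb, 0, bw)$sigma,
                    300, 300)$eigenvalues[1]
  }, numeric(1))
  mc_se <- sd(lam) / sqrt(length(lam))
  expect_gte(mean(lam), 0.5 - 3 * mc_se)
})

test_that("significance trace is consistent with direct calls and deterministic", {
  g1 <- simulate_group_1d(90, 0.5, seed = 6)
  g2 <- simulate_group_1d(90, 1, seed = 7)
  f1 <- condcov(sample = g1, bandwidth = 0.8, mean_bandwidth = 0.8)
  f2 <- condcov(sample = g2, bandwidth = 0.8, mean_bandwidth = 0.8)
  tr <- significance_trace(f1, f2, grid_u = 0.4, methods = "forkman",
                           B = 80, seed = 11)
  expect_equal(nrow(tr), 1L)
  # the trace derives the first row's substream from (seed, 1)
  direct <- condcov_test(f1, f2, 0.4, method = "forkman", B = 80,
                         seed = covtrace:::sub_seed(11, 1))
  expect_equal(tr$statistic, direct$statistic)
  expect_equal(tr$p_value, direct$p_value)
  tr2 <- significance_trace(f1, f2, grid_u = c(-0.5, 0, 0.5),
                            methods = c("tracy_widom", "permutation"),
                            B = 50, seed = 13)
  tr3 <- significance_trace(f1, f2, grid_u = c(-0.5, 0, 0.5),
                            methods = c("tracy_widom", "permutation"),
                            B = 50, seed = 13)
  expect_identical(tr2, tr3)
  expect_equal(nrow(tr2), 6L)
  expect_true(all(tr2$flag == "ok"))
  expect_true(all(tr2$p_value >= 0 & tr2$p_value <= 1))
})
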