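#' Simulate one group of the single-covariate design
#'
#' Draws `U ~ Uniform(-1, 1)` and, conditionally on `U = u`, a bivariate
#' normal response with zero means, unit variances and correlation
#' `rho(u) = theta * u`. The bivariate normal is generated through the
#' closed-form Cholesky factor of the 2 x 2 correlation matrix:
#' `x1 = z1`, `x2 = rho z1 + sqrt(1 - rho^2) z2`.
#'
#' @param n sample size.
#' @param theta correlation slope in `[0, 1]`.
#' @param seed optional integer seed (restores the ambient RNG stream).
#' @return a [group_sample()] with `p = 2` responses and one covariate.
#' @export
simulate_group_1d <- function(n, theta, seed = NULL) {
  if (theta < 0 || theta > 1) {
    stop_covtrace("theta must lie in [0, 1]", "invalid_parameter")
  }
  with_seed(seed, {
    U <- stats::runif(n, -1, 1)
    rho <- theta * U
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    group_sample(cbind(x1 = z1, x2 = rho * z1 + sqrt(1 - rho^2) * z2), U)
  })
}

#' Simulate one group of the two-covariate design
#'
#' Two independent `Uniform(0, 1)` covariates; the response correlation is
#' `rho = theta * (U1 - U2)`, which vanishes on the diagonal `U1 = U2` and
#' ranges over `(-theta, theta)`.
#'
#' @inheritParams simulate_group_1d
#' @return a [group_sample()] with `p = 2` responses and `q = 2` covariates.
#' @export
simulate_group_2d <- function(n, theta, seed = NULL) {
  if (theta < 0 || theta > 1) {
    stop_covtrace("theta must lie in [0, 1]", "invalid_parameter")
  }
  with_seed(seed, {
    U1 <- stats::runif(n); U2 <- stats::runif(n)
    rho <- theta * (U1 - U2)
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    group_sample(cbind(x1 = z1, x2 = rho * z1 + sqrt(1 - rho^2) * z2),
                 cbind(u1 = U1, u2 = U2))
  })
}

#' Analytic largest combined eigenvalue of the single-covariate design
#'
#' With true correlation matrices
#' `Sigma_j(u) = [[1, theta_j u], [theta_j u, 1]]`, the combined matrix
#' `Z(u) = (Sigma_1 + r Sigma_2)^{-1} r Sigma_2` (`r` = ratio of the second
#' group's size to the first) has closed-form eigenvalues because all 2 x 2
#' correlation matrices share the eigenvectors `(1, 1)` and `(1, -1)`:
#' `r (1 +/- rho_2) / ((1 +/- rho_1) + r (1 +/- rho_2))`. When
#' `theta_1 = theta_2` and `r = 1` both eigenvalues are 1/2 for every `u`.
#'
#' @param theta1,theta2 correlation slopes of the two groups.
#' @param u covariate value(s) in `[-1, 1]` (vectorized).
#' @param n_ratio size ratio `n2/n1`, default 1.
#' @return numeric vector of largest eigenvalues.
#' @export
true_combined_eigen_1d <- function(theta1, theta2, u, n_ratio = 1) {
  rho1 <- theta1 * u; rho2 <- theta2 * u
  if (any(abs(rho1) >= 1) || any(abs(rho2) >= 1)) {
    stop_covtrace("|theta * u| must be < 1", "invalid_parameter")
  }
  r <- n_ratio
  lp <- r * (1 + rho2) / ((1 + rho1) + r * (1 + rho2))
  lm <- r * (1 - rho2) / ((1 - rho1) + r * (1 - rho2))
  pmax(lp, lm)
}

#' Define a simulation study
#'
#' Collects the parameters of a type-I error / power / eigenvalue-accuracy
#' experiment. Presets mirror the study conditions: `"paper"` uses
#' n = 1000 per group with 100 repetitions (n = 5000, 50 repetitions for
#' eigenvalue accuracy); `"ci"` is a scaled-down variant (n = 500,
#' 25 repetitions) labeled as such in outputs.
#'
#' @param dim covariate dimension, 1 or 2.
#' @param n per-group sample size.
#' @param theta1,theta2 correlation slopes in `[0, 1]`.
#' @param reps number of repetitions.
#' @param seed integer seed; repetition r uses substreams derived from
#'   `seed + r`.
#' @param grid_u covariate evaluation points (numeric vector for `dim = 1`,
#'   list of length-2 points for `dim = 2`).
#' @param h_grid covariance bandwidths to sweep.
#' @param alpha nominal significance level.
#' @param B resampling size for the bootstrap/permutation tests.
#' @param preset `"custom"`, `"paper"` or `"ci"`; a named preset fills any
#'   of `n` and `reps` left `NULL`.
#' @return an object of class `"sim_design"`.
#' @export
sim_design <- function(dim = 1L, n = NULL, theta1 = 0.5, theta2 = 0.5,
                       reps = NULL, seed = 1L,
                       grid_u = if (dim == 1L) c(-1, -0.5, 0, 0.5, 1)
                                else list(c(0.25, 0.75), c(0.5, 0.5),
                                          c(0.75, 0.25)),
                       h_grid = 1, alpha = 0.05, B = 199L,
                       preset = c("custom", "paper", "ci")) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    if (is.null(n)) n <- 1000L
    if (is.null(reps)) reps <- 100L
  } else if (preset == "ci") {
    if (is.null(n)) n <- 500L
    if (is.null(reps)) reps <- 25L
  }
  if (is.null(n) || is.null(reps)) {
    stop_covtrace("supply n and reps (or choose a preset)",
                  "invalid_parameter")
  }
  if (n < 10L || reps < 1L) {
    stop_covtrace("need n >= 10 and reps >= 1", "invalid_parameter")
  }
  if (theta1 < 0 || theta1 > 1 || theta2 < 0 || theta2 > 1) {
    stop_covtrace("theta1, theta2 must lie in [0, 1]", "invalid_parameter")
  }
  structure(list(dim = as.integer(dim), n = as.integer(n), theta1 = theta1,
                 theta2 = theta2, reps = as.integer(reps),
                 seed = as.integer(seed), grid_u = grid_u, h_grid = h_grid,
                 alpha = alpha, B = as.integer(B), preset = preset),
            class = "sim_design")
}

## simulate the pair of groups for repetition r of a design
.sim_pair <- function(design, r) {
  s0 <- sub_seed(design$seed, 2 * r)
  s1 <- sub_seed(design$seed, 2 * r + 1)
  if (design$dim == 1L) {
    list(g1 = simulate_group_1d(design$n, design$theta1, s0),
         g2 = simulate_group_1d(design$n, design$theta2, s1))
  } else {
    list(g1 = simulate_group_2d(design$n, design$theta1, s0),
         g2 = simulate_group_2d(design$n, design$theta2, s1))
  }
}

## quick fit with fixed bandwidths (mean bandwidth selected by LOO CV once)
.harness_fit <- function(sample, h) {
  mh <- as.numeric(select_mean_bandwidth(sample))
  condcov(sample = sample, bandwidth = h, mean_bandwidth = mh)
}

#' Run a rejection-rate study (type-I error / power)
#'
#' For each repetition, simulates both groups of the design, fits the
#' conditional covariance machinery, and runs the requested tests at every
#' combination of grid point and bandwidth, recording rejections at the
#' design's nominal level. Rows where the two groups truly share a
#' covariance (equal thetas; or `u = 0` in the 1-D design, `u1 = u2` in the
#' 2-D design) are labeled `type_I_error`, the rest `power`.
#'
#' @param design a [sim_design()].
#' @param methods subset of
#'   `c("permutation", "forkman", "tracy_widom")`.
#' @return a tidy data.frame: one row per (u, h, method) with columns
#'   `dim, n, theta1, theta2, u (or u1, u2), h, method, metric, value,
#'   rep_count, failures, seed, preset`.
#' @export
run_rejection_study <- function(design,
                                methods = c("permutation", "forkman",
                                            "tracy_widom")) {
  methods <- match.arg(methods, several.ok = TRUE)
  pts <- if (is.list(design$grid_u)) design$grid_u
         else as.list(as.numeric(design$grid_u))
  combos <- expand.grid(pt = seq_along(pts),
                        h = seq_along(design$h_grid),
                        m = seq_along(methods))
  rej <- matrix(0, nrow(combos), design$reps)
  ok <- matrix(FALSE, nrow(combos), design$reps)
  for (r in seq_len(design$reps)) {
    pair <- .sim_pair(design, r)
    fit1 <- tryCatch(.harness_fit(pair$g1, design$h_grid[[1L]]),
                     covtrace_error = function(e) NULL)
    fit2 <- tryCatch(.harness_fit(pair$g2, design$h_grid[[1L]]),
                     covtrace_error = function(e) NULL)
    if (is.null(fit1) || is.null(fit2)) next
    for (ci in seq_len(nrow(combos))) {
      h <- design$h_grid[[combos$h[ci]]]
      fit1$bandwidth$h <- rep(as.numeric(h), length.out = design$dim)
      fit2$bandwidth$h <- rep(as.numeric(h), length.out = design$dim)
      res <- tryCatch(
        condcov_test(fit1, fit2, pts[[combos$pt[ci]]],
                     method = methods[combos$m[ci]], B = design$B,
                     seed = sub_seed(design$seed, r * 1000 + ci)),
        covtrace_error = function(e) NULL)
      if (!is.null(res) && is.finite(res$p_value)) {
        ok[ci, r] <- TRUE
        rej[ci, r] <- as.numeric(res$p_value <= design$alpha)
      }
    }
  }
  fail_frac <- 1 - rowMeans(ok)
  if (any(fail_frac > 0.05)) {
    stop_covtrace(
      sprintf("estimator failures in %.1f%% of repetitions (max allowed 5%%)",
              100 * max(fail_frac)), "too_many_failures")
  }
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(ci) {
    u0 <- as.numeric(pts[[combos$pt[ci]]])
    is_null <- design$theta1 == design$theta2 ||
      (design$dim == 1L && u0[1L] == 0) ||
      (design$dim == 2L && u0[1L] == u0[2L])
    ucols <- as.list(u0)
    names(ucols) <- if (length(u0) == 1L) "u" else paste0("u", seq_along(u0))
    as.data.frame(c(
      list(dim = design$dim, n = design$n, theta1 = design$theta1,
           theta2 = design$theta2),
      ucols,
      list(h = paste(format(design$h_grid[[combos$h[ci]]], digits = 6),
                     collapse = "/"),
           method = methods[combos$m[ci]],
           metric = if (is_null) "type_I_error" else "power",
           value = mean(rej[ci, ok[ci, ]]),
           rep_count = sum(ok[ci, ]),
           failures = design$reps - sum(ok[ci, ]),
           seed = design$seed, preset = design$preset)))
  }))
  rownames(out) <- NULL
  out
}

#' Run an eigenvalue-accuracy study
#'
#' For each repetition, simulates both groups, selects the covariance
#' bandwidth per group by the leave-one-out log-likelihood criterion over
#' `design$h_grid`, and records the estimated largest combined eigenvalue at
#' each grid point. Aggregates to the mean and spread across repetitions and
#' attaches the analytic truth from [true_combined_eigen_1d()].
#'
#' @param design a [sim_design()] with `dim = 1`.
#' @return a tidy data.frame with one row per grid point and metric
#'   (`lambda1_mean`, `lambda1_sd`, `lambda1_truth`).
#' @export
run_eigen_accuracy <- function(design) {
  if (design$dim != 1L) {
    stop_covtrace("eigenvalue-accuracy study is defined for dim = 1",
                  "invalid_parameter")
  }
  grid_u <- as.numeric(design$grid_u)
  lam <- matrix(NA_real_, length(grid_u), design$reps)
  for (r in seq_len(design$reps)) {
    pair <- .sim_pair(design, r)
    est <- tryCatch({
      f1 <- .accuracy_fit(pair$g1, design$h_grid)
      f2 <- .accuracy_fit(pair$g2, design$h_grid)
      vapply(grid_u, function(u0) {
        c1 <- predict(f1, u0); c2 <- predict(f2, u0)
        combined_matrix(c1$sigma, c2$sigma, design$n,
                        design$n)$eigenvalues[1L]
      }, numeric(1))
    }, covtrace_error = function(e) NULL)
    if (!is.null(est)) lam[, r] <- est
  }
  okrep <- colSums(is.na(lam)) == 0L
  if (mean(!okrep) > 0.05) {
    stop_covtrace("estimator failures in more than 5% of repetitions",
                  "too_many_failures")
  }
  lam <- lam[, okrep, drop = FALSE]
  out <- do.call(rbind, lapply(seq_along(grid_u), function(i) {
    truth <- true_combined_eigen_1d(design$theta1, design$theta2, grid_u[i])
    data.frame(
      dim = design$dim, n = design$n, theta1 = design$theta1,
      theta2 = design$theta2, u = grid_u[i],
      metric = c("lambda1_mean", "lambda1_sd", "lambda1_mae",
                 "lambda1_truth"),
      value = c(mean(lam[i, ]), stats::sd(lam[i, ]),
                mean(abs(lam[i, ] - truth)), truth),
      rep_count = ncol(lam), seed = design$seed, preset = design$preset)
  }))
  rownames(out) <- NULL
  out
}

## fit with CV-selected covariance bandwidth over the design's grid
.accuracy_fit <- function(sample, h_grid) {
  mh <- as.numeric(select_mean_bandwidth(sample))
  bw <- cv_cov_bandwidth(sample, h_grid, mean_h = mh)
  condcov(sample = sample, bandwidth = bw$h, mean_bandwidth = mh)
}
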