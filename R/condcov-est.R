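#' Nadaraya-Watson conditional covariance at a covariate point
#'
#' Kernel-weighted average of residual outer products
#' `(x_i - m(U_i))(x_i - m(U_i))'` with weights equal to the product of the
#' per-dimension continuous kernels times the Aitchison-Aitken categorical
#' kernel. The residuals use the mean fit at each sample's *own* covariate
#' value, so the estimate at `u` is a weighted sum of fixed outer products
#' and is symmetric positive semi-definite by construction.
#'
#' @param sample a [group_sample()].
#' @param u covariate point (continuous part), length-q numeric.
#' @param bw a [bandwidth_spec()] (or a single number, taken as both `h` and
#'   `mean_h`).
#' @param level target categorical level(s), required when `sample` has
#'   factor covariates.
#' @param residuals optional precomputed n x p residual matrix
#'   `x - m(U_i)`; computed from the mean estimator when `NULL`.
#' @param mean_estimator,family passed to the inner mean fit when residuals
#'   are computed here.
#' @return an object of class `"cond_cov"`: list with `u`, `level`, `sigma`
#'   (p x p), `total_weight` and `ess` (effective sample size
#'   `(sum w)^2 / sum w^2`).
#' @export
nw_cond_cov <- function(sample, u, bw, level = NULL, residuals = NULL,
                        mean_estimator = "local_linear",
                        family = "gaussian") {
  if (!inherits(bw, "bandwidth_spec")) bw <- bandwidth_spec(bw)
  if (is.null(residuals)) {
    residuals <- sample$x - .mean_fit_all(sample, bw$mean_h, bw$lambda,
                                          family, mean_estimator)
  }
  h <- if (length(bw$h) == 1L && sample$q > 1L) rep(bw$h, sample$q) else bw$h
  if (!is.null(sample$ucat) && is.null(level)) {
    stop_covtrace("sample has categorical covariates: supply level",
                  "invalid_parameter")
  }
  w <- .cont_weights(sample$u, u, h, family) *
    .cat_weights(sample$ucat, level, bw$lambda)
  .wcov_record(residuals, w, u, level, sample$n)
}

## weighted residual covariance from precomputed weights
.wcov_record <- function(E, w, u, level, n) {
  sw <- sum(w)
  if (!is.null(level) && sw == 0) {
    stop_covtrace("no sample carries weight at the requested factor level",
                  "empty_cell")
  }
  if (!is.finite(sw) || sw < n * 1e-12) {
    stop_covtrace("total kernel weight below degeneracy threshold at u",
                  "extrapolation")
  }
  sigma <- crossprod(E, w * E) / sw
  sigma <- (sigma + t(sigma)) / 2
  structure(list(u = u, level = level, sigma = sigma, total_weight = sw,
                 ess = sw^2 / sum(w^2)),
            class = "cond_cov")
}

#' @export
print.cond_cov <- function(x, ...) {
  cat("conditional covariance at u =",
      paste(format(x$u, digits = 4), collapse = ", "))
  if (!is.null(x$level)) {
    cat(" | level =", paste(unlist(x$level), collapse = ", "))
  }
  cat(sprintf("  (ess = %.1f)\n", x$ess))
  print(x$sigma, ...)
  invisible(x)
}

#' Conditional covariance along a covariate grid
#'
#' Evaluates [nw_cond_cov()] at each grid point, preserving order. Points
#' where the total kernel weight degenerates (outside the data range) are
#' returned as flagged entries (`ok = FALSE`, `sigma = NA`) rather than
#' aborting the whole curve.
#'
#' @inheritParams nw_cond_cov
#' @param grid_u list of covariate points, or a numeric vector for `q = 1`.
#' @return list of `"cond_cov"` records, each carrying an `ok` flag.
#' @export
cond_cov_curve <- function(sample, grid_u, bw, level = NULL,
                           residuals = NULL,
                           mean_estimator = "local_linear",
                           family = "gaussian") {
  if (length(grid_u) == 0L) {
    stop_covtrace("empty evaluation grid", "invalid_parameter")
  }
  if (!inherits(bw, "bandwidth_spec")) bw <- bandwidth_spec(bw)
  if (!is.list(grid_u)) grid_u <- as.list(grid_u)
  if (is.null(residuals)) {
    residuals <- sample$x - .mean_fit_all(sample, bw$mean_h, bw$lambda,
                                          family, mean_estimator)
  }
  lapply(grid_u, function(u0) {
    out <- tryCatch(
      nw_cond_cov(sample, u0, bw, level = level, residuals = residuals),
      covtrace_extrapolation = function(e) {
        structure(list(u = u0, level = level, sigma = NA, total_weight = 0,
                       ess = 0, ok = FALSE, message = conditionMessage(e)),
                  class = "cond_cov")
      })
    if (is.null(out$ok)) out$ok <- TRUE
    out
  })
}

#' Covariance bandwidth selection by the leave-one-out log-likelihood
#'
#' Scores each candidate bandwidth by the Gaussian leave-one-out criterion
#' `CV(h) = (1/n) sum_i [ e_i' S_(-i)(U_i)^{-1} e_i + log det S_(-i)(U_i) ]`,
#' where `e_i` are the full-sample mean residuals and `S_(-i)(U_i)` is the
#' conditional covariance at `U_i` computed without observation i. Candidates
#' whose leave-one-out estimate is numerically singular anywhere (condition
#' number above 1e12) score `+Inf`. Ties are broken toward the smallest
#' bandwidth.
#'
#' @param sample a [group_sample()] with `n >= p + 2`.
#' @param grid candidate covariance bandwidths: numeric vector for `q = 1`,
#'   or a list of length-q vectors (alternatively a numeric vector of
#'   multipliers of the per-dimension covariate standard deviations) for
#'   `q > 1`.
#' @param mean_h bandwidth(s) for the inner mean fit, frozen across
#'   candidates; selected by [select_mean_bandwidth()] when `NULL`.
#' @param lambda,family,mean_estimator as in [nw_cond_cov()].
#' @param jitter optional ridge `jitter * I` added inside the criterion's
#'   inverse only (default 0).
#' @param every score every `every`-th sample point (subsampled CV for large
#'   n); default 1 uses all points.
#' @return the selected [bandwidth_spec()], with the criterion table in
#'   attribute `"cv"`.
#' @export
cv_cov_bandwidth <- function(sample, grid, mean_h = NULL, lambda = 1,
                             family = "gaussian",
                             mean_estimator = "local_linear",
                             jitter = 0, every = 1L) {
  n <- sample$n; p <- sample$p; q <- sample$q
  if (n < p + 2L) {
    stop_covtrace("need n >= p + 2 for covariance bandwidth selection",
                  "invalid_parameter")
  }
  if (is.null(mean_h)) {
    mean_h <- as.numeric(select_mean_bandwidth(sample, lambda = lambda,
                                               family = family))
  }
  cand <- .normalize_cov_grid(grid, sample)
  E <- sample$x - .mean_fit_all(sample, mean_h, lambda, family,
                                mean_estimator)
  idx <- seq(1L, n, by = as.integer(every))
  W1 <- .pairwise_cat_weights(sample$ucat, lambda)
  score <- vapply(cand, function(h) {
    K <- .pairwise_cont_weights(sample$u, h, family) * W1
    diag(K) <- 0
    sw <- rowSums(K)
    tot <- 0
    for (i in idx) {
      if (sw[i] < (n - 1) * 1e-12) return(Inf)
      S <- crossprod(E, K[i, ] * E) / sw[i]
      S <- (S + t(S)) / 2
      if (jitter > 0) S <- S + diag(jitter, p)
      R <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(R)) return(Inf)
      dvals <- diag(R)
      if (min(dvals)^2 < max(dvals)^2 / 1e12) return(Inf)  # cond > 1e12
      z <- backsolve(R, E[i, ], transpose = TRUE)
      tot <- tot + sum(z^2) + 2 * sum(log(dvals))
    }
    tot / length(idx)
  }, numeric(1))
  if (all(!is.finite(score))) {
    stop_covtrace("every candidate bandwidth is non-invertible somewhere",
                  "no_valid_bandwidth")
  }
  best <- which(score == min(score))[1L]
  bw <- bandwidth_spec(cand[[best]], mean_h = mean_h, lambda = lambda)
  attr(bw, "cv") <- data.frame(
    h = vapply(cand, function(h) paste(format(h, digits = 6),
                                       collapse = "/"), character(1)),
    score = score)
  bw
}

## grid -> list of length-q bandwidth vectors, sorted ascending, deduplicated
.normalize_cov_grid <- function(grid, sample) {
  q <- sample$q
  if (is.list(grid)) {
    cand <- lapply(grid, function(h) {
      if (length(h) == 1L && q > 1L) h <- rep(h, q)
      as.numeric(h)
    })
  } else {
    if (length(grid) == 0L) stop_covtrace("empty grid", "invalid_parameter")
    if (q == 1L) {
      cand <- as.list(as.numeric(grid))
    } else {
      sds <- apply(sample$u, 2L, stats::sd)
      cand <- lapply(as.numeric(grid), function(g) g * sds)
    }
  }
  if (any(vapply(cand, function(h) any(!is.finite(h)) || any(h <= 0),
                 logical(1)))) {
    stop_covtrace("bandwidth grid entries must be positive",
                  "invalid_parameter")
  }
  cand <- unique(cand)
  ord <- do.call(order, as.data.frame(do.call(rbind, cand)))
  cand[ord]
}

## n x n matrix of product continuous kernel weights: K[i, j] = weight of j
## when estimating at U_i
.pairwise_cont_weights <- function(U, h, family) {
  n <- nrow(U)
  if (length(h) == 1L && ncol(U) > 1L) h <- rep(h, ncol(U))
  K <- matrix(1, n, n)
  for (j in seq_len(ncol(U))) {
    D <- outer(U[, j], U[, j], "-")
    K <- K * .kern(D / h[j], family) / h[j]
  }
  K
}

.pairwise_cat_weights <- function(ucat, lambda) {
  if (is.null(ucat) || ncol(ucat) == 0L) return(1)
  n <- nrow(ucat)
  W <- matrix(1, n, n)
  for (j in seq_along(ucat)) {
    lev <- as.integer(ucat[[j]])
    k <- nlevels(ucat[[j]])
    W <- W * ifelse(outer(lev, lev, "=="), lambda, (1 - lambda) / (k - 1))
  }
  W
}
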