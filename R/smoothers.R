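#' Local constant (Nadaraya-Watson) conditional mean
#'
#' Kernel-weighted average of the response rows with weights
#' `Kh(U_i - u)` (times the Aitchison-Aitken weight for any categorical
#' covariates). As `h` grows the estimate tends to the global column means.
#'
#' @param sample a [group_sample()].
#' @param u covariate point: length-q numeric vector (continuous part).
#' @param h bandwidth(s), one per continuous covariate dimension.
#' @param level target level(s) of the categorical covariates, if any.
#' @param lambda Aitchison-Aitken weight, default 1.
#' @param family kernel family.
#' @return an object of class `"mean_estimate"`: list with `u`, `m` (length-p
#'   vector) and `estimator`.
#' @export
local_constant_mean <- function(sample, u, h, level = NULL, lambda = 1,
                                family = c("gaussian", "epanechnikov")) {
  family <- match.arg(family)
  m <- .mean_at(sample$x, sample$u, sample$ucat, u, level, h, lambda,
                family, "local_constant")
  structure(list(u = u, m = m, estimator = "local_constant"),
            class = "mean_estimate")
}

#' Local linear conditional mean
#'
#' Fits a local degree-1 polynomial around `u` with kernel weights and
#' returns the intercept. Reproduces affine functions of the covariates
#' exactly for any bandwidth and has smaller boundary bias than the local
#' constant fit.
#'
#' @inheritParams local_constant_mean
#' @return an object of class `"mean_estimate"`.
#' @export
local_linear_mean <- function(sample, u, h, level = NULL, lambda = 1,
                              family = c("gaussian", "epanechnikov")) {
  family <- match.arg(family)
  m <- .mean_at(sample$x, sample$u, sample$ucat, u, level, h, lambda,
                family, "local_linear")
  structure(list(u = u, m = m, estimator = "local_linear"),
            class = "mean_estimate")
}

## single-point mean estimate; x n x p, U n x q
.mean_at <- function(x, U, ucat, u0, level, h, lambda, family, estimator) {
  n <- nrow(x)
  if (length(h) == 1L && ncol(U) > 1L) h <- rep(h, ncol(U))
  if (length(h) != ncol(U)) {
    stop_covtrace("need one bandwidth per continuous covariate dimension",
                  "invalid_parameter")
  }
  if (is.null(level) && !is.null(ucat)) {
    stop_covtrace("sample has categorical covariates: supply level",
                  "invalid_parameter")
  }
  w <- .cont_weights(U, u0, h, family) * .cat_weights(ucat, level, lambda)
  sw <- sum(w)
  if (!is.finite(sw) || sw < n * 1e-12) {
    stop_covtrace(
      "total kernel weight below degeneracy threshold: point outside the data range",
      "extrapolation")
  }
  if (estimator == "local_constant") {
    return(unname(drop(colSums(w * x) / sw)))
  }
  if (ncol(U) == 1L) {
    d <- U[, 1L] - u0[1L]
    S0 <- sum(w); S1 <- sum(d * w); S2 <- sum(d^2 * w)
    den <- S2 * S0 - S1^2
    if (!is.finite(den) || den <= max(S2 * S0, .Machine$double.xmin) * 1e-12) {
      stop_covtrace(
        "degenerate local neighborhood: need >= 2 distinct covariate values with positive weight",
        "degenerate")
    }
    wi <- (S2 - S1 * d) * w
    return(unname(drop(colSums(wi * x) / sum(wi))))
  }
  ## multivariate: weighted least squares; fitted value at u0 is the intercept
  Xd <- cbind(1, sweep(U, 2L, u0))
  A <- crossprod(Xd, w * Xd)
  b <- crossprod(Xd, w * x)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol) || rcond(A) < 1e-12) {
    stop_covtrace("rank-deficient local design at u", "degenerate")
  }
  unname(drop(sol[1L, ]))
}

## mean fit at every sample point (for residuals). Vectorized 1-D path;
## per-point loop for q > 1. loo = TRUE zeroes each point's own weight
## (used by bandwidth selection).
.mean_fit_all <- function(sample, h, lambda = 1, family = "gaussian",
                          estimator = "local_linear", loo = FALSE) {
  x <- sample$x; U <- sample$u; ucat <- sample$ucat; n <- sample$n
  if (length(h) == 1L && ncol(U) > 1L) h <- rep(h, ncol(U))
  if (sample$q == 1L) {
    ## block-wise over evaluation points to keep memory at O(block * n)
    out <- matrix(NA_real_, n, sample$p)
    blocks <- split(seq_len(n), ceiling(seq_len(n) / 1000L))
    for (I in blocks) {
      D <- outer(U[I, 1L], U[, 1L], "-")   # D[i, j] = U_I[i] - U_j
      K <- .kern(D / h[1L], family) / h[1L]  # symmetric: Kh(U_j - U_Ii)
      if (!is.null(ucat)) {
        for (jc in seq_along(ucat)) {
          lev <- as.integer(ucat[[jc]])
          k <- nlevels(ucat[[jc]])
          K <- K * ifelse(outer(lev[I], lev, "=="),
                          lambda, (1 - lambda) / (k - 1))
        }
      }
      if (loo) K[cbind(seq_along(I), I)] <- 0
      sw <- rowSums(K)
      bad_w <- sw < n * 1e-12
      if (estimator == "local_constant") {
        if (any(bad_w)) {
          stop_covtrace("degenerate neighborhood at a sample point",
                        "degenerate")
        }
        out[I, ] <- (K %*% x) / sw
      } else {
        S1 <- rowSums(K * (-D))            # sum_j (U_j - U_i) K
        S2 <- rowSums(K * D^2)
        Wnum <- (S2 + S1 * D) * K          # (S2 - S1 (U_j - U_i)) K
        den <- rowSums(Wnum)               # = S2*S0 - S1^2
        if (any(bad_w) || any(!is.finite(den)) ||
            any(den <= pmax(S2 * sw, .Machine$double.xmin) * 1e-12)) {
          stop_covtrace(
            "degenerate local-linear neighborhood at a sample point",
            "degenerate")
        }
        out[I, ] <- (Wnum %*% x) / den
      }
    }
    return(out)
  }
  out <- matrix(NA_real_, n, sample$p)
  for (i in seq_len(n)) {
    lev <- if (is.null(ucat)) NULL else lapply(ucat, function(z) z[i])
    xi <- x; Ui <- U; uci <- ucat
    if (loo) { xi <- x[-i, , drop = FALSE]; Ui <- U[-i, , drop = FALSE]
               if (!is.null(ucat)) uci <- ucat[-i, , drop = FALSE] }
    out[i, ] <- .mean_at(xi, Ui, uci, U[i, ], lev, h, lambda, family,
                         estimator)
  }
  out
}

#' Select the mean-estimator bandwidth by leave-one-out cross-validation
#'
#' Minimizes the leave-one-out squared prediction error of the chosen mean
#' estimator, summed over the p responses, on a bandwidth grid. The default
#' grid has 25 log-spaced points between 0.05 and 2 times the per-dimension
#' covariate standard deviation. Ties are broken toward the smallest
#' bandwidth; grid values that produce a degenerate neighborhood anywhere are
#' scored infinite.
#'
#' @param sample a [group_sample()] with `n >= 3`.
#' @param grid numeric vector: candidate bandwidths for `q = 1`, or
#'   multipliers of the per-dimension covariate standard deviations for
#'   `q > 1`. `NULL` for the default grid.
#' @param estimator `"local_linear"` (default) or `"local_constant"`.
#' @param lambda,family as in [local_linear_mean()].
#' @return the selected bandwidth: scalar for `q = 1`, length-q vector
#'   otherwise, with the CV score table in attribute `"cv"`.
#' @export
select_mean_bandwidth <- function(sample, grid = NULL,
                                  estimator = c("local_linear",
                                                "local_constant"),
                                  lambda = 1, family = "gaussian") {
  estimator <- match.arg(estimator)
  if (sample$n < 3L) {
    stop_covtrace("need n >= 3 for bandwidth selection", "invalid_parameter")
  }
  sds <- apply(sample$u, 2L, stats::sd)
  if (any(sds <= 0)) sds[sds <= 0] <- 1
  if (is.null(grid)) {
    grid <- exp(seq(log(0.05), log(2), length.out = 25L))
    if (sample$q == 1L) grid <- grid * sds[1L]
  }
  if (length(grid) < 1L) {
    stop_covtrace("empty bandwidth grid", "invalid_parameter")
  }
  grid <- sort(unique(grid))
  score <- vapply(grid, function(g) {
    h <- if (sample$q == 1L) g else g * sds
    m <- tryCatch(
      .mean_fit_all(sample, h, lambda, family, estimator, loo = TRUE),
      covtrace_error = function(e) NULL)
    if (is.null(m)) return(Inf)
    sum((sample$x - m)^2) / sample$n
  }, numeric(1))
  if (all(!is.finite(score))) {
    stop_covtrace("no valid bandwidth in the grid", "no_valid_bandwidth")
  }
  best <- which(score == min(score))[1L]   # grid sorted: smallest minimizer
  h <- if (sample$q == 1L) grid[best] else grid[best] * sds
  structure(h, cv = data.frame(grid = grid, score = score))
}
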