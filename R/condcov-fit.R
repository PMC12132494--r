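#' Fit a conditional covariance function
#'
#' The main model-fitting entry point. Fits the covariate-conditional
#' covariance function of a multivariate response for one group: a local
#' linear (default) or local constant mean fit produces residuals, and the
#' conditional covariance at any covariate value is the Nadaraya-Watson
#' kernel-weighted average of the residual outer products. Bandwidths are
#' selected automatically when not supplied: the mean bandwidth by
#' leave-one-out squared-error cross-validation and the covariance bandwidth
#' by the leave-one-out Gaussian log-likelihood criterion.
#'
#' @param formula a formula of the form
#'   `cbind(y1, y2, ...) ~ u1 + u2 + factor1`: a multi-column response on the
#'   left and covariates on the right. Factor (or character) terms are
#'   treated as categorical covariates smoothed with the Aitchison-Aitken
#'   kernel; the remaining terms are continuous.
#' @param data a data.frame containing the variables.
#' @param bandwidth covariance bandwidth(s) `h` (one per continuous
#'   covariate), or `NULL` to select by [cv_cov_bandwidth()].
#' @param mean_bandwidth mean-fit bandwidth(s), or `NULL` to select by
#'   [select_mean_bandwidth()].
#' @param lambda Aitchison-Aitken weight for categorical covariates,
#'   default 1 (stratified estimation).
#' @param kernel kernel family: `"gaussian"` (default) or `"epanechnikov"`.
#' @param mean_estimator `"local_linear"` (default) or `"local_constant"`.
#' @param h_grid candidate grid for covariance bandwidth selection (see
#'   [cv_cov_bandwidth()]); `NULL` for a default log-spaced grid of 10 points
#'   between 0.1 and 2 times the covariate standard deviation.
#' @param standardize if `TRUE`, standardize each response column to zero
#'   mean and unit variance before fitting (the comparison tests assume
#'   standardized responses).
#' @param sample alternatively to `formula`/`data`, a ready
#'   [group_sample()].
#' @return an object of class `"condcov"` with components `sample`,
#'   `bandwidth` (a [bandwidth_spec()]), `residuals`, `mean_fit`,
#'   `mean_estimator`, `kernel` and `call`. Methods: [predict.condcov()],
#'   [print.condcov()], `summary`, `residuals`, `fitted`, [plot.condcov()].
#' @examples
#' g <- simulate_group_1d(200, theta = 0.5, seed = 1)
#' fit <- condcov(sample = g, bandwidth = 0.6, mean_bandwidth = 0.6)
#' predict(fit, u = 0.5)
#' @export
condcov <- function(formula = NULL, data = NULL, bandwidth = NULL,
                    mean_bandwidth = NULL, lambda = 1,
                    kernel = c("gaussian", "epanechnikov"),
                    mean_estimator = c("local_linear", "local_constant"),
                    h_grid = NULL, standardize = FALSE, sample = NULL) {
  kernel <- match.arg(kernel)
  mean_estimator <- match.arg(mean_estimator)
  cl <- match.call()
  if (is.null(sample)) {
    if (is.null(formula) || is.null(data)) {
      stop_covtrace("supply either a formula and data, or a group_sample",
                    "invalid_parameter")
    }
    sample <- .sample_from_formula(formula, data)
  }
  if (standardize) {
    sample$x <- scale(sample$x)[, , drop = FALSE]
    attr(sample$x, "scaled:center") <- NULL
    attr(sample$x, "scaled:scale") <- NULL
  }
  if (is.null(mean_bandwidth)) {
    mean_bandwidth <- as.numeric(
      select_mean_bandwidth(sample, estimator = mean_estimator,
                            lambda = lambda, family = kernel))
  }
  if (is.null(bandwidth)) {
    if (is.null(h_grid)) {
      h_grid <- exp(seq(log(0.1), log(2), length.out = 10L))
      if (sample$q == 1L) h_grid <- h_grid * stats::sd(sample$u[, 1L])
    }
    bw <- cv_cov_bandwidth(sample, h_grid, mean_h = mean_bandwidth,
                           lambda = lambda, family = kernel,
                           mean_estimator = mean_estimator)
  } else {
    bw <- bandwidth_spec(bandwidth, mean_h = mean_bandwidth, lambda = lambda)
  }
  mean_fit <- .mean_fit_all(sample, bw$mean_h, lambda, kernel,
                            mean_estimator)
  structure(
    list(sample = sample, bandwidth = bw,
         residuals = sample$x - mean_fit, mean_fit = mean_fit,
         mean_estimator = mean_estimator, kernel = kernel,
         cv = attr(bw, "cv"), call = cl),
    class = "condcov")
}

## parse cbind(y1,...) ~ u1 + f1 into a group_sample
.sample_from_formula <- function(formula, data) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (is.null(dim(y)) || ncol(y) < 2L) {
    stop_covtrace(
      "response must be a multi-column matrix, e.g. cbind(y1, y2) ~ u",
      "invalid_parameter")
  }
  rhs <- mf[-1L]
  is_cat <- vapply(rhs, function(z) is.factor(z) || is.character(z),
                   logical(1))
  if (all(is_cat)) {
    stop_covtrace("at least one continuous covariate is required",
                  "invalid_parameter")
  }
  u <- as.matrix(as.data.frame(rhs[!is_cat]))
  ucat <- if (any(is_cat)) as.data.frame(rhs[is_cat]) else NULL
  group_sample(as.matrix(y), u, ucat)
}

#' @export
print.condcov <- function(x, ...) {
  s <- x$sample
  cat("Conditional covariance fit (Nadaraya-Watson)\n")
  cat(sprintf("  n = %d, responses p = %d, continuous covariates q = %d",
              s$n, s$p, s$q))
  if (s$r > 0) cat(sprintf(", categorical r = %d", s$r))
  cat("\n")
  cat(sprintf("  mean estimator: %s (h = %s)\n", x$mean_estimator,
              paste(format(x$bandwidth$mean_h, digits = 4), collapse = ", ")))
  cat(sprintf("  covariance bandwidth h = %s, kernel = %s\n",
              paste(format(x$bandwidth$h, digits = 4), collapse = ", "),
              x$kernel))
  invisible(x)
}

#' @export
summary.condcov <- function(object, ...) {
  s <- object$sample
  out <- list(
    fit = object,
    u_range = apply(s$u, 2L, range),
    resid_sd = apply(object$residuals, 2L, stats::sd),
    cv = object$cv)
  class(out) <- "summary.condcov"
  out
}

#' @export
print.summary.condcov <- function(x, ...) {
  print(x$fit)
  cat("  covariate range(s):\n")
  print(signif(x$u_range, 4))
  cat("  residual SD by response:",
      paste(format(x$resid_sd, digits = 4), collapse = ", "), "\n")
  if (!is.null(x$cv)) {
    cat("  covariance-bandwidth CV criterion:\n")
    print(x$cv, row.names = FALSE)
  }
  invisible(x)
}

#' Predict conditional covariance matrices
#'
#' Evaluates the fitted conditional covariance function at new covariate
#' values.
#'
#' @param object a [condcov()] fit.
#' @param u covariate point(s): numeric vector (grid for `q = 1`, single
#'   point for `q > 1`) or list of length-q points.
#' @param level target categorical level(s) when the fit has factor
#'   covariates.
#' @param simplify if `TRUE` (default) a single point returns the
#'   `"cond_cov"` record itself rather than a length-1 list.
#' @param ... unused.
#' @return a `"cond_cov"` record or a list of them (flagged, not failed, at
#'   extrapolating points).
#' @export
predict.condcov <- function(object, u, level = NULL, simplify = TRUE, ...) {
  s <- object$sample
  pts <- if (is.list(u)) u
         else if (s$q == 1L) as.list(as.numeric(u))
         else list(as.numeric(u))
  out <- cond_cov_curve(s, pts, object$bandwidth, level = level,
                        residuals = object$residuals,
                        family = object$kernel)
  if (simplify && length(out) == 1L) out[[1L]] else out
}

#' @export
residuals.condcov <- function(object, ...) object$residuals

#' @export
fitted.condcov <- function(object, ...) object$mean_fit

#' Plot a fitted conditional covariance function
#'
#' For a single continuous covariate, draws the unique entries of the
#' estimated conditional covariance matrix against the covariate over a grid
#' spanning the observed range.
#'
#' @param x a [condcov()] fit with `q = 1`.
#' @param grid evaluation grid; default 60 points across the observed range.
#' @param level factor level(s) when the fit has categorical covariates.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.condcov <- function(x, grid = NULL, level = NULL, ...) {
  if (x$sample$q != 1L) {
    stop_covtrace("plotting is implemented for a single continuous covariate",
                  "invalid_parameter")
  }
  rng <- range(x$sample$u[, 1L])
  if (is.null(grid)) grid <- seq(rng[1L], rng[2L], length.out = 60L)
  cc <- predict(x, grid, level = level, simplify = FALSE)
  p <- x$sample$p
  idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  Y <- t(vapply(cc, function(z) {
    if (isTRUE(z$ok)) z$sigma[idx] else rep(NA_real_, nrow(idx))
  }, numeric(nrow(idx))))
  labs <- paste0("sigma[", idx[, 1L], ",", idx[, 2L], "]")
  graphics::matplot(grid, Y, type = "l", lty = 1,
                    xlab = colnames(x$sample$u)[1L],
                    ylab = "conditional covariance", ...)
  graphics::legend("topleft", legend = labs, lty = 1,
                   col = seq_len(nrow(idx)), bty = "n", cex = 0.8)
  invisible(Y)
}
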