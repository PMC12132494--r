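#' Construct a group sample
#'
#' Bundles one group's multivariate response matrix with its covariates.
#' Responses are assumed already standardized (zero mean, unit variance) when
#' used by the comparison tests; [load_and_preprocess()] performs that
#' standardization for CSV inputs.
#'
#' @param x numeric matrix (n x p) of responses; a vector is treated as a
#'   single column.
#' @param u numeric matrix (n x q) of continuous covariates; a vector is
#'   treated as one column.
#' @param ucat optional data.frame of factor covariates (n rows). Character
#'   columns are converted to factors; factor levels are taken as the declared
#'   alphabet.
#' @return an object of class `"group_sample"`: a list with elements `x`, `u`,
#'   `ucat` and the sizes `n`, `p`, `q`, `r`.
#' @export
group_sample <- function(x, u, ucat = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  u <- as.matrix(u)
  storage.mode(u) <- "double"
  if (nrow(x) != nrow(u)) {
    stop_covtrace("x and u must have the same number of rows",
                  "invalid_parameter")
  }
  if (anyNA(x) || anyNA(u)) {
    stop_covtrace("group_sample requires complete rows (no missing entries)",
                  "invalid_parameter")
  }
  if (!is.null(ucat)) {
    ucat <- as.data.frame(ucat)
    if (nrow(ucat) != nrow(x)) {
      stop_covtrace("ucat must have the same number of rows as x",
                    "invalid_parameter")
    }
    for (j in seq_along(ucat)) {
      if (!is.factor(ucat[[j]])) ucat[[j]] <- factor(ucat[[j]])
      if (anyNA(ucat[[j]])) {
        stop_covtrace("ucat contains missing values", "invalid_parameter")
      }
      if (nlevels(ucat[[j]]) < 2L) {
        stop_covtrace("each categorical covariate needs >= 2 declared levels",
                      "invalid_parameter")
      }
    }
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (is.null(colnames(u))) colnames(u) <- paste0("u", seq_len(ncol(u)))
  structure(
    list(x = x, u = u, ucat = ucat,
         n = nrow(x), p = ncol(x), q = ncol(u),
         r = if (is.null(ucat)) 0L else ncol(ucat)),
    class = "group_sample")
}

#' @export
print.group_sample <- function(x, ...) {
  cat(sprintf("group_sample: n = %d, p = %d responses, q = %d continuous",
              x$n, x$p, x$q))
  if (x$r > 0) cat(sprintf(" + %d categorical", x$r))
  cat(" covariate(s)\n")
  invisible(x)
}

#' Bandwidth specification
#'
#' Smoothing bandwidths for conditional covariance estimation: one covariance
#' bandwidth per continuous covariate dimension (product kernel), the
#' Aitchison-Aitken weight `lambda` for categorical covariates, and the
#' bandwidth(s) used by the inner mean estimator.
#'
#' @param h positive covariance bandwidth(s), one per continuous covariate.
#' @param mean_h positive mean-estimator bandwidth(s); defaults to `h`.
#' @param lambda categorical kernel weight in `[1/k, 1]`; default 1
#'   (estimation within the matching stratum only).
#' @return an object of class `"bandwidth_spec"`.
#' @export
bandwidth_spec <- function(h, mean_h = h, lambda = 1) {
  if (!is.numeric(h) || length(h) < 1L || any(!is.finite(h)) || any(h <= 0)) {
    stop_covtrace("h must be positive and finite", "invalid_parameter")
  }
  if (!is.numeric(mean_h) || any(!is.finite(mean_h)) || any(mean_h <= 0)) {
    stop_covtrace("mean_h must be positive and finite", "invalid_parameter")
  }
  structure(list(h = as.numeric(h), mean_h = as.numeric(mean_h),
                 lambda = lambda),
            class = "bandwidth_spec")
}

#' @export
print.bandwidth_spec <- function(x, ...) {
  cat("bandwidth_spec: h =", format(x$h, digits = 4),
      "| mean_h =", format(x$mean_h, digits = 4),
      "| lambda =", format(x$lambda, digits = 4), "\n")
  invisible(x)
}

## run expr with a temporary RNG seed, restoring the caller's stream.
## seed = NULL leaves the ambient stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% 2147483647L)
  expr
}

## deterministic substream seed for iteration b of a user seed (kept < 2^31).
## The (seed, b) pair is scrambled through multiplicative congruential
## rounds: adjacent integer seeds fed straight to set.seed() produce
## noticeably correlated initial output, which would couple the streams of
## consecutive iterations (all arithmetic stays below 2^53, so it is exact).
sub_seed <- function(seed, b) {
  if (is.null(seed)) return(NULL)
  m <- 2147483647
  x <- as.numeric(seed) %% m
  x <- (x * 48271 + 1) %% m
  x <- (x + (as.numeric(b) %% m) * 69621) %% m
  x <- (x * 48271 + 1) %% m
  x
}
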