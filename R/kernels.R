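#' Continuous kernel weight
#'
#' Scaled symmetric kernel weight `Kh(d) = K(d/h)/h` used throughout the
#' smoothing machinery. Two families are supported: the Gaussian kernel
#' (default; unbounded support, so no neighborhood is ever empty) and the
#' Epanechnikov kernel `K(u) = 0.75 (1 - u^2)` on `[-1, 1]`.
#'
#' @param distance numeric vector of signed distances `U - u` in covariate
#'   units.
#' @param bandwidth positive smoothing bandwidth `h`, in the same units.
#' @param family kernel family, `"gaussian"` or `"epanechnikov"`.
#' @return numeric vector of nonnegative weights, symmetric in the sign of
#'   `distance`.
#' @examples
#' kernel_weight(0, 1)            # dnorm(0) = 1/sqrt(2*pi)
#' kernel_weight(c(-1, 1), 0.5)   # symmetric
#' @export
kernel_weight <- function(distance, bandwidth,
                          family = c("gaussian", "epanechnikov")) {
  family <- match.arg(family)
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L ||
      !is.finite(bandwidth) || bandwidth <= 0) {
    stop_covtrace("bandwidth must be a single positive number",
                  "invalid_parameter")
  }
  .kern(distance / bandwidth, family) / bandwidth
}

## unscaled kernel density K(u)
.kern <- function(u, family) {
  switch(family,
    gaussian = stats::dnorm(u),
    epanechnikov = ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0)
  )
}

#' Aitchison-Aitken categorical kernel weight
#'
#' Discrete kernel for an unordered factor with `nlevels` levels: weight
#' `lambda` when the observed level matches the target level and
#' `(1 - lambda)/(nlevels - 1)` otherwise. `lambda = 1` reduces estimation to
#' the matching stratum; `lambda = 1/nlevels` weights every level uniformly.
#' The weights over the `nlevels` levels always sum to 1.
#'
#' @param level observed factor level(s).
#' @param target the level at which estimation is carried out.
#' @param lambda tuning weight in `[1/nlevels, 1]` for the matching level.
#' @param nlevels number of levels `k >= 2` of the factor.
#' @return numeric vector of nonnegative weights.
#' @export
categorical_weight <- function(level, target, lambda, nlevels) {
  if (!is.numeric(nlevels) || length(nlevels) != 1L || nlevels < 2 ||
      nlevels != round(nlevels)) {
    stop_covtrace("nlevels must be an integer >= 2", "invalid_parameter")
  }
  if (!is.numeric(lambda) || length(lambda) != 1L ||
      lambda < 1 / nlevels - 1e-12 || lambda > 1 + 1e-12) {
    stop_covtrace(
      sprintf("lambda must lie in [1/k, 1] = [%.6g, 1]", 1 / nlevels),
      "invalid_parameter")
  }
  ifelse(as.character(level) == as.character(target),
         lambda, (1 - lambda) / (nlevels - 1))
}

## classed error helper: all package errors carry class
## c("covtrace_<what>", "covtrace_error", "error", "condition")
stop_covtrace <- function(msg, what, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("covtrace_", what),
                                     "covtrace_error")))
}

## product of per-dimension continuous kernel weights at one point.
## U: n x q matrix, u0: length-q point, h: length-q bandwidths.
.cont_weights <- function(U, u0, h, family) {
  n <- nrow(U)
  w <- rep(1, n)
  for (j in seq_len(ncol(U))) {
    w <- w * kernel_weight(U[, j] - u0[j], h[j], family)
  }
  w
}

## product of Aitchison-Aitken weights over the categorical columns.
## ucat: data.frame of factors (or NULL), target: list/char vector of levels.
.cat_weights <- function(ucat, target, lambda) {
  if (is.null(ucat) || ncol(ucat) == 0L) return(1)
  w <- rep(1, nrow(ucat))
  for (j in seq_len(ncol(ucat))) {
    k <- nlevels(ucat[[j]])
    w <- w * categorical_weight(ucat[[j]], target[[j]], lambda, k)
  }
  w
}
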