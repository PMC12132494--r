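# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's computational paths (explicit loops, explicit inverses).

# weighted covariance of residual rows by an explicit double loop
naive_wcov <- function(E, w) {
  p <- ncol(E)
  S <- matrix(0, p, p)
  for (i in seq_len(nrow(E))) {
    S <- S + w[i] * (E[i, ] %o% E[i, ])
  }
  S / sum(w)
}

# leave-one-out Gaussian log-likelihood criterion recomputed naively
naive_cv_criterion <- function(sample, h, residuals, family = "gaussian") {
  n <- sample$n
  tot <- 0
  for (i in seq_len(n)) {
    w <- numeric(n)
    for (j in seq_len(n)) {
      if (j == i) next
      w[j] <- prod(covtrace::kernel_weight(sample$u[j, ] - sample$u[i, ],
                                           h, family))
    }
    S <- naive_wcov(residuals, w)
    tot <- tot + drop(t(residuals[i, ]) %*% solve(S) %*% residuals[i, ]) +
      determinant(S, logarithm = TRUE)$modulus
  }
  as.numeric(tot / n)
}

# combined-matrix eigenvalues through the explicit inverse
naive_combined_eigen <- function(S0, S1, n0, n1) {
  sort(Re(eigen(solve(n0 * S0 + n1 * S1) %*% (n1 * S1))$values),
       decreasing = TRUE)
}

# a random symmetric positive definite matrix
random_spd <- function(p) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) + diag(p) * 0.5
}

# small fixed design with a linear mean trend for smoother tests
affine_sample <- function(n = 40, a = c(1, -2), b = c(0.5, 3), seed = 42) {
  withr_seed <- function(s, expr) { set.seed(s); expr }
  withr_seed(seed, {
    u <- sort(runif(n, -1, 1))
    x <- cbind(a[1] + b[1] * u, a[2] + b[2] * u)
    covtrace::group_sample(x, u)
  })
}
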