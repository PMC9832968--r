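#' KL divergence from a diagonal Gaussian to the standard normal
#'
#' Closed form for KL(N(mu, diag(exp(log_var))) || N(0, I)), the latent
#' regularizer of the variational autoencoder objective:
#' \deqn{\tfrac12 \sum_j \left(e^{\ell_j} + \mu_j^2 - 1 - \ell_j\right)}
#' with \eqn{\ell_j} the log-variances. Always non-negative.
#'
#' @param mu numeric vector of means.
#' @param log_var numeric vector of log-variances, same length as `mu`.
#' @return a single non-negative number.
#' @examples
#' kl_diag_gaussian_to_standard(0, 0)      # 0: identical distributions
#' kl_diag_gaussian_to_standard(1, 0)      # 0.5
#' @export
kl_diag_gaussian_to_standard <- function(mu, log_var) {
  if (length(mu) != length(log_var)) {
    stop("`mu` and `log_var` must have the same length")
  }
  if (anyNA(mu) || anyNA(log_var) || any(!is.finite(mu)) || any(!is.finite(log_var))) {
    stop("non-finite values in `mu` or `log_var`")
  }
  0.5 * sum(exp(log_var) + mu^2 - 1 - log_var)
}

# KL(N(mu1, s1^2) || N(mu2, s2^2)) for diagonal Gaussians (used in tests and
# the conjugate-toy gap identity)
kl_gaussian_gaussian <- function(mu1, log_var1, mu2, log_var2) {
  0.5 * sum(log_var2 - log_var1 +
              (exp(log_var1) + (mu1 - mu2)^2) / exp(log_var2) - 1)
}

# log N(x; mean, var) elementwise, summed over columns when given matrices
gaussian_loglik <- function(x, mean, log_var) {
  -0.5 * (log(2 * pi) + log_var + (x - mean)^2 / exp(log_var))
}

# Gauss-Hermite nodes/weights for integrals against N(0,1), via Golub-Welsch
# on the Hermite Jacobi matrix (probabilists' convention).
gauss_hermite <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 1))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1L))
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  ev <- eigen(J, symmetric = TRUE)
  list(nodes = ev$values, weights = ev$vectors[1L, ]^2)
}
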