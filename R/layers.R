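# Bayesian linear layers with variational dropout.
#
# Each layer keeps a Gaussian posterior over every weight: a mean matrix and a
# log-variance matrix. The per-weight dropout rate is alpha =
# sigma^2 / mean^2, i.e. log alpha = log_var - 2 log|mean|; the KL to the
# scale-invariant log-uniform prior is the standard cubic-sigmoid
# approximation in log alpha. Biases are point estimates.

LOG_ALPHA_CLIP <- 8
LATENT_LOGVAR_CLIP <- 10

#' Create a Bayesian linear layer
#'
#' @param n_in,n_out layer dimensions.
#' @param init_weight_sd sd of the mean initialization (default
#'   `1/sqrt(n_in)`).
#' @param init_log_var initial per-weight posterior log-variance; the default
#'   -10 starts the layer close to deterministic.
#' @return a `bayes_linear` object with fields `weight_mean`,
#'   `weight_log_var`, `bias_mean`.
#' @export
bayes_linear <- function(n_in, n_out, init_weight_sd = 1 / sqrt(n_in),
                         init_log_var = -10) {
  structure(list(
    weight_mean = matrix(stats::rnorm(n_in * n_out, 0, init_weight_sd), n_in, n_out),
    weight_log_var = matrix(init_log_var, n_in, n_out),
    bias_mean = rep(0, n_out)
  ), class = "bayes_linear")
}

#' Per-weight dropout rates of a Bayesian layer
#'
#' `log alpha = log_var - 2 log|mean|`, clipped to `[-8, 8]` for stability.
#'
#' @param layer a [bayes_linear()] layer.
#' @return matrix of log-alpha values, same shape as the weights.
#' @export
log_alpha <- function(layer) {
  la <- layer$weight_log_var - 2 * log(abs(layer$weight_mean) + 1e-12)
  pmin(pmax(la, -LOG_ALPHA_CLIP), LOG_ALPHA_CLIP)
}

# cubic-sigmoid approximation of the variational-dropout KL, as a function of
# log alpha; >= 0, maximal at the lower clip (alpha -> 0), -> 0 as alpha grows
vd_kl_from_log_alpha <- function(la) {
  k1 <- 0.63576; k2 <- 1.87320; k3 <- 1.48695
  neg_kl <- k1 * plogis(k2 + k3 * la) - 0.5 * log1p(exp(-la)) - k1
  -neg_kl
}

#' Variational-dropout KL and L2 penalty of a Bayesian layer
#'
#' Sums the log-uniform-prior KL approximation over all weights and reports
#' the L2 penalty on the weight means separately (log-variances are never
#' L2-penalized).
#'
#' @param layer a [bayes_linear()] layer.
#' @param lambda L2 coefficient for the reported penalty.
#' @return list with `kl` (non-negative) and `l2` (`lambda * sum(mean^2)`).
#' @export
variational_dropout_kl <- function(layer, lambda = 0) {
  kl <- sum(vd_kl_from_log_alpha(log_alpha(layer)))
  list(kl = kl, l2 = lambda * sum(layer$weight_mean^2))
}

# deterministic forward: propagate posterior means
bl_forward_mean <- function(layer, X) {
  sweep(X %*% layer$weight_mean, 2L, layer$bias_mean, "+")
}

# stochastic forward: one draw from the weight posterior, shared by all rows
bl_forward_sample <- function(layer, X) {
  eps <- matrix(stats::rnorm(length(layer$weight_mean)),
                nrow(layer$weight_mean), ncol(layer$weight_mean))
  Ws <- layer$weight_mean + exp(layer$weight_log_var / 2) * eps
  sweep(X %*% Ws, 2L, layer$bias_mean, "+")
}

# ---- tape versions (training path) ----
# `p` is a list of node ids: p$W (mean), p$V (log-var), p$b (bias)

bl_tape_mean <- function(tape, p, X) {
  ad_add_bias(tape, ad_matmul(tape, X, p$W), p$b)
}

# one posterior weight draw per batch: W = W_mean + exp(V/2) * eps, with eps
# a per-weight standard normal; rows of the batch share the draw
bl_tape_sample <- function(tape, p, X, eps) {
  Ws <- ad_add(tape, p$W,
               ad_mul(tape, ad_exp(tape, ad_scale(tape, p$V, 0.5)),
                      ad_const(tape, eps)))
  ad_add_bias(tape, ad_matmul(tape, X, Ws), p$b)
}

# KL + L2 of one layer on the tape; returns list(kl=node, l2=node)
bl_tape_kl <- function(tape, p) {
  k1 <- 0.63576; k2 <- 1.87320; k3 <- 1.48695
  logw2 <- ad_log(tape, ad_shift(tape, ad_square(tape, p$W), 1e-24))
  la <- ad_clip(tape, ad_sub(tape, p$V, logw2), -LOG_ALPHA_CLIP, LOG_ALPHA_CLIP)
  sig <- ad_sigmoid(tape, ad_shift(tape, ad_scale(tape, la, k3), k2))
  sp <- ad_softplus(tape, ad_neg(tape, la)) # log(1 + alpha^-1)
  neg_kl <- ad_shift(tape, ad_sub(tape, ad_scale(tape, sig, k1),
                                  ad_scale(tape, sp, 0.5)), -k1)
  list(kl = ad_sum(tape, ad_neg(tape, neg_kl)),
       l2 = ad_sum(tape, ad_square(tape, p$W)))
}
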