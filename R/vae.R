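#' Class-conditional Gaussian VAE for the expression modality
#'
#' Builds the variational autoencoder used for the microarray modality: a
#' Gaussian encoder `q(z | x, y)` and decoder `p(x | y, z)`. The encoder's
#' hidden tanh trunk `h(x)` is label-free (the label joins at the latent
#' heads), so it doubles as the learned low-dimensional gene-profile
#' representation consumed by the microarray classifier; the decoder is
#' conditioned on the label (hidden layer and a direct label-to-gene-mean
#' skip), so unlabeled patients can be handled by marginalizing it. All layers are
#' Bayesian ([bayes_linear()]) unless `bayesian = FALSE`, in which case
#' weights are point estimates and the weight-KL term is zero.
#'
#' @param n_genes number of expression features (standardized inputs).
#' @param latent_dim latent dimension (default 8).
#' @param hidden hidden width of encoder and decoder (default 32).
#' @param bayesian use variational-dropout Bayesian weights (default TRUE).
#' @return a `prog_vae` object.
#' @export
prog_vae <- function(n_genes, latent_dim = 8, hidden = 32, bayesian = TRUE) {
  structure(list(
    enc1 = bayes_linear(n_genes, hidden),
    enc_mu = bayes_linear(hidden + 1L, latent_dim),
    enc_lv = bayes_linear(hidden + 1L, latent_dim),
    dec1 = bayes_linear(latent_dim + 1L, hidden),
    dec_mu = bayes_linear(hidden, n_genes),
    dec_skip = bayes_linear(1L, n_genes),
    dec_lv = bayes_linear(hidden, n_genes),
    n_genes = as.integer(n_genes),
    latent_dim = as.integer(latent_dim),
    hidden = as.integer(hidden),
    bayesian = isTRUE(bayesian)
  ), class = "prog_vae")
}

vae_layer_names <- c("enc1", "enc_mu", "enc_lv", "dec1", "dec_mu", "dec_lv", "dec_skip")

# label-free encoder trunk: the low-dimensional gene-profile representation
# shared by the latent heads and the microarray classifier
vae_trunk <- function(vae, x, weight_mode = "mean") {
  tanh(bl_forward(vae$enc1, x, weight_mode))
}

# forward through one bayes layer honoring the weight mode
bl_forward <- function(layer, X, weight_mode) {
  if (weight_mode == "sample") bl_forward_sample(layer, X) else bl_forward_mean(layer, X)
}

#' Encode expression vectors to a Gaussian latent
#'
#' @param vae a [prog_vae()] model.
#' @param x numeric matrix (patients x genes) or a single vector of
#'   standardized expression values.
#' @param y label channel in `[0,1]` (scalar or per-patient vector); 1 codes
#'   poor prognosis. Defaults to 0.5 (unknown).
#' @param weight_mode `"mean"` propagates posterior weight means
#'   (deterministic); `"sample"` draws one set of Bayesian weights from the
#'   posterior (set a seed for reproducibility).
#' @return `gaussian_latent` object with matrices `mu` and `log_var`
#'   (patients x latent dim); log-variances are clipped to `[-10, 10]`.
#' @export
vae_encode <- function(vae, x, y = 0.5, weight_mode = c("mean", "sample")) {
  weight_mode <- match.arg(weight_mode)
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(x) != vae$n_genes) stop("expected ", vae$n_genes, " expression features, got ", ncol(x))
  if (any(!is.finite(x))) stop("non-finite expression input")
  h <- vae_trunk(vae, x, weight_mode)
  hy <- cbind(h, rep_len(y, nrow(x)))
  mu <- bl_forward(vae$enc_mu, hy, weight_mode)
  lv <- pmin(pmax(bl_forward(vae$enc_lv, hy, weight_mode), -LATENT_LOGVAR_CLIP),
             LATENT_LOGVAR_CLIP)
  structure(list(mu = mu, log_var = lv, dim = vae$latent_dim),
            class = "gaussian_latent")
}

#' Sample from a Gaussian latent by reparameterization
#'
#' Draws `mu + exp(log_var / 2) * eps` with `eps ~ N(0, I)`.
#'
#' @param latent a `gaussian_latent` from [vae_encode()].
#' @param seed optional integer seed for the draw.
#' @return matrix of samples, same shape as `latent$mu`.
#' @export
reparameterize <- function(latent, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eps <- matrix(stats::rnorm(length(latent$mu)), nrow(latent$mu), ncol(latent$mu))
  latent$mu + exp(latent$log_var / 2) * eps
}

#' Decode latent samples to per-gene Gaussian likelihood parameters
#'
#' @param vae a [prog_vae()] model.
#' @param z latent matrix (patients x latent dim).
#' @param y label channel as in [vae_encode()].
#' @param weight_mode see [vae_encode()].
#' @return list with matrices `mean` and `log_var` (patients x genes).
#' @export
vae_decode <- function(vae, z, y = 0.5, weight_mode = c("mean", "sample")) {
  weight_mode <- match.arg(weight_mode)
  z <- if (is.matrix(z)) z else matrix(z, nrow = 1L)
  if (ncol(z) != vae$latent_dim) stop("expected latent dim ", vae$latent_dim, ", got ", ncol(z))
  yv <- matrix(rep_len(y, nrow(z)), ncol = 1L)
  h <- tanh(bl_forward(vae$dec1, cbind(z, yv), weight_mode))
  # direct label -> gene-mean skip: the poor class can shift every gene mean
  # additively, so reconstruction genuinely depends on the label
  list(mean = bl_forward(vae$dec_mu, h, weight_mode) +
         bl_forward(vae$dec_skip, yv, weight_mode),
       log_var = pmin(pmax(bl_forward(vae$dec_lv, h, weight_mode),
                           -LATENT_LOGVAR_CLIP), LATENT_LOGVAR_CLIP))
}

# Gaussian reconstruction log-likelihood of x under decoder params, per row
vae_recon_loglik <- function(x, dec) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  rowSums(gaussian_loglik(x, dec$mean, dec$log_var))
}

# total weight KL and L2 across the VAE's layers (0 if not Bayesian)
vae_weight_kl <- function(vae, lambda = 0) {
  if (!vae$bayesian) return(list(kl = 0, l2 = 0))
  terms <- lapply(vae_layer_names, function(nm) variational_dropout_kl(vae[[nm]], lambda))
  list(kl = sum(vapply(terms, `[[`, 0, "kl")),
       l2 = sum(vapply(terms, `[[`, 0, "l2")))
}

#' Decomposed evidence lower bound for one expression vector
#'
#' Returns the pieces of the (Bayesian) ELBO
#' `recon_loglik - kl_latent - kl_weights` for a single patient:
#' the Monte-Carlo (or Gauss-Hermite) reconstruction expectation
#' `E_q(z|x,y) log p(x|y,z)`, the closed-form latent KL to the standard
#' normal prior, and the variational-dropout KL of the weight posteriors.
#' Weight means are propagated deterministically; the expectation is over
#' the latent only.
#'
#' @param vae a [prog_vae()] model.
#' @param x one standardized expression vector.
#' @param y label channel in `[0,1]` (default 0.5).
#' @param n_mc_samples Monte-Carlo sample count for the reconstruction term
#'   (use >= 100 for reported ELBOs; training uses 1).
#' @param seed integer seed for the latent draws.
#' @param method `"mc"` (default) or `"quadrature"`: Gauss-Hermite product
#'   quadrature over the latent, exact for linear decoders; only available
#'   for latent dimension <= 3.
#' @param n_quad nodes per latent dimension for `method = "quadrature"`.
#' @return an `elbo_terms` object: `recon_loglik`, `kl_latent`,
#'   `kl_weights`, `total_elbo`.
#' @export
elbo <- function(vae, x, y = 0.5, n_mc_samples = 100, seed = NULL,
                 method = c("mc", "quadrature"), n_quad = 20) {
  method <- match.arg(method)
  if (method == "mc" && n_mc_samples < 1) stop("`n_mc_samples` must be >= 1")
  x <- as.numeric(x)
  lat <- vae_encode(vae, x, y)
  klz <- kl_diag_gaussian_to_standard(as.numeric(lat$mu), as.numeric(lat$log_var))
  if (method == "mc") {
    if (!is.null(seed)) set.seed(seed)
    L <- vae$latent_dim
    eps <- matrix(stats::rnorm(n_mc_samples * L), n_mc_samples, L)
    z <- sweep(eps, 2L, exp(as.numeric(lat$log_var) / 2), "*")
    z <- sweep(z, 2L, as.numeric(lat$mu), "+")
    dec <- vae_decode(vae, z, y)
    recon <- mean(vae_recon_loglik(matrix(x, n_mc_samples, length(x), byrow = TRUE), dec))
  } else {
    L <- vae$latent_dim
    if (L > 3L) stop("quadrature ELBO supports latent dimension <= 3")
    gh <- gauss_hermite(n_quad)
    grids <- do.call(expand.grid, rep(list(gh$nodes), L))
    wgrid <- apply(do.call(expand.grid, rep(list(gh$weights), L)), 1L, prod)
    z <- sweep(as.matrix(grids), 2L, exp(as.numeric(lat$log_var) / 2), "*")
    z <- sweep(z, 2L, as.numeric(lat$mu), "+")
    dec <- vae_decode(vae, z, y)
    recon <- sum(wgrid * vae_recon_loglik(matrix(x, nrow(z), length(x), byrow = TRUE), dec))
  }
  klw <- vae_weight_kl(vae)$kl
  structure(list(recon_loglik = recon, kl_latent = klz, kl_weights = klw,
                 total_elbo = recon - klz - klw),
            class = "elbo_terms")
}

#' @export
print.elbo_terms <- function(x, ...) {
  cat(sprintf("ELBO: %.4f  (recon %.4f - KL_latent %.4f - KL_weights %.4f)\n",
              x$total_elbo, x$recon_loglik, x$kl_latent, x$kl_weights))
  invisible(x)
}
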