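# Variational autoencoder machinery: closed-form KLs, reparameterization,
# decoding likelihoods, the decomposed ELBO and its lower-bound property.

test_that("diagonal-Gaussian KL matches closed forms and quadrature", {
  expect_equal(kl_diag_gaussian_to_standard(0, 0), 0)
  expect_equal(kl_diag_gaussian_to_standard(1, 0), 0.5)
  # numerical quadrature oracle for mu = 0.3, var = 2.0
  mu <- 0.3; s2 <- 2.0
  integrand <- function(z) {
    q <- dnorm(z, mu, sqrt(s2))
    q * (dnorm(z, mu, sqrt(s2), log = TRUE) - dnorm(z, 0, 1, log = TRUE))
  }
  kl_num <- integrate(integrand, -20, 20, rel.tol = 1e-10)$value
  expect_lt(abs(kl_diag_gaussian_to_standard(mu, log(s2)) - kl_num), 1e-6)
  # vectorized and non-negative on random inputs
  set.seed(1)
  for (i in 1:20) {
    expect_gte(kl_diag_gaussian_to_standard(rnorm(5), rnorm(5)), 0)
  }
  expect_error(kl_diag_gaussian_to_standard(c(0, 1), 0), "length")
  expect_error(kl_diag_gaussian_to_standard(NaN, 0), "non-finite")
})

test_that("encoding is shape-correct, deterministic in mean mode", {
  set.seed(3)
  vae <- prog_vae(6, latent_dim = 4, hidden = 5)
  x <- matrix(rnorm(18), 3, 6)
  lat <- vae_encode(vae, x, y = 1)
  expect_equal(dim(lat$mu), c(3L, 4L))
  expect_equal(dim(lat$log_var), c(3L, 4L))
  expect_true(all(abs(lat$log_var) <= 10))
  # zero weights and biases give a zero latent mean
  for (nm in c("enc1", "enc_mu", "enc_lv")) {
    vae[[nm]]$weight_mean[] <- 0
    vae[[nm]]$bias_mean[] <- 0
  }
  expect_equal(vae_encode(vae, x)$mu, matrix(0, 3, 4))
  # sampled-weight mode reproducible under a seed
  vae2 <- prog_vae(6, 4, 5)
  set.seed(11); a <- vae_encode(vae2, x, weight_mode = "sample")
  set.seed(11); b <- vae_encode(vae2, x, weight_mode = "sample")
  expect_identical(a, b)
  expect_error(vae_encode(vae2, matrix(0, 2, 5)), "expected 6")
})

test_that("reparameterization has the right moments and determinism", {
  lat <- structure(list(mu = matrix(c(0.5, -1), 1), log_var = matrix(c(0, 1), 1)),
                   class = "gaussian_latent")
  # near-degenerate variance collapses on the mean
  lat0 <- structure(list(mu = matrix(0.7), log_var = matrix(-10)),
                    class = "gaussian_latent")
  expect_lt(abs(reparameterize(lat0, seed = 4) - 0.7), 0.01)
  # moments over many draws: sd of a standard latent within [0.99, 1.01]
  latN <- structure(list(mu = matrix(0, 1e5, 1), log_var = matrix(0, 1e5, 1)),
                    class = "gaussian_latent")
  z <- reparameterize(latN, seed = 8)
  expect_lt(abs(mean(z)), 3 / sqrt(1e5))
  expect_gte(sd(z), 0.99); expect_lte(sd(z), 1.01)
  expect_identical(reparameterize(lat, seed = 2), reparameterize(lat, seed = 2))
})

test_that("decoder log-likelihood matches hand-computed Gaussian densities", {
  x <- c(0.2, -1.1, 0.7)
  dec <- list(mean = matrix(x, 1), log_var = matrix(0, 1, 3))
  # perfect mean, unit variance: each gene contributes -log(2*pi)/2
  expect_equal(prognet:::vae_recon_loglik(x, dec), -3 * log(2 * pi) / 2,
               ignore_attr = TRUE)
  # hand-computed three-gene example
  dec2 <- list(mean = matrix(c(0, -1, 1), 1), log_var = matrix(log(c(1, 2, 0.5)), 1))
  by_hand <- sum(dnorm(x, c(0, -1, 1), sqrt(c(1, 2, 0.5)), log = TRUE))
  expect_equal(prognet:::vae_recon_loglik(x, dec2), by_hand, ignore_attr = TRUE)
  # likelihood decreases monotonically as the mean moves away from x
  offs <- seq(0, 3, by = 0.5)
  lls <- vapply(offs, function(o) {
    prognet:::vae_recon_loglik(x, list(mean = matrix(x + o, 1),
                                       log_var = matrix(0, 1, 3)))
  }, 0)
  expect_true(all(diff(lls) < 0))
})

test_that("variational-dropout KL behaves across the log-alpha range", {
  layer <- bayes_linear(2, 2)
  layer$weight_mean[] <- 1
  # alpha -> 0 (clip): KL per weight is maximal on the clipped range
  layer$weight_log_var[] <- -30
  kl_low <- variational_dropout_kl(layer)$kl
  layer$weight_log_var[] <- 0  # alpha = 1
  kl_mid <- variational_dropout_kl(layer)$kl
  layer$weight_log_var[] <- 30 # alpha -> infinity: KL -> 0
  kl_high <- variational_dropout_kl(layer)$kl
  expect_gt(kl_low, kl_mid); expect_gt(kl_mid, kl_high)
  expect_lt(kl_high, 1e-3)
  expect_gte(kl_high, 0)
  # lambda = 0 -> no L2; lambda scales the mean-squared sum
  expect_equal(variational_dropout_kl(layer, lambda = 0)$l2, 0)
  expect_equal(variational_dropout_kl(layer, lambda = 2)$l2, 2 * sum(layer$weight_mean^2))
  # matches an independent re-implementation of the cubic-sigmoid formula
  set.seed(7)
  layer$weight_mean <- matrix(rnorm(4), 2)
  layer$weight_log_var <- matrix(rnorm(4), 2)
  k1 <- 0.63576; k2 <- 1.87320; k3 <- 1.48695
  la <- pmin(pmax(layer$weight_log_var - 2 * log(abs(layer$weight_mean) + 1e-12), -8), 8)
  oracle <- -sum(k1 * plogis(k2 + k3 * la) - 0.5 * log1p(exp(-la)) - k1)
  expect_equal(variational_dropout_kl(layer)$kl, oracle)
})

test_that("the ELBO lower-bounds the evidence with gap KL(q || posterior)", {
  set.seed(99)
  worst <- 0
  for (i in 1:100) {
    w <- runif(1, -2, 2); b <- rnorm(1); lvx <- runif(1, -1, 1)
    mu_q <- rnorm(1); lv_q <- runif(1, -2, 1); x <- rnorm(1, 0, 2)
    vae <- linear_toy_vae(w, b, lvx, mu_q, lv_q)
    et <- elbo(vae, x, y = 0, method = "quadrature", n_quad = 40)
    s2x <- exp(lvx)
    log_evidence <- dnorm(x, b, sqrt(w^2 + s2x), log = TRUE)
    # exact posterior of z given x under the linear-Gaussian model
    prec <- 1 + w^2 / s2x
    mu_post <- (w * (x - b) / s2x) / prec
    kl_q_post <- prognet:::kl_gaussian_gaussian(mu_q, lv_q, mu_post, -log(prec))
    gap <- log_evidence - (et$total_elbo + et$kl_weights)
    expect_lte(et$total_elbo, log_evidence + 1e-9)
    worst <- max(worst, abs(gap - kl_q_post))
  }
  expect_lt(worst, 1e-6)
})

test_that("Monte-Carlo ELBO converges to the quadrature value", {
  vae <- linear_toy_vae(1.3, 0.2, 0.1, 0.4, -0.5)
  exact <- elbo(vae, x = 0.9, y = 0, method = "quadrature", n_quad = 30)
  # MC standard error of the reconstruction term, estimated at small n
  set.seed(5)
  draws <- replicate(200, elbo(vae, 0.9, y = 0, n_mc_samples = 1)$recon_loglik)
  se_1e4 <- sd(draws) / sqrt(1e4)
  mc <- elbo(vae, 0.9, y = 0, n_mc_samples = 1e4, seed = 3)
  expect_lt(abs(mc$total_elbo - exact$total_elbo), 4 * se_1e4)
  # the decomposition identity holds exactly
  expect_equal(mc$total_elbo, mc$recon_loglik - mc$kl_latent - mc$kl_weights)
  expect_error(elbo(vae, 0.9, n_mc_samples = 0), ">= 1")
})

test_that("ELBO gradients agree with finite differences", {
  set.seed(42)
  cfg <- synthetic_config(n_labeled = 10, n_unlabeled = 6, n_genes = 5,
                          n_clinical = 3, n_binary_clinical = 1, seed = 5)
  gen <- generate_cohort(cfg)
  co <- split_cohort(gen$cohort, c(train = 0.7, test = 0.3), seed = 2)
  std <- standardize(co, fit_on = "train", include_unlabeled = TRUE)
  model <- prognet(5, 3, train_config(latent_dim = 2, hidden = 4, hidden_clf = 3), 0.45)
  params <- prognet:::model_params(model)
  rows <- which(co$split %in% c("train", "unlabeled"))
  batch <- prognet:::make_batch(std$cohort, rows, 3)
  hp <- list(alpha = 1.3, lambda = 0.01, kl_temper = 0.5, n_total = length(rows),
             prior_poor = 0.45, variant = "full", weight_mode = "sample",
             unl_weight = 0.8)
  evalf <- function(p) {
    set.seed(777)
    lf <- prognet:::loss_forward(p, batch, hp)
    prognet:::ad_value(lf$tape, lf$total)[1]
  }
  set.seed(777)
  lf <- prognet:::loss_forward(params, batch, hp)
  grads <- prognet:::ad_backward(lf$tape, lf$total,
                                 vapply(lf$pnodes, identity, 0L))
  set.seed(9)
  h <- 1e-5
  for (t in 1:10) {
    nm <- sample(names(params), 1)
    i <- sample(length(params[[nm]]), 1)
    p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + h
    p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - h
    fd <- (evalf(p2) - evalf(p3)) / (2 * h)
    expect_lt(abs(fd - grads[[nm]][i]) / max(1e-6, abs(fd), abs(grads[[nm]][i])),
              1e-4)
  }
})
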