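# shared fixtures: tiny delimited-text cohorts written to tempdir, and small
# trained models reused across test files

write_toy_cohort_files <- function(dir = tempfile("cohort")) {
  dir.create(dir)
  writeLines(c("id,gene_a,gene_b",
               "p1,1.0,2.0",
               "p2,2.5,1.0",
               "p3,0.5,3.5"), file.path(dir, "expression.csv"))
  writeLines(c("id,age,chemo",
               "p1,55,1",
               "p2,,0",
               "p3,61,1"), file.path(dir, "clinical.csv"))
  writeLines(c("id,time_months,event",
               "p1,40,1",
               "p2,70,0",
               "p3,40,0"), file.path(dir, "survival.csv"))
  dir
}

# deterministic split cohort for model tests: small but trainable
toy_split_cohort <- function(seed = 11, n_labeled = 120, n_unlabeled = 80,
                             effect_size = 2.5, ...) {
  cfg <- synthetic_config(n_labeled = n_labeled, n_unlabeled = n_unlabeled,
                          effect_size = effect_size, seed = seed, ...)
  gen <- generate_cohort(cfg)
  gen$cohort <- split_cohort(gen$cohort,
                             c(train = 0.5, validation = 0.25, test = 0.25),
                             seed = seed)
  gen
}

# one small trained fit shared by prediction/attribution tests
shared_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- toy_split_cohort()
      cfg <- train_config(epochs = 30, batch_size = 500, learning_rate = 0.01,
                          patience = Inf, seed = 5)
      cache <<- list(gen = gen, fit = train_prognet(gen$cohort, cfg))
    }
    cache
  }
})

# build a 1-gene, 1-latent VAE whose decoder is linear to numerical precision
# (tiny first-layer weight, rescaled head) with a freely chosen encoder
linear_toy_vae <- function(w, b, log_var_x, mu_q, lv_q, s = 2e-5) {
  vae <- prog_vae(1, latent_dim = 1, hidden = 1)
  zero <- function(l) { l$weight_mean[] <- 0; l$bias_mean[] <- 0; l$weight_log_var[] <- -40; l }
  for (nm in prognet:::vae_layer_names) vae[[nm]] <- zero(vae[[nm]])
  vae$dec1$weight_mean[1, 1] <- s                 # h = tanh(s z) ~ s z
  vae$dec_mu$weight_mean[1, 1] <- w / s           # mean = w z + b
  vae$dec_mu$bias_mean <- b
  vae$dec_lv$bias_mean <- log_var_x
  vae$enc_mu$bias_mean <- mu_q                    # q(z|x) = N(mu_q, exp(lv_q))
  vae$enc_lv$bias_mean <- lv_q
  vae
}

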