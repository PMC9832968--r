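# Model surface and semi-supervised training: votes, vote combination,
# per-type loss dispatch, the marginalization identity, training dynamics,
# cross-validation and seed ensembles.

zeroed_model <- function(n_genes = 4, n_clinical = 3) {
  model <- prognet(n_genes, n_clinical,
                   train_config(latent_dim = 2, hidden = 3, hidden_clf = 2), 0.37)
  params <- prognet:::model_params(model)
  for (nm in names(params)) if (!nm %in% c("w1", "w2")) params[[nm]][] <- 0
  prognet:::set_model_params(model, params)
}

test_that("zero-weight subnetworks vote 0.5 and probabilities stay in (0,1)", {
  model <- zeroed_model()
  expect_equal(classify_microarray(model, rep(0.3, 4)), 0.5)
  expect_equal(classify_clinical(model, c(0.1, -0.2, 0.5))$prob, 0.5)
  set.seed(2)
  model2 <- prognet(4, 3, train_config(latent_dim = 2, hidden = 3, hidden_clf = 2))
  p <- classify_microarray(model2, matrix(rnorm(4000), 1000, 4))
  expect_true(all(p > 0 & p < 1))
})

test_that("fully masked clinical vectors fall back to the class prior", {
  model <- zeroed_model()
  res <- classify_clinical(model, c(NA_real_, NA_real_, NA_real_))
  expect_false(res$available)
  expect_equal(res$prob, model$prior_poor)
  # masking a zero-weight feature leaves the vote unchanged
  m2 <- zeroed_model()
  a <- classify_clinical(m2, c(0.5, 0.5, 0.5))$prob
  b <- classify_clinical(m2, c(0.5, NA, 0.5))$prob
  expect_equal(a, b)
})

test_that("vote combination averages weighted logits over available modalities", {
  expect_equal(combine_votes(list(y1_hat = 0.8, y2_hat = 0.8)), 0.8)
  expect_equal(combine_votes(list(y1_hat = plogis(1), y2_hat = plogis(-1))), 0.5)
  # single available modality: the weighted vote passes through
  expect_equal(combine_votes(list(y1_hat = 0.73, y2_hat = NA_real_, w1 = 1)), 0.73)
  expect_equal(combine_votes(list(y1_hat = NA_real_, y2_hat = 0.31, w2 = 1)), 0.31)
  # learnable weights scale the logit before averaging
  expect_equal(combine_votes(list(y1_hat = plogis(1), y2_hat = NA_real_, w1 = 2)),
               plogis(2))
  expect_error(combine_votes(list(y1_hat = NA_real_, y2_hat = NA_real_)), "no modality")
})

test_that("labeled loss decomposes and the classifier term scales with alpha", {
  set.seed(21)
  model <- prognet(4, 3, train_config(latent_dim = 2, hidden = 3, hidden_clf = 2), 0.4)
  x <- rnorm(4); cl <- c(0.2, NA, -1)
  l0 <- labeled_loss(model, x, cl, "poor", alpha = 0, seed = 7)
  expect_equal(l0$classifier_term, 0)
  l1 <- labeled_loss(model, x, cl, "poor", alpha = 1, seed = 7)
  l2 <- labeled_loss(model, x, cl, "poor", alpha = 2, seed = 7)
  expect_equal(l2$classifier_term, 2 * l1$classifier_term)
  expect_equal(l1$labeled_term, l2$labeled_term)
  # total equals the hand-assembled sum of its reported parts
  expect_equal(l1$total,
               l1$labeled_term + l1$classifier_term + l1$kl_weights + l1$l2_term)
  expect_true(is.finite(l1$total))
  expect_error(labeled_loss(model, x, cl, "undefined"), "defined label")
})

test_that("unlabeled loss equals the two-label enumeration oracle", {
  set.seed(31)
  model <- prognet(5, 3, train_config(latent_dim = 2, hidden = 4, hidden_clf = 3), 0.42)
  for (clinical in list(c(0.4, -0.3, 1.1), NULL)) {
    x <- rnorm(5)
    u <- unlabeled_loss(model, x, clinical, seed = 55)
    bound_poor <- labeled_loss(model, x, clinical, "poor", alpha = 0, seed = 55)$labeled_term
    bound_good <- labeled_loss(model, x, clinical, "good", alpha = 0, seed = 55)$labeled_term
    # classifier posterior from the deterministic votes (combined when the
    # clinical modality is present, microarray alone otherwise)
    y1 <- classify_microarray(model, x)
    bundle <- list(y1_hat = y1, w1 = model$w_shared[[1]], w2 = model$w_shared[[2]])
    bundle$y2_hat <- if (is.null(clinical)) NA_real_
                     else classify_clinical(model, clinical)$prob
    q <- combine_votes(bundle)
    H <- -q * log(q) - (1 - q) * log(1 - q)
    oracle <- q * bound_poor + (1 - q) * bound_good - H
    expect_lt(abs(u$unlabeled_term - oracle), 1e-10)
    # entropy is reported with its sign and matches -H
    expect_lt(abs(u$entropy_term + H), 1e-10)
  }
})

test_that("a confident posterior has vanishing entropy bonus", {
  model <- zeroed_model()
  params <- prognet:::model_params(model)
  params$clf_x2.b[] <- 30 # saturated microarray vote
  model <- prognet:::set_model_params(model, params)
  u <- unlabeled_loss(model, rep(0, 4), NULL, seed = 1)
  expect_lt(abs(u$entropy_term), 1e-9)
})

test_that("duplicating a patient doubles the batch data loss", {
  set.seed(41)
  model <- prognet(4, 3, train_config(latent_dim = 2, hidden = 3, hidden_clf = 2), 0.5)
  params <- prognet:::model_params(model)
  # pin the encoder variance at its lower clip so the latent draw is
  # essentially the mean and the comparison is draw-independent
  params$vae.enc_lv.W[] <- 0
  params$vae.enc_lv.b[] <- -40
  X <- matrix(rnorm(4), 1)
  batch1 <- list(X = X, C2 = prognet:::clinical_design(matrix(c(1, NA, 0), 1), 3),
                 mc = 1, ylab = 1, is_lab = 1)
  batch2 <- lapply(batch1, function(v) if (is.matrix(v)) rbind(v, v) else c(v, v))
  hp <- list(alpha = 1, lambda = 0, kl_temper = 1, n_total = 1, prior_poor = 0.5,
             variant = "full", weight_mode = "mean")
  set.seed(5); lf1 <- prognet:::loss_forward(params, batch1, hp)
  set.seed(5); lf2 <- prognet:::loss_forward(params, batch2, hp)
  # per-patient means are identical, so the summed data loss doubles
  d1 <- lf1$comps$labeled_term + lf1$comps$classifier_term
  d2 <- lf2$comps$labeled_term + lf2$comps$classifier_term
  expect_equal(d2, d1, tolerance = 1e-3)
  expect_equal(lf2$comps$classifier_term, lf1$comps$classifier_term,
               tolerance = 1e-12)
})

test_that("loss dispatch covers every patient type without dropping records", {
  gen <- toy_split_cohort(seed = 13, n_labeled = 40, n_unlabeled = 30,
                          type_proportions = c(II = 0.6, III = 0.3, IV = 0.1))
  co <- gen$cohort
  expect_setequal(unique(co$ptype), c("I", "II", "III", "IV"))
  std <- standardize(co, fit_on = "train", include_unlabeled = TRUE)
  rows <- which(co$split %in% c("train", "unlabeled"))
  batch <- prognet:::make_batch(std$cohort, rows, length(co$clinical_names))
  # every joint-training record is either labeled or unlabeled, never both
  expect_equal(length(rows), sum(batch$is_lab) + sum(1 - batch$is_lab))
  expect_true(all(batch$is_lab[co$ptype[rows] %in% c("I", "IV")] == 1))
  expect_true(all(batch$is_lab[co$label[rows] == "undefined"] == 0))
})

test_that("training reduces the supervised cross-entropy and is reproducible", {
  gen <- toy_split_cohort(seed = 17, n_labeled = 200, n_unlabeled = 100,
                          effect_size = 2)
  cfg <- train_config(epochs = 100, batch_size = 500, learning_rate = 0.01,
                      alpha = 3, patience = Inf, unlabeled_warmup = 0, seed = 2)
  fit <- train_prognet(gen$cohort, cfg)
  ce <- fit$history$classifier_term
  expect_lt(mean(tail(ce, 5)), 0.5 * ce[1])
  # bitwise reproducibility under an identical seed
  fit2 <- train_prognet(gen$cohort, cfg)
  expect_identical(prognet:::model_params(fit$model),
                   prognet:::model_params(fit2$model))
  expect_identical(fit$history, fit2$history)
  expect_error(train_prognet(subset_cohort(gen$cohort,
                                           which(gen$cohort$split == "test")), cfg),
               "empty")
})

test_that("without supervision the classifier stays near chance", {
  gen <- toy_split_cohort(seed = 19, n_labeled = 80, n_unlabeled = 0)
  cfg <- train_config(epochs = 40, batch_size = 500, learning_rate = 0.01,
                      alpha = 0, patience = Inf, seed = 3,
                      variant = "no_unlabeled")
  fit <- train_prognet(gen$cohort, cfg)
  pred <- predict(fit, gen$cohort)
  expect_lt(mean(abs(pred$y_tilde - 0.5)), 0.15)
})

test_that("cross-validation partitions folds and prefers a config that learns", {
  gen <- toy_split_cohort(seed = 23, n_labeled = 80, n_unlabeled = 40,
                          effect_size = 3)
  good_cfg <- train_config(epochs = 40, batch_size = 500, learning_rate = 0.01,
                           alpha = 3, patience = Inf, unlabeled_warmup = 10,
                           hidden = 8, seed = 1)
  dead_cfg <- good_cfg
  dead_cfg$learning_rate <- 1e-9 # cannot move off initialization
  one <- cross_validate(gen$cohort, list(good_cfg), k = 4, seed = 5)
  expect_identical(one$best_config, good_cfg)
  labeled <- which(gen$cohort$split %in% c("train", "validation") &
                     gen$cohort$label %in% c("good", "poor"))
  expect_true(all(one$folds[labeled] %in% 1:4))
  expect_true(all(table(one$folds[labeled]) >= 1))
  two <- cross_validate(gen$cohort, list(dead_cfg, good_cfg), k = 4, seed = 5)
  expect_identical(two$best_config, good_cfg)
  expect_error(cross_validate(gen$cohort, list(good_cfg), k = 1000), "minority")
})

test_that("a one-member ensemble reproduces the single model", {
  gen <- toy_split_cohort(seed = 29, n_labeled = 60, n_unlabeled = 20)
  cfg <- train_config(epochs = 15, batch_size = 500, learning_rate = 0.01,
                      patience = Inf, seed = 1)
  ens <- train_ensemble(gen$cohort, cfg, n_members = 1, base_seed = 10)
  cfg$seed <- 11
  single <- train_prognet(gen$cohort, cfg)
  p1 <- predict(ens, gen$cohort)
  p2 <- predict(single, gen$cohort)
  expect_equal(p1$y_tilde, p2$y_tilde)
  # ensemble predictions are reproducible bit for bit from the members
  expect_identical(predict(ens, gen$cohort)$y_tilde, p1$y_tilde)
})

test_that("prediction bundles respect availability and internal consistency", {
  sf <- shared_fit()
  co <- sf$gen$cohort
  model <- sf$fit$model
  pred <- predict(model, co)
  expect_true(all(pred$y_tilde >= 0 & pred$y_tilde <= 1))
  type3 <- which(co$ptype == "III")
  expect_true(all(is.na(pred$y2_hat[type3])))
  # final vote equals combine_votes applied to the bundle's own parts
  redo <- combine_votes(list(y1_hat = pred$y1_hat, y2_hat = pred$y2_hat,
                             w1 = model$w_shared[[1]], w2 = model$w_shared[[2]]))
  expect_equal(redo, pred$y_tilde, tolerance = 1e-12)
  # a Type III record predicts from the weighted microarray vote alone
  rec <- get_record(co, co$ids[type3[1]])
  b <- predict_record(model, rec)
  expect_true(is.na(b$y2_hat))
  expect_equal(b$y_tilde, plogis(model$w_shared[[1]] * qlogis(b$y1_hat)))
})
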