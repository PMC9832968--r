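# Packaged study protocols: the unlabeled-data dose-response experiment, the
# loss-ablation comparison, and the seed-ensemble variance comparison. Each
# runs on synthetic cohorts with known ground truth at desk scale; the
# methods vignette discusses the problem sizes and their rationale.

#' Subset a cohort to a set of patient rows
#'
#' @param cohort a `prog_cohort`.
#' @param rows integer indices to keep.
#' @return the reduced `prog_cohort`.
#' @export
subset_cohort <- function(cohort, rows) {
  cohort$ids <- cohort$ids[rows]
  cohort$expression <- cohort$expression[rows, , drop = FALSE]
  cohort$clinical <- cohort$clinical[rows, , drop = FALSE]
  cohort$clinical_present <- cohort$clinical_present[rows]
  cohort$survival <- cohort$survival[rows, ]
  cohort$label <- cohort$label[rows]
  cohort$ptype <- cohort$ptype[rows]
  cohort$split <- cohort$split[rows]
  cohort
}

# shared experiment conditions: 100 labeled training patients, a large
# held-out labeled test set, and a Type II/III unlabeled pool; full-batch
# Adam with the supervised warmup, no validation split (fixed epoch budget)
experiment_train_config <- function(seed) {
  train_config(epochs = 120, batch_size = 4000, learning_rate = 0.01,
               alpha = 3, hidden = 16, patience = Inf, unlabeled_warmup = 48,
               seed = seed)
}

experiment_cohort <- function(seed, n_test = 850, n_unlabeled = 2000,
                              effect_size = 1.5) {
  cfg <- synthetic_config(n_labeled = 100 + n_test, n_unlabeled = n_unlabeled,
                          effect_size = effect_size, seed = seed)
  gen <- generate_cohort(cfg)
  gen$cohort$split[seq_len(100)] <- "train"
  gen$cohort$split[100 + seq_len(n_test)] <- "test"
  gen
}

test_auroc <- function(predictor, cohort) {
  rows <- which(cohort$split %in% "test")
  pred <- stats::predict(predictor, cohort, rows = rows)
  auroc(pred$y_tilde, as.integer(cohort$label[rows] == "poor"))
}

#' Unlabeled-data dose-response experiment
#'
#' For each seed, generates one synthetic cohort (100 labeled training
#' patients, `n_test` labeled test patients, a 2000-patient unlabeled pool)
#' and trains the full semi-supervised model with nested unlabeled subsets
#' of the requested sizes, holding every hyper-parameter fixed. Reports the
#' test AUROC per cell, the mean dose-response curve, a one-sided paired
#' test of the largest-pool vs no-pool difference, and one-sided paired
#' tests for a significant decrease at each adjacent step (the
#' population-level reading of "performance does not drop with more
#' unlabeled data" — sample means of a noisy quantity are never exactly
#' monotone).
#'
#' @param sizes unlabeled pool sizes (default 0 to 2000 in steps of 400).
#' @param n_seeds number of independent cohorts/seeds (default 10).
#' @param base_seed seed offset; cohort `i` uses `base_seed + i`.
#' @param n_test labeled test-set size per cohort.
#' @param effect_size per-gene class shift of the generator.
#' @return list with `auroc` (seeds x sizes matrix), `means`, `gain`
#'   (per-seed endpoint differences), `p_gain` (one-sided paired t),
#'   `p_adjacent_decrease` (one-sided paired t p-values that each step
#'   DECREASED; large values mean no evidence of degradation).
#' @export
ssl_gain_experiment <- function(sizes = c(0, 400, 800, 1200, 1600, 2000),
                                n_seeds = 10, base_seed = 1000,
                                n_test = 850, effect_size = 1.5) {
  res <- matrix(NA_real_, n_seeds, length(sizes),
                dimnames = list(NULL, paste0("u", sizes)))
  for (s in seq_len(n_seeds)) {
    gen <- experiment_cohort(base_seed + s, n_test = n_test,
                             n_unlabeled = max(sizes),
                             effect_size = effect_size)
    n_lab_rows <- 100 + n_test
    for (j in seq_along(sizes)) {
      u <- sizes[j]
      co <- subset_cohort(gen$cohort,
                          c(seq_len(n_lab_rows),
                            if (u > 0) n_lab_rows + seq_len(u)))
      fit <- train_prognet(co, experiment_train_config(seed = s))
      res[s, j] <- test_auroc(fit$model, co)
    }
  }
  means <- colMeans(res)
  gain <- res[, ncol(res)] - res[, 1L]
  p_gain <- stats::t.test(gain, alternative = "greater")$p.value
  p_adj <- vapply(seq_len(ncol(res) - 1L), function(j) {
    d <- res[, j + 1L] - res[, j]
    stats::t.test(d, alternative = "less")$p.value
  }, 0)
  list(auroc = res, sizes = sizes, means = means, gain = gain,
       p_gain = p_gain, p_adjacent_decrease = p_adj)
}

#' Loss-ablation experiment
#'
#' Trains the three model variants on identical synthetic cohorts: the full
#' semi-supervised model, the model without the Type II/III (unlabeled)
#' losses, and the model without any VAE term (classifiers only), and
#' reports mean test AUROC per variant over the seeds. The expected ordering
#' is full >= no-unlabeled >= no-VAE.
#'
#' @param n_seeds number of independent cohorts (default 10).
#' @param base_seed seed offset.
#' @param n_unlabeled unlabeled pool size for the full variant.
#' @param n_test labeled test-set size.
#' @return list with `auroc` (seeds x 3), `means`.
#' @export
ablation_experiment <- function(n_seeds = 10, base_seed = 2000,
                                n_unlabeled = 1000, n_test = 850) {
  variants <- c("full", "no_unlabeled", "no_vae")
  res <- matrix(NA_real_, n_seeds, 3L, dimnames = list(NULL, variants))
  for (s in seq_len(n_seeds)) {
    gen <- experiment_cohort(base_seed + s, n_test = n_test,
                             n_unlabeled = n_unlabeled)
    for (v in variants) {
      cfg <- experiment_train_config(seed = s)
      cfg$variant <- v
      fit <- train_prognet(gen$cohort, cfg)
      res[s, v] <- test_auroc(fit$model, gen$cohort)
    }
  }
  list(auroc = res, means = colMeans(res))
}

#' Seed-ensemble variance experiment
#'
#' Compares, patient by patient, the variance of logit-averaged ensemble
#' predictions across replicate ensembles with the variance of single-model
#' predictions across seeds, on one synthetic test set. Averaging logits
#' over members shrinks the initialization/training noise roughly by the
#' member count, so the ensemble variance should be well below the
#' single-model variance.
#'
#' @param n_members members per ensemble.
#' @param n_replicates replicate ensembles (disjoint seed blocks).
#' @param n_single single-model seeds for the reference variance.
#' @param base_seed seed offset.
#' @param n_test test-set size.
#' @return list with per-patient variance vectors `var_ensemble`,
#'   `var_single`, and their means.
#' @export
ensemble_variance_experiment <- function(n_members = 8, n_replicates = 10,
                                         n_single = 40, base_seed = 3000,
                                         n_test = 200) {
  gen <- experiment_cohort(base_seed, n_test = n_test, n_unlabeled = 200)
  co <- gen$cohort
  cfg <- experiment_train_config(seed = 1)
  cfg$epochs <- 60
  cfg$unlabeled_warmup <- 24
  test_rows <- which(co$split %in% "test")

  single_logits <- sapply(seq_len(n_single), function(i) {
    cfg$seed <- i
    fit <- train_prognet(co, cfg)
    stats::predict(fit$model, co, rows = test_rows)$logit_tilde
  })
  ens_logits <- sapply(seq_len(n_replicates), function(r) {
    ens <- train_ensemble(co, cfg, n_members = n_members,
                          base_seed = n_single + (r - 1L) * n_members)
    stats::predict(ens, co, rows = test_rows)$logit_tilde
  })
  # compare on the probability scale, per patient
  var_single <- apply(plogis(single_logits), 1L, stats::var)
  var_ens <- apply(plogis(ens_logits), 1L, stats::var)
  list(var_ensemble = var_ens, var_single = var_single,
       mean_var_ensemble = mean(var_ens), mean_var_single = mean(var_single),
       fraction_reduced = mean(var_ens < var_single))
}
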