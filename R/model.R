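# The semi-supervised multimodal prognosis network: a class-conditional
# expression VAE plus two subnetwork classifiers (microarray, clinical)
# whose weighted votes are combined with equal importance by a learnable
# shared output layer.

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size (set >= cohort size for full-batch).
#' @param alpha weight of the supervised classifier cross-entropy term;
#'   `NULL` (default) uses `0.1 * n_joint / n_labeled`, which keeps the
#'   supervised term comparable to the generative term as the unlabeled pool
#'   grows.
#' @param lambda L2 penalty on Bayesian weight means.
#' @param kl_temper temperature on the variational-dropout weight KL
#'   (default 0.1, a tempered/cold weight posterior): the log-uniform prior
#'   at full strength prunes most of a small network when the joint training
#'   set has only a few hundred patients.
#' @param latent_dim,hidden VAE latent dimension and hidden width.
#' @param hidden_clf hidden width of the two subnetwork classifiers.
#' @param unlabeled_warmup epochs over which the unlabeled-loss weight ramps
#'   linearly from 0 to 1 (0 disables). Anchoring the classifiers on the
#'   supervised term before the marginalized bound and its entropy bonus
#'   engage keeps the label channel from locking onto a mis-aligned
#'   clustering of the unlabeled pool.
#' @param patience early-stopping patience (epochs without validation AUROC
#'   improvement); `Inf` disables early stopping.
#' @param eval_every validate every this many epochs.
#' @param seed integer seed; training is bit-reproducible under a fixed seed.
#' @param variant `"full"` (default), `"no_unlabeled"` (Type II/III losses
#'   removed) or `"no_vae"` (classifiers only, no generative term) — the
#'   ablation axes.
#' @return a `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 200, batch_size = 64,
                         alpha = NULL, lambda = 1e-4, kl_temper = 0.1,
                         latent_dim = 8, hidden = 32, hidden_clf = 16,
                         unlabeled_warmup = 30, patience = 20,
                         eval_every = 1, seed = 1,
                         variant = c("full", "no_unlabeled", "no_vae")) {
  variant <- match.arg(variant)
  cfg <- as.list(environment())
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1, lambda >= 0,
            kl_temper >= 0, latent_dim >= 1, hidden >= 1, hidden_clf >= 1)
  if (!is.null(alpha) && alpha < 0) stop("`alpha` must be >= 0")
  structure(cfg, class = "train_config")
}

#' Construct an untrained prognosis network
#'
#' @param n_genes,n_clinical input dimensions (clinical inputs are doubled
#'   internally by the observed-flag channel).
#' @param config a [train_config()] (architecture fields are read from it).
#' @param prior_poor prior probability of the poor class; set to the
#'   empirical labeled-training frequency by [train_prognet()].
#' @return a `prognet_model`.
#' @export
prognet <- function(n_genes, n_clinical, config = train_config(),
                    prior_poor = 0.5) {
  m <- structure(list(
    vae = prog_vae(n_genes, config$latent_dim, config$hidden, bayesian = TRUE),
    clf_x1 = bayes_linear(
      if (config$variant == "no_vae") n_genes else config$hidden,
      config$hidden_clf),
    clf_x2 = bayes_linear(config$hidden_clf, 1L),
    clf_c1 = bayes_linear(max(1L, 2L * n_clinical), config$hidden_clf),
    clf_c2 = bayes_linear(config$hidden_clf, 1L),
    w_shared = c(w1 = 1, w2 = 1),
    prior_poor = prior_poor,
    n_genes = as.integer(n_genes),
    n_clinical = as.integer(n_clinical),
    config = config,
    stats = NULL
  ), class = "prognet_model")
  m
}

#' @export
print.prognet_model <- function(x, ...) {
  cat(sprintf(paste0("prognet_model: %d genes + %d clinical features, ",
                     "latent dim %d, variant \"%s\"%s\n"),
              x$n_genes, x$n_clinical, x$vae$latent_dim, x$config$variant,
              if (is.null(x$stats)) " (untrained)" else ""))
  cat(sprintf("shared vote weights: w1=%.3f w2=%.3f; prior P(poor)=%.3f\n",
              x$w_shared[1], x$w_shared[2], x$prior_poor))
  invisible(x)
}

clf_layer_names <- c("clf_x1", "clf_x2", "clf_c1", "clf_c2")

# ---- deterministic (mean-propagation) forward passes ----

# the microarray classifier reads the VAE trunk representation, so
# generative training of the encoder (labeled or unlabeled) directly
# improves the classifier's feature space; the no-VAE ablation removes the
# representation and classifies the raw genes instead
microarray_logit <- function(model, X) {
  inp <- if (identical(model$config$variant, "no_vae")) X
         else vae_trunk(model$vae, X)
  h <- tanh(bl_forward_mean(model$clf_x1, inp))
  as.numeric(bl_forward_mean(model$clf_x2, h))
}

# clinical design matrix: masked cells as zeros, observed flags appended
clinical_design <- function(C, n_clinical) {
  if (n_clinical == 0L) return(matrix(0, nrow(C), 1L))
  M <- 1 * !is.na(C)
  Cz <- C; Cz[is.na(Cz)] <- 0
  cbind(Cz * M, M)
}

clinical_logit <- function(model, C) {
  X2 <- clinical_design(C, model$n_clinical)
  h <- tanh(bl_forward_mean(model$clf_c1, X2))
  as.numeric(bl_forward_mean(model$clf_c2, h))
}

#' Microarray subnetwork vote
#'
#' Deterministic (mean-propagated) probability of poor prognosis from the
#' expression modality alone.
#'
#' @param model a `prognet_model`.
#' @param x standardized expression vector or matrix (patients x genes).
#' @return probabilities in (0, 1).
#' @export
classify_microarray <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != model$n_genes) stop("expected ", model$n_genes, " genes")
  plogis(microarray_logit(model, X))
}

#' Clinical subnetwork vote
#'
#' Mask-aware: missing entries contribute zero input (plus an observed-flag
#' channel); there is no imputation. A fully masked vector returns the class
#' prior with the modality flagged unavailable.
#'
#' @param model a `prognet_model`.
#' @param clinical standardized clinical vector or matrix with `NA` for
#'   masked cells.
#' @return list with `prob` and logical `available` (per patient).
#' @export
classify_clinical <- function(model, clinical) {
  C <- if (is.matrix(clinical)) clinical else matrix(clinical, nrow = 1L)
  if (ncol(C) != model$n_clinical) stop("expected ", model$n_clinical, " clinical features")
  available <- rowSums(!is.na(C)) > 0L
  prob <- plogis(clinical_logit(model, C))
  prob[!available] <- model$prior_poor
  list(prob = prob, available = available)
}

#' Combine per-modality votes through the shared output layer
#'
#' The final logit is the equal-weight mean, over available modalities, of
#' each modality's learnable weighted logit:
#' `logit(y_tilde) = mean_i w_i * logit(y_i_hat)`. With a single available
#' modality the final vote is that weighted vote alone.
#'
#' @param bundle list or data.frame with `y1_hat`, `y2_hat` (probabilities;
#'   `NA` = modality unavailable) and optionally `w1`, `w2`.
#' @param w shared weights, used when the bundle carries none.
#' @return final probability `y_tilde`.
#' @export
combine_votes <- function(bundle, w = c(1, 1)) {
  w1 <- if (!is.null(bundle$w1)) bundle$w1 else w[1L]
  w2 <- if (!is.null(bundle$w2)) bundle$w2 else w[2L]
  l1 <- qlogis(bundle$y1_hat)
  l2 <- qlogis(bundle$y2_hat)
  a1 <- !is.na(l1); a2 <- !is.na(l2)
  if (any(!a1 & !a2)) stop("no modality available for some patients")
  num <- ifelse(a1, w1 * l1, 0) + ifelse(a2, w2 * l2, 0)
  plogis(num / (a1 + a2))
}

# parameter flattening -------------------------------------------------------


model_params <- function(model) {
  out <- list()
  grab <- function(layer, prefix) {
    out[[paste0(prefix, ".W")]] <<- layer$weight_mean
    out[[paste0(prefix, ".V")]] <<- layer$weight_log_var
    out[[paste0(prefix, ".b")]] <<- matrix(layer$bias_mean, 1L)
  }
  for (nm in vae_layer_names) grab(model$vae[[nm]], paste0("vae.", nm))
  for (nm in clf_layer_names) grab(model[[nm]], nm)
  out$w1 <- matrix(model$w_shared[1L], 1L, 1L)
  out$w2 <- matrix(model$w_shared[2L], 1L, 1L)
  out
}

set_model_params <- function(model, params) {
  put <- function(layer, prefix) {
    layer$weight_mean <- params[[paste0(prefix, ".W")]]
    layer$weight_log_var <- params[[paste0(prefix, ".V")]]
    layer$bias_mean <- as.numeric(params[[paste0(prefix, ".b")]])
    layer
  }
  for (nm in vae_layer_names) model$vae[[nm]] <- put(model$vae[[nm]], paste0("vae.", nm))
  for (nm in clf_layer_names) model[[nm]] <- put(model[[nm]], nm)
  model$w_shared <- c(w1 = params$w1[1L], w2 = params$w2[1L])
  model
}

n_model_params <- function(model) {
  sum(vapply(model_params(model), length, 0L))
}
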