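# Semi-supervised training: type-dispatched losses on the autodiff tape,
# Adam optimization, early stopping, cross-validation and seed ensembles.

# Assemble the tape for one minibatch. `batch` carries constants only:
#   X      n x G standardized expression
#   C2     n x 2D clinical design (masked zeros + observed flags)
#   mc     n-vector, 1 = clinical modality available
#   ylab   n-vector in {0,1} (NA -> 0; masked out for unlabeled rows)
#   is_lab n-vector, 1 = label defined
# `hp`: alpha, lambda, n_total, prior_poor, variant, weight_mode
loss_forward <- function(params, batch, hp) {
  tape <- ad_tape()
  pn <- lapply(params, function(v) ad_param(tape, v))
  n <- nrow(batch$X)
  use_vae <- hp$variant != "no_vae"
  use_unl <- hp$variant == "full"
  sample_w <- identical(hp$weight_mode, "sample")

  layer_nodes <- function(prefix) {
    list(W = pn[[paste0(prefix, ".W")]], V = pn[[paste0(prefix, ".V")]],
         b = pn[[paste0(prefix, ".b")]])
  }
  fwd <- function(prefix, Xn) {
    p <- layer_nodes(prefix)
    if (sample_w) {
      dims <- dim(params[[paste0(prefix, ".W")]])
      eps <- matrix(stats::rnorm(prod(dims)), dims[1L], dims[2L])
      bl_tape_sample(tape, p, Xn, eps)
    } else {
      bl_tape_mean(tape, p, Xn)
    }
  }

  # label-free encoder trunk: the learned low-dimensional gene-profile
  # representation, shared by the latent heads and the microarray
  # classifier (that sharing is how generative training, labeled or
  # unlabeled, improves classification); the no-VAE ablation removes the
  # representation and the classifier reads the raw genes
  Xc <- ad_const(tape, batch$X)
  henc <- if (use_vae) ad_tanh(tape, fwd("vae.enc1", Xc)) else NULL
  clf_in <- if (use_vae) henc else Xc

  # classifier votes
  lx <- fwd("clf_x2", ad_tanh(tape, fwd("clf_x1", clf_in)))
  C2c <- ad_const(tape, batch$C2)
  lc <- fwd("clf_c2", ad_tanh(tape, fwd("clf_c1", C2c)))
  mc <- matrix(batch$mc, ncol = 1L)
  t1 <- ad_mul(tape, pn$w1, lx)
  t2 <- ad_scale(tape, ad_mul(tape, pn$w2, lc), mc)
  lcomb <- ad_scale(tape, ad_add(tape, t1, t2), 1 / (1 + mc))

  # class-conditional VAE bounds for both label values
  nL <- list()
  if (use_vae) {
    G <- ncol(batch$X)
    L <- ncol(params$vae.enc_mu.W)
    for (yv in c(0, 1)) {
      hy <- ad_cbind_const(tape, henc, yv)
      mu <- fwd("vae.enc_mu", hy)
      lv <- ad_clip(tape, fwd("vae.enc_lv", hy), -LATENT_LOGVAR_CLIP, LATENT_LOGVAR_CLIP)
      eps_z <- matrix(stats::rnorm(n * L), n, L)
      z <- ad_add(tape, mu, ad_mul(tape, ad_exp(tape, ad_scale(tape, lv, 0.5)),
                                   ad_const(tape, eps_z)))
      dh <- ad_tanh(tape, fwd("vae.dec1", ad_cbind_const(tape, z, yv)))
      ycol <- ad_const(tape, matrix(yv, n, 1L))
      xm <- ad_add(tape, fwd("vae.dec_mu", dh), fwd("vae.dec_skip", ycol))
      xlv <- ad_clip(tape, fwd("vae.dec_lv", dh), -LATENT_LOGVAR_CLIP, LATENT_LOGVAR_CLIP)
      sq <- ad_square(tape, ad_sub(tape, Xc, xm))
      dens <- ad_add(tape, ad_shift(tape, xlv, log(2 * pi)),
                     ad_mul(tape, sq, ad_exp(tape, ad_neg(tape, xlv))))
      recon <- ad_scale(tape, ad_rowsums(tape, dens), -0.5)
      klz <- ad_scale(tape, ad_rowsums(tape, ad_sub(tape,
        ad_add(tape, ad_exp(tape, lv), ad_square(tape, mu)),
        ad_shift(tape, lv, 1))), 0.5)
      py <- if (yv == 1) hp$prior_poor else 1 - hp$prior_poor
      nL[[yv + 1L]] <- ad_shift(tape, ad_sub(tape, klz, recon), -log(py))
    }
  }

  ylab <- matrix(batch$ylab, ncol = 1L)
  wlab <- matrix(batch$is_lab, ncol = 1L)
  ce_of <- function(lgt) ad_sub(tape, ad_softplus(tape, lgt), ad_mul(tape, lgt, ad_const(tape, ylab)))
  ce_sum <- ad_add(tape, ce_of(lx),
                   ad_add(tape, ad_scale(tape, ce_of(lc), mc), ce_of(lcomb)))
  lab_ce <- ad_sum(tape, ad_scale(tape, ce_sum, wlab))

  comps <- list()
  total <- ad_scale(tape, lab_ce, hp$alpha / n)
  comps$classifier_term <- hp$alpha * ad_value(tape, lab_ce)[1L] / n

  if (use_vae) {
    nl_lab <- ad_add(tape, ad_scale(tape, nL[[2L]], ylab),
                     ad_scale(tape, nL[[1L]], 1 - ylab))
    lab_gen <- ad_sum(tape, ad_scale(tape, nl_lab, wlab))
    total <- ad_add(tape, total, ad_scale(tape, lab_gen, 1 / n))
    comps$labeled_term <- ad_value(tape, lab_gen)[1L] / n
  } else {
    comps$labeled_term <- 0
  }

  if (use_vae && use_unl) {
    uw <- if (is.null(hp$unl_weight)) 1 else hp$unl_weight
    wunl <- (1 - wlab) * uw
    q <- ad_sigmoid(tape, lcomb)
    H <- ad_sub(tape, ad_softplus(tape, lcomb), ad_mul(tape, q, lcomb))
    Eb <- ad_add(tape, ad_mul(tape, q, nL[[2L]]),
                 ad_mul(tape, ad_shift(tape, ad_neg(tape, q), 1), nL[[1L]]))
    U <- ad_sub(tape, Eb, H)
    unl <- ad_sum(tape, ad_scale(tape, U, wunl))
    total <- ad_add(tape, total, ad_scale(tape, unl, 1 / n))
    comps$unlabeled_term <- ad_value(tape, unl)[1L] / n
    comps$entropy_term <- -sum((1 - batch$is_lab) * ad_value(tape, H)) / n
  } else {
    comps$unlabeled_term <- 0
    comps$entropy_term <- 0
  }

  # weight KL + L2 over the layers in use, scaled per-dataset
  prefixes <- c(if (use_vae) paste0("vae.", vae_layer_names), clf_layer_names)
  kl_tot <- NULL; l2_tot <- NULL
  for (pf in prefixes) {
    kk <- bl_tape_kl(tape, layer_nodes(pf))
    kl_tot <- if (is.null(kl_tot)) kk$kl else ad_add(tape, kl_tot, kk$kl)
    l2_tot <- if (is.null(l2_tot)) kk$l2 else ad_add(tape, l2_tot, kk$l2)
  }
  tau <- if (is.null(hp$kl_temper)) 1 else hp$kl_temper
  reg <- ad_scale(tape, ad_add(tape, ad_scale(tape, kl_tot, tau),
                               ad_scale(tape, l2_tot, hp$lambda)),
                  1 / hp$n_total)
  total <- ad_add(tape, total, reg)
  comps$kl_weights <- ad_value(tape, kl_tot)[1L]
  comps$l2_term <- hp$lambda * ad_value(tape, l2_tot)[1L] / hp$n_total
  comps$total <- ad_value(tape, total)[1L]
  if (use_vae) {
    comps$bound_good <- as.numeric(ad_value(tape, nL[[1L]]))
    comps$bound_poor <- as.numeric(ad_value(tape, nL[[2L]]))
  }
  comps$q_poor <- as.numeric(plogis(ad_value(tape, lcomb)))
  list(tape = tape, total = total, pnodes = pn, comps = comps)
}

# cbind a node with a constant scalar column
ad_cbind_const <- function(tape, a, k) {
  force(a)
  A <- tape$nodes[[a]]$value
  ad_push(tape, cbind(A, k), a, function(g) list(g[, seq_len(ncol(A)), drop = FALSE]))
}

# batch constants for a set of cohort rows (cohort must be standardized)
make_batch <- function(cohort, rows, n_clinical) {
  C <- cohort$clinical[rows, , drop = FALSE]
  if (ncol(C)) C[!cohort$clinical_present[rows], ] <- NA_real_
  C2 <- clinical_design(C, n_clinical)
  mc <- if (ncol(C)) as.numeric(rowSums(!is.na(C)) > 0L) else rep(0, length(rows))
  lab <- cohort$label[rows]
  is_lab <- as.numeric(lab %in% c("good", "poor"))
  ylab <- ifelse(lab == "poor", 1, 0); ylab[is_lab == 0] <- 0
  X <- cohort$expression[rows, , drop = FALSE]
  dimnames(X) <- NULL; dimnames(C2) <- NULL
  list(X = X, C2 = C2, mc = mc, ylab = ylab, is_lab = is_lab)
}

new_loss_breakdown <- function(comps, alpha) {
  structure(list(labeled_term = comps$labeled_term,
                 unlabeled_term = comps$unlabeled_term,
                 classifier_term = comps$classifier_term,
                 entropy_term = comps$entropy_term,
                 l2_term = comps$l2_term,
                 kl_weights = comps$kl_weights,
                 alpha = alpha,
                 total = comps$total), class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(paste0("loss: total %.4f (labeled %.4f, unlabeled %.4f, ",
                     "classifier %.4f [alpha=%.3g], entropy %.4f, L2 %.4g, ",
                     "weight KL %.4f)\n"),
              x$total, x$labeled_term, x$unlabeled_term, x$classifier_term,
              x$alpha, x$entropy_term, x$l2_term, x$kl_weights))
  invisible(x)
}

record_loss <- function(model, x, clinical, y, alpha, lambda, seed, force_unlabeled = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(x, nrow = 1L)
  C <- matrix(if (is.null(clinical)) rep(NA_real_, model$n_clinical) else clinical,
              nrow = 1L)
  lab <- if (force_unlabeled) "undefined" else y
  batch <- list(X = X, C2 = clinical_design(C, model$n_clinical),
                mc = as.numeric(model$n_clinical > 0L && any(!is.na(C))),
                ylab = as.numeric(!force_unlabeled && y %in% c("poor", 1)),
                is_lab = as.numeric(!force_unlabeled))
  hp <- list(alpha = alpha, lambda = lambda, n_total = 1,
             prior_poor = model$prior_poor, variant = "full",
             weight_mode = "mean")
  lf <- loss_forward(model_params(model), batch, hp)
  lf
}

#' Per-patient loss for a labeled record (Types I and IV)
#'
#' The negative class-conditional ELBO `-E_q log p(x|y,z) + KL(q(z|x,y)||p(z))
#' - log p(y)` plus `alpha` times the cross-entropy of each available
#' subnetwork vote and of the combined vote, plus the variational-dropout
#' weight KL and L2 terms. Masked clinical cells contribute zero input (no
#' imputation); an absent clinical modality drops its vote and its
#' cross-entropy.
#'
#' @param model a `prognet_model`.
#' @param x standardized expression vector.
#' @param clinical standardized clinical vector with `NA` masks, or `NULL`.
#' @param y `"good"` or `"poor"` (or 0/1 with 1 = poor).
#' @param alpha classifier-term weight.
#' @param lambda L2 coefficient.
#' @param seed seed for the latent draw (weights are mean-propagated).
#' @return a `loss_breakdown`.
#' @export
labeled_loss <- function(model, x, clinical = NULL, y, alpha = 1, lambda = 0,
                         seed = NULL) {
  if (is.na(y) || identical(y, "undefined")) stop("labeled_loss needs a defined label")
  lf <- record_loss(model, x, clinical, y, alpha, lambda, seed)
  comps <- lf$comps
  ybin <- as.numeric(y %in% c("poor", 1))
  comps$labeled_term <- if (ybin == 1) comps$bound_poor else comps$bound_good
  comps$total <- comps$labeled_term + comps$classifier_term +
    comps$kl_weights + comps$l2_term
  new_loss_breakdown(comps, alpha)
}

#' Per-patient loss for an unlabeled record (Types II and III)
#'
#' Marginalizes the labeled bound over the classifier posterior:
#' `U(x) = sum_y q(y|.) * bound(x, y) - H(q(y|.))`, where `q(y|.)` is the
#' combined vote when the clinical modality is present (Type II) and the
#' microarray posterior alone otherwise (Type III). No cross-entropy term.
#'
#' @inheritParams labeled_loss
#' @return a `loss_breakdown` (with `q_poor` attribute giving the posterior
#'   used for the marginalization).
#' @export
unlabeled_loss <- function(model, x, clinical = NULL, lambda = 0, seed = NULL) {
  lf <- record_loss(model, x, clinical, y = NA, alpha = 0, lambda = lambda,
                    seed = seed, force_unlabeled = TRUE)
  comps <- lf$comps
  comps$classifier_term <- 0
  comps$total <- comps$unlabeled_term + comps$kl_weights + comps$l2_term
  out <- new_loss_breakdown(comps, 0)
  attr(out, "q_poor") <- comps$q_poor
  attr(out, "bounds") <- c(good = comps$bound_good, poor = comps$bound_poor)
  out
}

# Adam with bias correction and a global gradient-norm clip
adam_step <- function(params, grads, state, lr, clip = 50) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  sc <- if (is.finite(gn) && gn > clip) clip / gn else 1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]] * sc
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train a prognosis network on a split cohort
#'
#' Minibatch Adam on the type-dispatched semi-supervised objective over the
#' joint training set (labeled `train` split plus the whole unlabeled pool).
#' Labeled records contribute the class-conditional VAE bound and the
#' supervised cross-entropies; unlabeled records the label-marginalized
#' bound with its entropy bonus. Standardization statistics are fit on the
#' joint training set and stored in the model for inference. Early stopping
#' monitors validation AUROC. Fully reproducible under `config$seed`.
#'
#' @param cohort a `prog_cohort` with splits assigned (raw, unstandardized).
#' @param config a [train_config()].
#' @param model optionally a pre-built [prognet()] to continue training.
#' @return a `prognet_fit`: list with `model` (trained, carries
#'   standardization stats) and `history` (one row per epoch with every loss
#'   component and validation AUROC).
#' @export
train_prognet <- function(cohort, config = train_config(), model = NULL) {
  train_rows <- which(cohort$split %in% "train")
  lab_train <- train_rows[cohort$label[train_rows] %in% c("good", "poor")]
  if (!length(lab_train)) stop("labeled training split is empty")
  set.seed(config$seed)

  std <- standardize(cohort, fit_on = "train", include_unlabeled = TRUE)
  sc <- std$cohort
  prior_poor <- mean(cohort$label[lab_train] == "poor")
  prior_poor <- min(max(prior_poor, 1e-3), 1 - 1e-3)
  if (is.null(model)) {
    model <- prognet(length(cohort$gene_names), length(cohort$clinical_names),
                     config, prior_poor)
  } else {
    model$prior_poor <- prior_poor
    model$config <- config
  }

  joint <- if (config$variant == "full") {
    c(train_rows, which(cohort$split %in% "unlabeled"))
  } else {
    train_rows
  }
  n_total <- length(joint)
  alpha <- if (is.null(config$alpha)) 0.1 * n_total / length(lab_train) else config$alpha
  hp <- list(alpha = alpha, lambda = config$lambda,
             kl_temper = config$kl_temper, n_total = n_total,
             prior_poor = prior_poor, variant = config$variant,
             weight_mode = "sample")

  val_rows <- which(cohort$split %in% "validation" &
                      cohort$label %in% c("good", "poor"))
  can_validate <- length(val_rows) > 0L &&
    length(unique(cohort$label[val_rows])) == 2L
  val_batch <- if (can_validate) make_batch(sc, val_rows, model$n_clinical)
  val_y <- if (can_validate) as.integer(cohort$label[val_rows] == "poor")

  params <- model_params(model)
  state <- list(t = 0L, m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  hist_rows <- vector("list", config$epochs)
  best <- list(auroc = -Inf, params = params, epoch = 0L)
  stale <- 0L

  for (epoch in seq_len(config$epochs)) {
    hp$unl_weight <- if (config$unlabeled_warmup > 0) {
      # supervised-only anchoring for the first half of the warmup, then a
      # linear ramp: the marginalized bound must not steer the classifiers
      # before the labeled data have set their polarity
      w <- config$unlabeled_warmup
      min(1, max(0, (epoch - floor(w / 2)) / (w - floor(w / 2))))
    } else 1
    order_rows <- sample(joint)
    nb <- ceiling(length(order_rows) / config$batch_size)
    acc <- NULL
    for (b in seq_len(nb)) {
      rows <- order_rows[seq.int((b - 1L) * config$batch_size + 1L,
                                 min(b * config$batch_size, length(order_rows)))]
      batch <- make_batch(sc, rows, model$n_clinical)
      lf <- loss_forward(params, batch, hp)
      wanted <- vapply(lf$pnodes, identity, 0L)
      grads <- ad_backward(lf$tape, lf$total, wanted)
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
      keep <- c("labeled_term", "unlabeled_term", "classifier_term",
                "entropy_term", "l2_term", "kl_weights", "total")
      cv <- unlist(lf$comps[keep])
      acc <- if (is.null(acc)) cv else acc + cv
    }
    acc <- acc / nb
    val_auroc <- NA_real_
    if (can_validate && (epoch %% config$eval_every == 0L || epoch == config$epochs)) {
      mtmp <- set_model_params(model, params)
      scores <- val_scores(mtmp, val_batch)
      val_auroc <- auroc(scores, val_y)
      if (val_auroc > best$auroc + 1e-9) {
        best <- list(auroc = val_auroc, params = params, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + config$eval_every
      }
    }
    hist_rows[[epoch]] <- c(epoch = epoch, acc, val_auroc = val_auroc)
    if (can_validate && is.finite(config$patience) && stale >= config$patience) break
  }
  if (can_validate && best$auroc > -Inf) params <- best$params

  model <- set_model_params(model, params)
  model$stats <- std$stats
  model$alpha_used <- alpha
  history <- as.data.frame(do.call(rbind, hist_rows[!vapply(hist_rows, is.null, TRUE)]))
  structure(list(model = model, history = history,
                 best_epoch = if (can_validate) best$epoch else nrow(history)),
            class = "prognet_fit")
}

# combined-vote scores from a prepared batch (mean-propagation mode)
val_scores <- function(model, batch) {
  lx <- microarray_logit(model, batch$X)
  lc <- clinical_logit_from_design(model, batch$C2)
  w <- model$w_shared
  plogis((w[1L] * lx + batch$mc * w[2L] * lc) / (1 + batch$mc))
}

clinical_logit_from_design <- function(model, C2) {
  h <- tanh(bl_forward_mean(model$clf_c1, C2))
  as.numeric(bl_forward_mean(model$clf_c2, h))
}

#' @export
print.prognet_fit <- function(x, ...) {
  cat(sprintf("prognet_fit: %d epochs trained (best at %d)\n",
              nrow(x$history), x$best_epoch))
  print(x$model)
  invisible(x)
}

#' Four-fold cross-validation for hyper-parameter selection
#'
#' Stratified k-fold CV over the labeled patients of the joint training set;
#' the unlabeled pool joins every fold's training portion. Selects the
#' configuration maximizing mean held-out AUROC; ties are broken by smaller
#' model (parameter count), then lower `alpha`.
#'
#' @param cohort a split `prog_cohort`.
#' @param grid list of [train_config()] objects.
#' @param k number of folds (default 4).
#' @param seed fold-assignment seed.
#' @return list with `best_config`, `results` (per-config mean/sd AUROC) and
#'   `folds`.
#' @export
cross_validate <- function(cohort, grid, k = 4, seed = 1) {
  if (!length(grid)) stop("empty configuration grid")
  labeled <- which(cohort$split %in% c("train", "validation") &
                     cohort$label %in% c("good", "poor"))
  counts <- table(cohort$label[labeled])
  if (k > min(counts)) stop("k exceeds the labeled minority-class count")
  set.seed(seed)
  fold <- integer(length(cohort$ids))
  for (lab in c("good", "poor")) {
    idx <- sample(labeled[cohort$label[labeled] == lab])
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  score <- function(cfg) {
    aucs <- vapply(seq_len(k), function(f) {
      cv_cohort <- cohort
      cv_cohort$split[labeled] <- ifelse(fold[labeled] == f, "validation", "train")
      fit <- train_prognet(cv_cohort, cfg)
      val <- which(cv_cohort$split %in% "validation")
      pred <- predict(fit$model, cv_cohort, rows = val)
      auroc(pred$y_tilde, as.integer(cv_cohort$label[val] == "poor"))
    }, 0)
    c(mean = mean(aucs), sd = stats::sd(aucs))
  }
  res <- t(vapply(grid, score, c(mean = 0, sd = 0)))
  size <- vapply(grid, function(cfg) {
    n_model_params(prognet(length(cohort$gene_names),
                           length(cohort$clinical_names), cfg))
  }, 0)
  alphas <- vapply(grid, function(cfg) if (is.null(cfg$alpha)) Inf else cfg$alpha, 0)
  ord <- order(-res[, "mean"], size, alphas)
  list(best_config = grid[[ord[1L]]],
       results = data.frame(config = seq_along(grid), mean_auroc = res[, "mean"],
                            sd_auroc = res[, "sd"], n_params = size),
       folds = fold)
}

#' Train a seed ensemble
#'
#' Trains `n_members` models with identical hyper-parameters differing only
#' by seed (`base_seed + i`); the ensemble predicts with the sigmoid of the
#' mean of the member final-vote logits.
#'
#' @param cohort a split `prog_cohort`.
#' @param config a [train_config()].
#' @param n_members ensemble size.
#' @param base_seed base seed.
#' @return a `prognet_ensemble`.
#' @export
train_ensemble <- function(cohort, config = train_config(), n_members = 20,
                           base_seed = 1) {
  stopifnot(n_members >= 1)
  members <- lapply(seq_len(n_members), function(i) {
    cfg <- config
    cfg$seed <- base_seed + i
    train_prognet(cohort, cfg)$model
  })
  structure(list(members = members, config = config, base_seed = base_seed),
            class = "prognet_ensemble")
}

#' @export
print.prognet_ensemble <- function(x, ...) {
  cat(sprintf("prognet_ensemble: %d members (base seed %d)\n",
              length(x$members), x$base_seed))
  invisible(x)
}
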