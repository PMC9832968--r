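# Synthetic multimodal cohort generator with known ground truth.
#
# A latent binary risk class drives (i) a subset of informative genes (mean
# shift between classes), (ii) clinical features (linear for continuous,
# logistic for binary), and (iii) exponential survival times whose class
# medians straddle the 5-year horizon. Independent uniform administrative
# censoring produces undefined labels exactly as in real registries. The
# ground truth (latent classes, informative-gene flags, coefficients) is
# returned alongside but never shown to models.

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the structure of the microarray prognosis cohorts this
#' package targets: a small prognostic gene panel (20 genes, a sparse
#' informative subset of 2), ~10 mixed clinical features moderately coupled
#' to the risk class, a mildly imbalanced 5-year label, class-conditional
#' exponential survival (poor median 32 months, good median 110 — the heavy
#' overlap of exponential lifetimes makes the derived binary label an
#' intentionally noisy readout of the risk class, as in real registries) and
#' an unlabeled pool dominated by patients with clinical data but no label
#' (Type II), with a minority carrying expression only (Type III).
#'
#' @param n_labeled number of labeled patients.
#' @param n_unlabeled size of the unlabeled pool.
#' @param n_genes gene panel size.
#' @param n_clinical number of clinical features.
#' @param n_binary_clinical how many clinical features are binary.
#' @param poor_fraction latent poor-class probability.
#' @param effect_size mean shift (in noise-sd units) between classes for each
#'   informative gene.
#' @param noise_sd expression noise standard deviation.
#' @param informative_gene_fraction fraction of genes carrying signal.
#' @param clinical_effect latent-class coefficient for clinical features.
#' @param type_proportions named fractions for Types II/III over the
#'   unlabeled pool, plus the Type-IV share of the labeled set.
#' @param poor_median_months,good_median_months class-conditional exponential
#'   survival medians (calibrated to straddle the 60-month horizon).
#' @param censoring_rate approximate fraction of patients censored.
#' @param seed integer seed; generation is fully reproducible.
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(n_labeled = 500, n_unlabeled = 1250,
                             n_genes = 20, n_clinical = 10,
                             n_binary_clinical = 6,
                             poor_fraction = 0.4, effect_size = 1.5,
                             noise_sd = 1, informative_gene_fraction = 0.1,
                             clinical_effect = 0.8,
                             type_proportions = c(II = 0.9, III = 0.1, IV = 0),
                             poor_median_months = 32,
                             good_median_months = 110,
                             censoring_rate = 0.25, seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_genes < 1) stop("`n_genes` must be >= 1")
  fr <- c(poor_fraction, informative_gene_fraction, censoring_rate,
          type_proportions)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (censoring_rate >= 1) stop("`censoring_rate` must be < 1")
  if (sum(type_proportions[c("II", "III")]) > 1 + 1e-9) {
    stop("Type II + III proportions exceed the unlabeled pool")
  }
  if (poor_median_months >= 60 || good_median_months <= 60) {
    stop("class medians must straddle the 60-month horizon")
  }
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  structure(cfg, class = "synthetic_config")
}

# administrative censoring horizon C solved so that P(censored) ~ rate for a
# two-component exponential mixture; returns Inf when rate = 0
solve_censoring_horizon <- function(rate, rates, weights) {
  if (rate <= 0) return(Inf)
  # P(censored) = P(U < T) with U ~ Unif(0, C): (1 - exp(-lambda C)) / (lambda C)
  p_cens <- function(C) {
    sum(weights * (1 - exp(-rates * C)) / (rates * C)) - rate
  }
  # P(censored | C) decreases from 1 (C -> 0) to 0 (C -> Inf)
  stats::uniroot(p_cens, lower = 1e-3, upper = 1e5, tol = 1e-8)$root
}

#' Generate a synthetic multimodal cohort with ground truth
#'
#' See [synthetic_config()] for the generative model. Labeled patients are
#' guaranteed a defined 5-year label (their censoring times are redrawn past
#' the horizon when needed); the unlabeled pool receives Type II/III/IV
#' missingness via [inject_missingness()].
#'
#' @param config a [synthetic_config()].
#' @return list with `cohort` (a `prog_cohort`) and `truth` (latent classes,
#'   informative-gene flags and class-conditional means, clinical
#'   coefficients, survival rates, empirical censoring rate).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  set.seed(config$seed)
  n <- config$n_labeled + config$n_unlabeled
  G <- config$n_genes
  D <- config$n_clinical

  z <- stats::rbinom(n, 1L, config$poor_fraction) # 1 = poor latent class
  n_inf <- max(1L, round(config$informative_gene_fraction * G))
  informative <- seq_len(G) <= n_inf
  shift <- ifelse(informative, config$effect_size * config$noise_sd / 2, 0)
  mu0 <- -shift; mu1 <- shift # class-conditional gene means
  expression <- matrix(stats::rnorm(n * G, sd = config$noise_sd), n, G)
  expression <- expression + outer(z, mu1) + outer(1 - z, mu0)
  gene_names <- sprintf("gene_%02d", seq_len(G))
  colnames(expression) <- gene_names

  clin_names <- character(0)
  clinical <- matrix(numeric(0), n, 0L)
  beta <- numeric(0)
  if (D > 0L) {
    nb <- min(config$n_binary_clinical, D)
    is_bin <- seq_len(D) <= nb
    beta <- config$clinical_effect * stats::rnorm(D, 1, 0.25) *
      sample(c(-1, 1), D, replace = TRUE)
    clinical <- matrix(0, n, D)
    for (j in seq_len(D)) {
      eta <- beta[j] * (z - config$poor_fraction)
      clinical[, j] <- if (is_bin[j]) {
        stats::rbinom(n, 1L, stats::plogis(eta))
      } else {
        eta + stats::rnorm(n)
      }
    }
    clin_names <- sprintf("clin_%02d", seq_len(D))
    colnames(clinical) <- clin_names
  } else {
    is_bin <- logical(0)
  }

  rate_poor <- log(2) / config$poor_median_months
  rate_good <- log(2) / config$good_median_months
  rates <- ifelse(z == 1L, rate_poor, rate_good)
  event_time <- stats::rexp(n, rates)
  Cmax <- solve_censoring_horizon(config$censoring_rate, c(rate_poor, rate_good),
                                  c(config$poor_fraction, 1 - config$poor_fraction))
  cens_time <- if (is.finite(Cmax)) stats::runif(n, 0, Cmax) else rep(Inf, n)
  time <- pmin(event_time, cens_time)
  event <- as.numeric(event_time <= cens_time)

  # labeled patients must have a defined label: redraw censoring past the
  # horizon when it would censor them early (keeps the event time intact)
  labeled_idx <- seq_len(config$n_labeled)
  spec <- label_spec()
  lab <- assign_label(list(time_months = time, event = event), spec)
  redo <- intersect(labeled_idx, which(lab == "undefined"))
  if (length(redo) && is.finite(Cmax)) {
    new_cens <- stats::runif(length(redo), 60, max(Cmax, 61))
    time[redo] <- pmin(event_time[redo], new_cens)
    event[redo] <- as.numeric(event_time[redo] <= new_cens)
  }
  surv <- data.frame(time_months = time, event = event)
  label <- assign_label(surv, spec)

  ids <- sprintf("P%05d", seq_len(n))
  rownames(expression) <- ids
  cohort <- new_cohort(ids, expression, clinical, rep(D > 0L, n), surv, label,
                       gene_names, clin_names)
  truth <- list(
    latent_class = z,
    informative = informative,
    gene_means = rbind(good = mu0, poor = mu1),
    clinical_coef = beta,
    clinical_binary = is_bin,
    rates = c(good = rate_good, poor = rate_poor),
    poor_fraction = config$poor_fraction,
    noise_sd = config$noise_sd,
    censoring_horizon = Cmax,
    empirical_censoring_rate = mean(event == 0),
    unlabeled_idx = setdiff(seq_len(n), labeled_idx)
  )
  cohort <- inject_missingness(cohort, config, unlabeled_idx = truth$unlabeled_idx)
  list(cohort = cohort, truth = truth)
}

#' Impose Type II/III/IV missingness on a generated cohort
#'
#' Marks the requested fractions of the unlabeled pool as Type II (label
#' removed, clinical kept) or Type III (label removed, clinical vector
#' dropped), and masks one random clinical cell for a Type-IV share of the
#' labeled patients. Missingness is completely at random (MCAR), independent
#' of outcome. Counts match the request within one patient (largest
#' remainder rounding).
#'
#' @param cohort a `prog_cohort` (fully observed).
#' @param config a [synthetic_config()] whose `type_proportions` are used.
#' @param unlabeled_idx indices of the designated unlabeled pool (defaults to
#'   patients whose label is already undefined plus the tail of the cohort
#'   beyond `config$n_labeled`).
#' @return the modified cohort with labels/ptypes/splits updated.
#' @export
inject_missingness <- function(cohort, config, unlabeled_idx = NULL) {
  p <- config$type_proportions
  p <- c(II = unname(p["II"]), III = unname(p["III"]), IV = unname(p["IV"]))
  p[is.na(p)] <- 0
  if (sum(p[c("II", "III")]) > 1 + 1e-9) stop("Type II + III proportions exceed 1")
  n <- length(cohort$ids)
  if (is.null(unlabeled_idx)) {
    unlabeled_idx <- if (n > config$n_labeled) seq.int(config$n_labeled + 1L, n)
                     else integer(0)
  }
  nu <- length(unlabeled_idx)
  s23 <- sum(p[c("II", "III")])
  if (nu > 0L && s23 > 0) {
    counts <- allocate_counts(nu, c(p[["II"]], p[["III"]]) / s23)
    idx3 <- unlabeled_idx[seq_len(counts[2L])] # patients are iid, so pool order is MCAR
    cohort$label[unlabeled_idx] <- "undefined"
    cohort$survival$time_months[unlabeled_idx] <- NA_real_
    cohort$survival$event[unlabeled_idx] <- NA_real_
    if (length(idx3)) {
      cohort$clinical_present[idx3] <- FALSE
      if (ncol(cohort$clinical)) cohort$clinical[idx3, ] <- NA_real_
    }
  }
  if (p["IV"] > 0 && ncol(cohort$clinical)) {
    labeled_idx <- setdiff(seq_len(n), unlabeled_idx)
    n4 <- round(p["IV"] * length(labeled_idx))
    if (n4 > 0L) {
      idx4 <- labeled_idx[seq_len(n4)]
      cols <- sample(ncol(cohort$clinical), n4, replace = TRUE)
      cohort$clinical[cbind(idx4, cols)] <- NA_real_
    }
  }
  n_clin <- length(cohort$clinical_names)
  n_masked <- if (n_clin) rowSums(is.na(cohort$clinical)) else rep(0L, n)
  cohort$ptype <- ptype_vector(cohort$clinical_present, n_masked, n_clin, cohort$label)
  unl <- !(cohort$label %in% c("good", "poor"))
  cohort$split[unl] <- "unlabeled"
  cohort$split[!unl & cohort$split %in% "unlabeled"] <- NA_character_
  cohort
}

#' AUROC of the Bayes-optimal classifier on a synthetic cohort
#'
#' Scores every patient with the true posterior probability of the poor
#' latent class given all observed features (class-conditional Gaussians for
#' the genes and continuous clinical features, class-conditional logistic
#' Bernoullis for the binary ones; masked clinical cells are skipped) and
#' computes the AUROC against the derived 5-year labels on the requested
#' split. Serves as a performance ceiling for trained models: the survival
#' label depends on the features only through the latent class, so no
#' classifier can beat this score except by sampling noise.
#'
#' @param truth ground truth from [generate_cohort()].
#' @param cohort the matching cohort (unstandardized).
#' @param split which split to score (default `"test"`; use `NULL` for all
#'   labeled patients).
#' @return the AUROC as a single number.
#' @export
oracle_bayes_auroc <- function(truth, cohort, split = "test") {
  idx <- which(cohort$label %in% c("good", "poor"))
  if (!is.null(split)) idx <- idx[cohort$split[idx] %in% split]
  if (!length(idx)) stop("no labeled patients in the requested split")
  scores <- oracle_posterior(truth, cohort$expression[idx, , drop = FALSE],
                             cohort$clinical[idx, , drop = FALSE])
  auroc(scores, as.integer(cohort$label[idx] == "poor"))
}

# posterior P(poor | x, c) under the generative model; clinical optional
oracle_posterior <- function(truth, x, clinical = NULL) {
  ll <- function(mu) {
    rowSums(gaussian_loglik(x, matrix(mu, nrow(x), ncol(x), byrow = TRUE),
                            2 * log(truth$noise_sd)))
  }
  l1 <- ll(truth$gene_means["poor", ]) + log(truth$poor_fraction)
  l0 <- ll(truth$gene_means["good", ]) + log(1 - truth$poor_fraction)
  if (!is.null(clinical) && length(truth$clinical_coef)) {
    pf <- truth$poor_fraction
    for (j in seq_along(truth$clinical_coef)) {
      cj <- clinical[, j]
      obs <- !is.na(cj)
      eta1 <- truth$clinical_coef[j] * (1 - pf)
      eta0 <- truth$clinical_coef[j] * (0 - pf)
      if (truth$clinical_binary[j]) {
        l1[obs] <- l1[obs] + stats::dbinom(cj[obs], 1, stats::plogis(eta1), log = TRUE)
        l0[obs] <- l0[obs] + stats::dbinom(cj[obs], 1, stats::plogis(eta0), log = TRUE)
      } else {
        l1[obs] <- l1[obs] + stats::dnorm(cj[obs], eta1, 1, log = TRUE)
        l0[obs] <- l0[obs] + stats::dnorm(cj[obs], eta0, 1, log = TRUE)
      }
    }
  }
  1 / (1 + exp(l0 - l1))
}
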