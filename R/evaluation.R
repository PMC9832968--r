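# Evaluation machinery: threshold-free ranking metrics with the exact tie
# semantics used throughout (ties credited one half), bootstrap confidence
# intervals, mean ROC/PRC curves on a fixed grid, and Kaplan-Meier /
# log-rank stratification.

check_binary <- function(labels) {
  u <- unique(labels)
  if (!all(u %in% c(0, 1))) stop("labels must be 0/1")
  if (length(u) < 2L) stop("metric undefined: only one class present")
}

#' Area under the ROC curve
#'
#' Equals the pairwise probability `P(score_pos > score_neg) + 0.5 P(tie)`
#' (the Mann-Whitney statistic), so it is invariant under strictly
#' increasing transforms of the scores.
#'
#' @param scores numeric risk scores (higher = more likely positive).
#' @param labels 0/1 vector, 1 = positive (poor prognosis).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  check_binary(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated area: precision is evaluated at each achievable recall
#' level walking down the score ranking (ties processed as one block), and
#' the area adds `precision * delta-recall` per step.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  check_binary(labels)
  pr <- pr_points(scores, labels)
  sum(pr$precision * diff(c(0, pr$recall)))
}

# precision/recall at every distinct score cut, highest scores first
pr_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  cum_tp <- cumsum(y)
  cum_fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE) # block ends of tied scores
  tp <- cum_tp[last]; fp <- cum_fp[last]
  P <- sum(labels == 1)
  list(recall = tp / P, precision = tp / (tp + fp))
}

#' Accuracy and macro-averaged F1 of thresholded predictions
#'
#' `macro_f1` is the unweighted mean of the per-class F1 scores (a class
#' never predicted and never present scores 0).
#'
#' @param pred_labels 0/1 predictions (e.g. `y_tilde >= 0.5`).
#' @param labels 0/1 truth.
#' @return a single number in `[0, 1]`.
#' @export
macro_f1 <- function(pred_labels, labels) {
  f1_for <- function(cls) {
    tp <- sum(pred_labels == cls & labels == cls)
    fp <- sum(pred_labels == cls & labels != cls)
    fn <- sum(pred_labels != cls & labels == cls)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  mean(c(f1_for(0), f1_for(1)))
}

#' @rdname macro_f1
#' @export
acc <- function(pred_labels, labels) mean(pred_labels == labels)

#' Harrell's concordance index for censored survival
#'
#' Over all comparable pairs (the patient with the shorter time experienced
#' the event), the fraction in which that patient carries the higher risk
#' score; risk ties credit one half. Pairs with equal times where both had
#' events are comparable in neither direction and are skipped.
#'
#' @param risk_scores numeric risk scores (higher = shorter expected
#'   survival).
#' @param times survival times.
#' @param events 1 = event observed, 0 = censored.
#' @return concordance in `[0, 1]`.
#' @export
concordance_index <- function(risk_scores, times, events) {
  n <- length(times)
  if (n < 2L) stop("need at least two patients")
  conc <- 0; comp <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      # the comparable member is the one with the shorter time and an event
      if (times[i] == times[j]) next
      short <- if (times[i] < times[j]) i else j
      long <- if (short == i) j else i
      if (events[short] != 1) next
      comp <- comp + 1
      if (risk_scores[short] > risk_scores[long]) conc <- conc + 1
      else if (risk_scores[short] == risk_scores[long]) conc <- conc + 0.5
    }
  }
  if (comp == 0) stop("metric undefined: no comparable pairs")
  conc / comp
}

#' Point metrics with percentile-bootstrap confidence intervals
#'
#' Resamples the test set with replacement `n` times and reports the
#' 2.5/97.5 percentile interval for each metric. Replicates where only one
#' class survives the resampling are skipped and counted. The concordance
#' index is included when survival data are supplied.
#'
#' @param scores predicted probabilities of the positive (poor) class.
#' @param labels 0/1 truth.
#' @param times,events optional censored survival data for the concordance
#'   index.
#' @param n bootstrap replicates (default 1000).
#' @param seed resampling seed.
#' @param threshold classification threshold for ACC / macro F1.
#' @return a `metric_report`: data.frame with point estimate and CI bounds
#'   per metric, plus `n_bootstrap` and `n_skipped` attributes.
#' @export
bootstrap_report <- function(scores, labels, times = NULL, events = NULL,
                             n = 1000, seed = 1, threshold = 0.5) {
  if (!length(scores)) stop("empty test set")
  has_surv <- !is.null(times) && !is.null(events)
  one <- function(s, y, tt, ev) {
    pl <- as.integer(s >= threshold)
    out <- c(auroc = auroc(s, y), auprc = auprc(s, y),
             macro_f1 = macro_f1(pl, y), acc = acc(pl, y))
    if (has_surv) out <- c(out, concordance_index = concordance_index(s, tt, ev))
    out
  }
  point <- one(scores, labels, times, events)
  set.seed(seed)
  reps <- matrix(NA_real_, n, length(point))
  skipped <- 0L
  for (b in seq_len(n)) {
    idx <- sample(length(scores), replace = TRUE)
    if (length(unique(labels[idx])) < 2L) { skipped <- skipped + 1L; next }
    reps[b, ] <- one(scores[idx], labels[idx], times[idx], events[idx])
  }
  ok <- stats::complete.cases(reps)
  ci <- apply(reps[ok, , drop = FALSE], 2L, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  report <- data.frame(metric = names(point), estimate = unname(point),
                       ci_lo = ci[1L, ], ci_hi = ci[2L, ],
                       stringsAsFactors = FALSE)
  structure(report, class = c("metric_report", "data.frame"),
            n_bootstrap = n, n_skipped = skipped, threshold = threshold)
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Metrics with 95%% percentile-bootstrap CIs (%d replicates, %d skipped):\n",
              attr(x, "n_bootstrap"), attr(x, "n_skipped")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-18s %6.2f%% [%6.2f, %6.2f]\n", x$metric[i],
                100 * x$estimate[i], 100 * x$ci_lo[i], 100 * x$ci_hi[i]))
  }
  invisible(x)
}

# ROC as TPR at given FPR grid (step interpolation, no linear smoothing)
roc_at <- function(scores, labels, fpr_grid) {
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(y)); fpr <- c(0, fp[last] / sum(1 - y))
  vapply(fpr_grid, function(g) max(tpr[fpr <= g]), 0)
}

# precision at fixed recall via the rightmost (best-achievable) envelope
prc_at <- function(scores, labels, recall_grid) {
  pr <- pr_points(scores, labels)
  rec <- pr$recall; prec <- pr$precision
  # best precision among cuts achieving at least the requested recall
  env <- rev(cummax(rev(prec)))
  vapply(recall_grid, function(g) {
    if (g <= 0) 1 else env[match(TRUE, rec >= g)]
  }, 0)
}

#' Mean bootstrap ROC / precision-recall curve on a fixed grid
#'
#' Each bootstrap replicate's curve is interpolated onto 100 equally spaced
#' grid points in `[0, 1]` (ROC: TPR at fixed FPR; PRC: precision at fixed
#' recall), and the pointwise mean and sd over replicates are reported.
#'
#' @inheritParams bootstrap_report
#' @param kind `"roc"` or `"prc"`.
#' @param n_boot bootstrap replicates.
#' @return a `curve_bundle`: list with `grid` (length 100), `mean`, `sd`,
#'   `kind`, `n_boot`.
#' @export
mean_curve <- function(scores, labels, kind = c("roc", "prc"), n_boot = 1000,
                       seed = 1) {
  kind <- match.arg(kind)
  check_binary(labels)
  grid <- seq(0, 1, length.out = 100)
  fun <- if (kind == "roc") roc_at else prc_at
  set.seed(seed)
  mats <- matrix(NA_real_, n_boot, length(grid))
  for (b in seq_len(n_boot)) {
    idx <- if (n_boot == 1L) seq_along(scores) else sample(length(scores), replace = TRUE)
    if (length(unique(labels[idx])) < 2L) next
    mats[b, ] <- fun(scores[idx], labels[idx], grid)
  }
  ok <- stats::complete.cases(mats)
  structure(list(grid = grid, mean = colMeans(mats[ok, , drop = FALSE]),
                 sd = apply(mats[ok, , drop = FALSE], 2L, stats::sd),
                 kind = kind, n_boot = sum(ok)),
            class = "curve_bundle")
}

#' Kaplan-Meier curves and two-sample log-rank test for predicted groups
#'
#' Product-limit survival estimates per group (via the survival package),
#' the two-sample log-rank chi-square with one degree of freedom, and the
#' per-group median survival (NA when the curve never reaches 0.5).
#'
#' @param times,events censored survival data.
#' @param groups two-level factor or character vector (e.g. predicted
#'   good/poor).
#' @return a `stratification_report`: list with `km` (per-group step-curve
#'   data.frame), `chisq`, `p_value`, `medians`.
#' @export
km_logrank <- function(times, events, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L) stop("need exactly two groups")
  if (any(table(groups) == 0L)) stop("empty group")
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  sm <- summary(fit)
  km <- data.frame(group = sub("^groups=", "", as.character(sm$strata)),
                   time = sm$time, survival = sm$surv,
                   n_risk = sm$n.risk, n_event = sm$n.event)
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  chisq <- sd_$chisq
  p <- stats::pchisq(chisq, df = 1L, lower.tail = FALSE)
  med <- summary(fit)$table
  medians <- stats::setNames(med[, "median"], sub("^groups=", "", rownames(med)))
  structure(list(km = km, chisq = chisq, p_value = p, medians = medians,
                 n = as.integer(table(groups))),
            class = "stratification_report")
}

#' @export
print.stratification_report <- function(x, ...) {
  cat(sprintf("log-rank chi-square %.3f (1 df), p = %.3g\n", x$chisq, x$p_value))
  for (g in names(x$medians)) {
    cat(sprintf("  %s: median survival %s months\n", g,
                ifelse(is.na(x$medians[g]), "not reached",
                       format(x$medians[g]))))
  }
  invisible(x)
}
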