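# Inference: per-modality votes and the combined final prediction, for
# single models and logit-averaged seed ensembles.

# standardize a raw cohort with the stats stored in a trained model
apply_model_stats <- function(model, cohort) {
  if (is.null(model$stats)) stop("model carries no standardization stats; train it first")
  standardize(cohort, stats = model$stats)$cohort
}

bundle_from_logits <- function(ids, lx, lc, mc, w, prior_poor, threshold = 0.5) {
  y1 <- plogis(lx)
  y2 <- ifelse(mc > 0, plogis(lc), NA_real_)
  lcomb <- (w[1L] * lx + mc * w[2L] * lc) / (1 + mc)
  yt <- plogis(lcomb)
  data.frame(id = ids, y1_hat = y1, y2_hat = y2, y_tilde = yt,
             logit_tilde = lcomb,
             predicted_class = ifelse(yt >= threshold, "poor", "good"),
             stringsAsFactors = FALSE)
}

# per-patient logits for a standardized cohort subset
cohort_logits <- function(model, sc, rows) {
  batch <- make_batch(sc, rows, model$n_clinical)
  list(lx = microarray_logit(model, batch$X),
       lc = clinical_logit_from_design(model, batch$C2),
       mc = batch$mc)
}

#' Predict prognosis for the patients of a cohort
#'
#' Deterministic mean-propagation inference. Every patient gets the
#' microarray vote `y1_hat`; patients with at least one observed clinical
#' value also get the clinical vote `y2_hat`; the final probability
#' `y_tilde` combines the available weighted votes with equal importance
#' (see [combine_votes()]), so predictions are produced for microarray-only,
#' clinical-only and bimodal records alike.
#'
#' @param object a trained `prognet_model`.
#' @param cohort a raw `prog_cohort`; the model's stored standardization
#'   stats are applied.
#' @param rows optional row indices (default: all patients).
#' @param threshold classification threshold on `y_tilde` (default 0.5).
#' @param ... unused.
#' @return data.frame: `id`, `y1_hat`, `y2_hat`, `y_tilde`, `logit_tilde`,
#'   `predicted_class`.
#' @export
predict.prognet_model <- function(object, cohort, rows = NULL, threshold = 0.5, ...) {
  sc <- apply_model_stats(object, cohort)
  if (is.null(rows)) rows <- seq_along(cohort$ids)
  lg <- cohort_logits(object, sc, rows)
  bundle_from_logits(cohort$ids[rows], lg$lx, lg$lc, lg$mc, object$w_shared,
                     object$prior_poor, threshold)
}

#' @rdname predict.prognet_model
#' @export
predict.prognet_fit <- function(object, cohort, rows = NULL, threshold = 0.5, ...) {
  predict(object$model, cohort, rows = rows, threshold = threshold)
}

#' Ensemble prediction by logit averaging
#'
#' The final vote is the sigmoid of the mean of the member final logits;
#' per-modality votes are averaged the same way.
#'
#' @inheritParams predict.prognet_model
#' @export
predict.prognet_ensemble <- function(object, cohort, rows = NULL, threshold = 0.5, ...) {
  if (is.null(rows)) rows <- seq_along(cohort$ids)
  per <- lapply(object$members, function(m) {
    sc <- apply_model_stats(m, cohort)
    lg <- cohort_logits(m, sc, rows)
    w <- m$w_shared
    cbind(lx = lg$lx, lc = lg$lc, mc = lg$mc,
          lcomb = (w[1L] * lg$lx + lg$mc * w[2L] * lg$lc) / (1 + lg$mc))
  })
  lx <- rowMeans(sapply(per, function(p) p[, "lx"]))
  lc <- rowMeans(sapply(per, function(p) p[, "lc"]))
  mc <- per[[1L]][, "mc"]
  lcomb <- rowMeans(sapply(per, function(p) p[, "lcomb"]))
  yt <- plogis(lcomb)
  data.frame(id = cohort$ids[rows], y1_hat = plogis(lx),
             y2_hat = ifelse(mc > 0, plogis(lc), NA_real_),
             y_tilde = yt, logit_tilde = lcomb,
             predicted_class = ifelse(yt >= threshold, "poor", "good"),
             stringsAsFactors = FALSE)
}

#' Prediction bundle for a single patient record
#'
#' Works with any non-empty subset of modalities: microarray only (Type
#' III), clinical only, or both; the final vote combines whatever weighted
#' votes are available.
#'
#' @param model a trained `prognet_model`.
#' @param record a patient record from [get_record()] (raw scale); either
#'   modality may be `NULL`.
#' @return list with `y1_hat`, `y2_hat` (NA when the corresponding modality
#'   is absent), `y_tilde`, the shared weights and modality availability
#'   flags.
#' @export
predict_record <- function(model, record) {
  has_x <- !is.null(record$expression) && length(record$expression) > 0L
  has_c <- !is.null(record$clinical) && model$n_clinical > 0L &&
    any(!is.na(record$clinical))
  if (!has_x && !has_c) stop("no modality available")
  y1 <- NA_real_
  if (has_x) {
    xs <- (record$expression - model$stats$gene$mean) / model$stats$gene$sd
    y1 <- classify_microarray(model, xs)
  }
  y2 <- NA_real_
  if (has_c) {
    cs <- (record$clinical - model$stats$clinical$mean) / model$stats$clinical$sd
    res <- classify_clinical(model, cs)
    y2 <- if (res$available[1L]) res$prob[1L] else NA_real_
    has_c <- res$available[1L]
  }
  bundle <- list(y1_hat = y1, y2_hat = y2,
                 w1 = model$w_shared[[1L]], w2 = model$w_shared[[2L]],
                 modality_availability = c(microarray = has_x, clinical = has_c))
  bundle$y_tilde <- combine_votes(bundle)
  bundle
}
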