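# Post-hoc interpretation: connection-weights importance (chained products
# of layer weight matrices, nonlinearities ignored, Bayesian layers
# collapsed to their posterior means) and partial-dependence profiles.

#' Connection-weights feature importance
#'
#' Signed importance of each input feature of a feed-forward subnetwork as
#' the sum over hidden paths of the products of the (mean) weights along the
#' path — `importance_i = sum_h w_ih v_h`, chained through stacked layers.
#' Computed per modality; the two modalities are reported separately since
#' the algorithm defines no cross-modality combination. For an ensemble the
#' member weight matrices are averaged first (the default attribution mode).
#'
#' @param model a trained `prognet_model` or `prognet_ensemble`.
#' @param modality `"microarray"` or `"clinical"`.
#' @return data.frame: `feature`, `modality`, `importance`, `rank` (by
#'   absolute importance). Clinical rows include the observed-flag channels
#'   (suffix `_observed`).
#' @export
connection_weights <- function(model, modality = c("microarray", "clinical")) {
  modality <- match.arg(modality)
  if (inherits(model, "prognet_ensemble")) {
    mats <- lapply(model$members, cw_matrices, modality = modality)
    ms <- lapply(names(mats[[1L]]), function(nm) {
      Reduce(`+`, lapply(mats, `[[`, nm)) / length(mats)
    })
    names(ms) <- names(mats[[1L]])
    feats <- cw_features(model$members[[1L]], modality)
  } else {
    ms <- cw_matrices(model, modality)
    feats <- cw_features(model, modality)
  }
  if (modality == "microarray" && !is.null(ms$Wt)) {
    # chain gene -> trunk -> classifier hidden -> output
    imp <- as.numeric(ms$Wt %*% (ms$W1 %*% ms$W2))
  } else {
    imp <- as.numeric(ms$W1 %*% ms$W2)
  }
  data.frame(feature = feats, modality = modality, importance = imp,
             rank = rank(-abs(imp), ties.method = "min"),
             stringsAsFactors = FALSE)
}

cw_matrices <- function(model, modality) {
  if (modality == "microarray") {
    list(W1 = model$clf_x1$weight_mean, W2 = model$clf_x2$weight_mean,
         Wt = if (identical(model$config$variant, "no_vae")) NULL
              else model$vae$enc1$weight_mean)
  } else {
    list(W1 = model$clf_c1$weight_mean, W2 = model$clf_c2$weight_mean)
  }
}

cw_features <- function(model, modality) {
  if (modality == "microarray") {
    nms <- names(model$stats$gene$mean)
    if (is.null(nms)) nms <- sprintf("gene_%02d", seq_len(model$n_genes))
    nms
  } else {
    if (model$n_clinical == 0L) return("(none)")
    nms <- names(model$stats$clinical$mean)
    if (is.null(nms)) nms <- sprintf("clin_%02d", seq_len(model$n_clinical))
    c(nms, paste0(nms, "_observed"))
  }
}

#' Partial-dependence profile of one input feature
#'
#' `PDP(g)` is the mean final prediction over the background cohort when the
#' chosen feature is forced to the grid value `g` for every patient (raw
#' scale; the model's standardization is applied internally).
#'
#' @param model a trained `prognet_model` or `prognet_ensemble`.
#' @param feature a gene or clinical feature name.
#' @param cohort background `prog_cohort` (raw scale).
#' @param grid grid of raw feature values; default 20 points between the 5th
#'   and 95th percentile of the observed values.
#' @param rows optional background row subset.
#' @return data.frame `value`, `mean_prediction` of class `pdp_profile`.
#' @export
partial_dependence <- function(model, feature, cohort, grid = NULL, rows = NULL) {
  in_genes <- feature %in% cohort$gene_names
  in_clin <- feature %in% cohort$clinical_names
  if (!in_genes && !in_clin) stop("unknown feature: ", feature)
  if (is.null(rows)) rows <- seq_along(cohort$ids)
  obs <- if (in_genes) cohort$expression[rows, feature]
         else cohort$clinical[rows, feature]
  if (is.null(grid)) {
    qs <- stats::quantile(obs, c(0.05, 0.95), na.rm = TRUE)
    grid <- seq(qs[1L], qs[2L], length.out = 20L)
  }
  mean_pred <- vapply(grid, function(g) {
    cc <- cohort
    if (in_genes) cc$expression[rows, feature] <- g
    else cc$clinical[rows, feature] <- g
    mean(predict(model, cc, rows = rows)$y_tilde)
  }, 0)
  structure(data.frame(value = grid, mean_prediction = mean_pred),
            class = c("pdp_profile", "data.frame"), feature = feature)
}

#' Full attribution report for both modalities
#'
#' @param model trained `prognet_model` or `prognet_ensemble`.
#' @return data.frame combining [connection_weights()] for both modalities.
#' @export
attribution_report <- function(model) {
  rbind(connection_weights(model, "microarray"),
        connection_weights(model, "clinical"))
}
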