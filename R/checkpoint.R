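# Model checkpoints: a single versioned JSON document holding every weight
# posterior (means and log-variances), the shared vote weights, the class
# prior, the training configuration and the standardization statistics.

CHECKPOINT_FORMAT <- "prognet-checkpoint-1"

#' Save a trained model to a JSON checkpoint
#'
#' @param model a `prognet_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  params <- model_params(model)
  doc <- list(
    format = CHECKPOINT_FORMAT,
    package_version = as.character(utils::packageVersion("prognet")),
    n_genes = model$n_genes,
    n_clinical = model$n_clinical,
    prior_poor = model$prior_poor,
    config = unclass(model$config),
    stats = model$stats,
    shapes = lapply(params, dim),
    params = lapply(params, as.numeric)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model from a JSON checkpoint
#'
#' @param path checkpoint written by [save_checkpoint()].
#' @return a `prognet_model`.
#' @export
load_checkpoint <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, CHECKPOINT_FORMAT)) {
    stop("not a prognet checkpoint (format: ", doc$format, ")")
  }
  cfg <- doc$config
  cfg$alpha <- if (is.null(cfg$alpha)) NULL else cfg$alpha
  config <- do.call(train_config, cfg[names(cfg) %in% names(formals(train_config))])
  model <- prognet(doc$n_genes, doc$n_clinical, config, doc$prior_poor)
  params <- mapply(function(v, s) matrix(v, s[1L], s[2L]),
                   doc$params, doc$shapes, SIMPLIFY = FALSE)
  model <- set_model_params(model, params)
  if (!is.null(doc$stats) && length(doc$stats)) {
    st <- doc$stats
    st$gene <- lapply(st$gene, unlist)
    st$clinical <- lapply(st$clinical, unlist)
    st$clinical_binary <- as.logical(unlist(st$clinical_binary))
    model$stats <- st
  }
  model
}
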