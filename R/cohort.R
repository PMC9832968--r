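# Cohort data model: multimodal patient records (expression + clinical +
# censored survival), 5-year label construction, patient typing, file I/O,
# standardization, splitting and summaries.

#' Label construction rule for 5-year prognosis
#'
#' @param horizon_months prediction horizon in months (default 60 = 5 years).
#' @param event_semantics which survival endpoint the event column encodes:
#'   disease-specific (`"DSS"`), overall (`"OS"`) or disease-free (`"DFS"`)
#'   survival. Metadata only; the labeling rule is identical.
#' @return a `label_spec` object.
#' @export
label_spec <- function(horizon_months = 60, event_semantics = c("DSS", "OS", "DFS")) {
  if (!is.numeric(horizon_months) || horizon_months <= 0) {
    stop("`horizon_months` must be a positive number")
  }
  structure(list(horizon_months = horizon_months,
                 event_semantics = match.arg(event_semantics)),
            class = "label_spec")
}

#' Derive the binary prognosis label from a censored survival outcome
#'
#' A patient is `"poor"` if the event occurred before the horizon, `"good"`
#' if followed up to at least the horizon (event or not; surviving exactly to
#' the horizon counts as good), and `"undefined"` when censored before the
#' horizon — such patients carry no supervised signal and join the unlabeled
#' pool.
#'
#' @param outcome list or data.frame row with `time_months` (non-negative)
#'   and `event` (1 = event observed, 0 = censored). Vectors are accepted.
#' @param spec a [label_spec()].
#' @return character vector in `{"good", "poor", "undefined"}`.
#' @export
assign_label <- function(outcome, spec = label_spec()) {
  time <- outcome$time_months
  event <- outcome$event
  if (any(!is.na(time) & time < 0)) stop("negative survival time")
  if (!all(stats::na.omit(event) %in% c(0, 1))) stop("`event` must be 0 or 1")
  out <- ifelse(is.na(time) | is.na(event), "undefined",
         ifelse(time >= spec$horizon_months, "good",
         ifelse(event == 1, "poor", "undefined")))
  as.character(out)
}

#' Classify a patient record into Types I-IV
#'
#' The partition used for loss dispatch, by completeness of the clinical
#' vector and the label: entirely missing clinical data dominates (Type III);
#' otherwise an undefined label gives Type II; otherwise any masked clinical
#' cell gives Type IV; fully observed labeled records are Type I. Expression
#' must always be present.
#'
#' @param record list with `expression` (numeric vector or NULL), `clinical`
#'   (numeric vector with NA for masked cells, or NULL), `label` (one of
#'   good/poor/undefined).
#' @return one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
classify_patient_type <- function(record) {
  if (is.null(record$expression) || length(record$expression) == 0L) {
    stop("unsupported record: expression data absent")
  }
  cl <- record$clinical
  if (is.null(cl) || length(cl) == 0L || all(is.na(cl))) return("III")
  lab <- record$label
  if (is.null(lab) || is.na(lab) || lab == "undefined") return("II")
  if (anyNA(cl)) return("IV")
  "I"
}

# vectorized typing over cohort columns
ptype_vector <- function(clinical_present, n_masked, n_clin, label) {
  unlabeled <- is.na(label) | label == "undefined"
  ifelse(!clinical_present | (n_clin > 0L & n_masked == n_clin), "III",
  ifelse(unlabeled, "II",
  ifelse(n_masked > 0L, "IV", "I")))
}

new_cohort <- function(ids, expression, clinical, clinical_present, survival,
                       label, gene_names, clinical_names, split = NULL) {
  n <- length(ids)
  n_clin <- length(clinical_names)
  n_masked <- if (n_clin) rowSums(is.na(clinical)) else rep(0L, n)
  ptype <- ptype_vector(clinical_present, n_masked, n_clin, label)
  if (is.null(split)) {
    split <- ifelse(label %in% c("good", "poor"), NA_character_, "unlabeled")
  }
  structure(list(
    ids = ids,
    expression = expression,
    clinical = clinical,
    clinical_present = clinical_present,
    survival = survival,
    label = label,
    ptype = ptype,
    split = split,
    gene_names = gene_names,
    clinical_names = clinical_names
  ), class = "prog_cohort")
}

#' @export
print.prog_cohort <- function(x, ...) {
  cat(sprintf("prog_cohort: %d patients, %d genes, %d clinical features\n",
              length(x$ids), length(x$gene_names), length(x$clinical_names)))
  cat("types: ", paste(sprintf("%s=%d", names(table(x$ptype)), table(x$ptype)),
                       collapse = " "), "\n")
  lab <- table(factor(x$label, c("good", "poor", "undefined")))
  cat("labels:", paste(sprintf("%s=%d", names(lab), lab), collapse = " "), "\n")
  if (!all(is.na(x$split))) {
    cat("splits:", paste(sprintf("%s=%d", names(table(x$split)), table(x$split)),
                         collapse = " "), "\n")
  }
  invisible(x)
}

#' Extract one patient record
#'
#' @param cohort a `prog_cohort`.
#' @param id patient identifier.
#' @return list with `id`, `expression`, `clinical` (NA-masked, or NULL when
#'   the modality is absent), `outcome`, `label`, `ptype`, `split`.
#' @export
get_record <- function(cohort, id) {
  i <- match(id, cohort$ids)
  if (is.na(i)) stop("unknown patient id: ", id)
  list(id = id,
       expression = cohort$expression[i, ],
       clinical = if (cohort$clinical_present[i]) cohort$clinical[i, ] else NULL,
       outcome = list(time_months = cohort$survival$time_months[i],
                      event = cohort$survival$event[i]),
       label = cohort$label[i],
       ptype = cohort$ptype[i],
       split = cohort$split[i])
}

# delimiter autodetection: tab if the header contains tabs, else comma
read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"), check.names = FALSE,
                    comment.char = "")
}

numeric_matrix <- function(df, what) {
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate patient ids in ", what, " table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (ncol(df) < 2L) {
    return(list(ids = ids, mat = matrix(numeric(0), length(ids), 0L), names = character(0)))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(m)[!apply(m, 2L, function(col) {
      suppressWarnings(all(is.na(col) | !is.na(as.numeric(col))))
    })]
    if (length(bad)) {
      stop("non-numeric cells in ", what, " column(s): ", paste(bad, collapse = ", "))
    }
    m <- apply(m, 2L, function(col) suppressWarnings(as.numeric(col)))
    m <- matrix(m, nrow = length(ids), dimnames = list(NULL, colnames(df)[-1L]))
  }
  list(ids = ids, mat = m, names = colnames(df)[-1L])
}

#' Read a multimodal cohort from delimited text files
#'
#' All three tables are comma- or tab-delimited (autodetected), one patient
#' per row, with a header row whose first column is the patient id. Missing
#' clinical cells may be empty or `NA`. Every patient must have expression
#' data; patients absent from the clinical table have no clinical modality
#' (Type III), and patients absent from the survival table (or `NULL`
#' `survival_path`) get undefined labels.
#'
#' @param expression_path patients x genes table of continuous values.
#' @param clinical_path patients x clinical-features table (may be `NULL`).
#' @param survival_path table with columns id, `time_months`, `event`
#'   (may be `NULL`).
#' @param spec a [label_spec()].
#' @return a `prog_cohort`.
#' @export
read_cohort <- function(expression_path, clinical_path = NULL,
                        survival_path = NULL, spec = label_spec()) {
  ex <- numeric_matrix(read_delim_auto(expression_path), "expression")
  if (anyNA(ex$mat)) stop("missing values in the expression table")
  ids <- ex$ids
  n <- length(ids)

  clin_mat <- matrix(numeric(0), n, 0L)
  clin_names <- character(0)
  clin_present <- rep(FALSE, n)
  if (!is.null(clinical_path)) {
    cl <- numeric_matrix(read_delim_auto(clinical_path), "clinical")
    extra <- setdiff(cl$ids, ids)
    if (length(extra)) {
      stop("id(s) present in clinical but not expression table: ",
           paste(extra, collapse = ", "))
    }
    clin_names <- cl$names
    clin_mat <- matrix(NA_real_, n, length(clin_names),
                       dimnames = list(NULL, clin_names))
    idx <- match(cl$ids, ids)
    clin_mat[idx, ] <- cl$mat
    clin_present[idx] <- TRUE
    # rows with every cell missing carry no clinical modality
    if (length(clin_names)) {
      clin_present[rowSums(!is.na(clin_mat)) == 0L] <- FALSE
    } else {
      clin_present[] <- FALSE
    }
  }

  surv <- data.frame(time_months = rep(NA_real_, n), event = rep(NA_real_, n))
  if (!is.null(survival_path)) {
    sv <- read_delim_auto(survival_path)
    if (!all(c("time_months", "event") %in% names(sv))) {
      stop("survival table must have columns `time_months` and `event`")
    }
    sids <- as.character(sv[[1L]])
    if (anyDuplicated(sids)) stop("duplicate patient ids in survival table")
    idx <- match(sids, ids)
    keep <- !is.na(idx)
    surv$time_months[idx[keep]] <- as.numeric(sv$time_months[keep])
    surv$event[idx[keep]] <- as.numeric(sv$event[keep])
  }
  label <- assign_label(surv, spec)
  rownames(ex$mat) <- ids
  new_cohort(ids, ex$mat, clin_mat, clin_present, surv, label,
             ex$names, clin_names)
}

#' Write a cohort back to delimited text files
#'
#' Emits `expression.csv`, `clinical.csv` and `survival.csv` under `dir`
#' in the format [read_cohort()] expects.
#'
#' @param cohort a `prog_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ed <- data.frame(id = cohort$ids, cohort$expression, check.names = FALSE)
  utils::write.csv(ed, file.path(dir, "expression.csv"), row.names = FALSE)
  keep <- cohort$clinical_present
  cd <- data.frame(id = cohort$ids[keep],
                   cohort$clinical[keep, , drop = FALSE], check.names = FALSE)
  utils::write.csv(cd, file.path(dir, "clinical.csv"), row.names = FALSE, na = "")
  keep_s <- !is.na(cohort$survival$time_months)
  sd <- data.frame(id = cohort$ids[keep_s],
                   time_months = cohort$survival$time_months[keep_s],
                   event = cohort$survival$event[keep_s])
  utils::write.csv(sd, file.path(dir, "survival.csv"), row.names = FALSE)
  invisible(dir)
}

#' Split manifest as a data frame
#'
#' @param cohort a `prog_cohort` (after [split_cohort()]).
#' @return data.frame with columns id, split, ptype, label.
#' @export
split_manifest <- function(cohort) {
  data.frame(id = cohort$ids, split = cohort$split, ptype = cohort$ptype,
             label = cohort$label, stringsAsFactors = FALSE)
}

# columns that take only values {0,1} among observed entries are binary and
# are never standardized
binary_columns <- function(mat) {
  if (ncol(mat) == 0L) return(logical(0))
  apply(mat, 2L, function(col) {
    v <- unique(stats::na.omit(col))
    length(v) > 0L && all(v %in% c(0, 1))
  })
}

#' Standardize continuous features using statistics of one split
#'
#' Expression columns and continuous clinical columns are centered and scaled
#' to the mean/sd of the fit split only (training statistics are reused at
#' inference). Binary clinical columns (observed values in {0,1}) and the
#' missingness pattern are untouched. Zero-variance columns get sd 1 with a
#' warning.
#'
#' @param cohort a `prog_cohort`.
#' @param fit_on split name whose patients define the statistics (default
#'   `"train"`; the unlabeled pool is included for generative training
#'   stability when `include_unlabeled = TRUE`).
#' @param include_unlabeled also pool unlabeled patients when fitting the
#'   statistics (default FALSE).
#' @param stats reuse previously fitted statistics (output field `stats` of
#'   an earlier call) instead of fitting.
#' @return list with `cohort` (transformed) and `stats` (per-column means
#'   and sds for both modalities).
#' @export
standardize <- function(cohort, fit_on = "train", include_unlabeled = FALSE,
                        stats = NULL) {
  if (is.null(stats)) {
    rows <- cohort$split %in% fit_on
    if (include_unlabeled) rows <- rows | cohort$split %in% "unlabeled"
    if (!any(rows)) stop("fit split `", paste(fit_on, collapse = ","), "` is empty")
    col_stats <- function(mat) {
      if (ncol(mat) == 0L) return(list(mean = numeric(0), sd = numeric(0)))
      m <- apply(mat[rows, , drop = FALSE], 2L, mean, na.rm = TRUE)
      s <- apply(mat[rows, , drop = FALSE], 2L, stats::sd, na.rm = TRUE)
      if (any(!is.finite(s) | s == 0)) {
        warning("zero-variance column(s): ",
                paste(colnames(mat)[!is.finite(s) | s == 0], collapse = ", "),
                "; sd set to 1")
        s[!is.finite(s) | s == 0] <- 1
      }
      list(mean = m, sd = s)
    }
    bin <- binary_columns(cohort$clinical)
    ge <- col_stats(cohort$expression)
    cl <- col_stats(cohort$clinical)
    if (any(bin)) { cl$mean[bin] <- 0; cl$sd[bin] <- 1 }
    stats <- list(gene = ge, clinical = cl, clinical_binary = bin)
  }
  out <- cohort
  out$expression <- sweep(sweep(cohort$expression, 2L, stats$gene$mean, "-"),
                          2L, stats$gene$sd, "/")
  if (ncol(cohort$clinical)) {
    out$clinical <- sweep(sweep(cohort$clinical, 2L, stats$clinical$mean, "-"),
                          2L, stats$clinical$sd, "/")
  }
  list(cohort = out, stats = stats)
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize a cohort the way study tables report it
#'
#' Per labeled split: patient counts, good/poor counts with percentages
#' (rounded half-up to 2 decimals), the majority/minority imbalance ratio and
#' the median survival time. For the unlabeled pool: per-type counts and
#' percentages.
#'
#' @param cohort a `prog_cohort` with labels assigned.
#' @return a `cohort_summary` object (list of data.frames).
#' @export
summarize_cohort <- function(cohort) {
  splits <- c("train", "validation", "test")
  rows <- lapply(splits, function(s) {
    i <- which(cohort$split %in% s)
    good <- sum(cohort$label[i] == "good")
    poor <- sum(cohort$label[i] == "poor")
    n <- length(i)
    imb <- if (min(good, poor) > 0) max(good, poor) / min(good, poor) else NA_real_
    data.frame(split = s, n = n, good = good, poor = poor,
               good_pct = if (n) round_half_up(100 * good / n) else 0,
               poor_pct = if (n) round_half_up(100 * poor / n) else 0,
               imbalance_ratio = round_half_up(imb),
               median_survival = if (n) stats::median(cohort$survival$time_months[i],
                                                      na.rm = TRUE) else NA_real_)
  })
  unl <- which(cohort$split %in% "unlabeled")
  tcount <- table(factor(cohort$ptype[unl], c("II", "III", "IV")))
  unlabeled <- data.frame(
    ptype = names(tcount), n = as.integer(tcount),
    pct = if (length(unl)) round_half_up(100 * as.integer(tcount) / length(unl))
          else rep(0, 3L))
  structure(list(labeled = do.call(rbind, rows), unlabeled = unlabeled,
                 n_total = length(cohort$ids)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Labeled splits:\n")
  print(x$labeled, row.names = FALSE)
  cat("Unlabeled pool by patient type:\n")
  print(x$unlabeled, row.names = FALSE)
  invisible(x)
}

# largest-remainder allocation of n into fractions (sums to n exactly)
allocate_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Assign labeled patients to train/validation/test splits
#'
#' Only labeled patients are split; every unlabeled patient joins the
#' `"unlabeled"` pool used during semi-supervised training. Deterministic
#' under a fixed seed; with `stratify_by_label` the class proportions per
#' split match the cohort within one patient.
#'
#' @param cohort a `prog_cohort`.
#' @param fractions numeric vector of 2 or 3 fractions summing to 1, named or
#'   in the order train, (validation,) test.
#' @param seed integer seed.
#' @param stratify_by_label stratify the assignment on the label.
#' @return the cohort with its `split` field populated.
#' @export
split_cohort <- function(cohort, fractions = c(train = 0.6, validation = 0.2, test = 0.2),
                         seed = 1, stratify_by_label = TRUE) {
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (is.null(names(fractions))) {
    names(fractions) <- if (length(fractions) == 2L) c("train", "test")
                        else c("train", "validation", "test")
  }
  labeled <- which(cohort$label %in% c("good", "poor"))
  split <- ifelse(seq_along(cohort$ids) %in% labeled, NA_character_, "unlabeled")
  set.seed(seed)
  if (stratify_by_label) {
    for (lab in c("good", "poor")) {
      idx <- labeled[cohort$label[labeled] == lab]
      if (length(idx)) {
        idx_sh <- sample(idx)
        counts <- allocate_counts(length(idx_sh), fractions)
        split[idx_sh] <- rep(names(fractions), counts)
      }
    }
  } else {
    idx_sh <- sample(labeled)
    counts <- allocate_counts(length(idx_sh), fractions)
    split[idx_sh] <- rep(names(fractions), counts)
  }
  cohort$split <- split
  cohort
}
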