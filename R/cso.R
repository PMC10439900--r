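# Cancer-signal-origin cascade: a Cancer Classifier (any cancer vs control)
# gates a Cancer Type Classifier (colorectal vs lung). Performance is
# measured by plain stratified 5-fold cross-validation (80% train / 20%
# test per fold); only test samples called cancer-positive are forwarded to
# the type classifier, whose argmax class probability gives the type call.

#' Cancer-signal-origin cross-validation
#'
#' Per fold, both classifiers are trained on the 80% training split: the
#' Cancer Classifier on both cancer classes versus controls, the Cancer
#' Type Classifier on the two cancer classes against each other. On the
#' held-out 20%, samples whose cancer-class probability exceeds
#' `cancer_threshold` are forwarded to the type classifier and receive the
#' type with the highest probability; the rest are "not detected".
#'
#' @param x Samples x features matrix.
#' @param classes Character vector over `control_label` and `type_labels`.
#' @param dnn_cfg From [dnn_config()].
#' @param folds Number of cross-validation folds.
#' @param seed Master seed.
#' @param cancer_threshold Probability gate of the Cancer Classifier.
#' @param control_label,type_labels Class names.
#' @return A `cso_report`: `calls` (per-sample truth, cancer_score,
#'   cancer_call, type_call), `confusion` (truth type x called type matrix
#'   with a `not_detected` column).
#' @export
cso_crossval <- function(x, classes, dnn_cfg, folds = 5L, seed = 1L,
                         cancer_threshold = 0.5,
                         control_label = "control",
                         type_labels = c("crc", "lung")) {
  x <- as.matrix(x)
  stopifnot(length(classes) == nrow(x))
  needed <- c(control_label, type_labels)
  if (!all(needed %in% classes))
    stop("classes must include all of: ", paste(needed, collapse = ", "))
  if (any(table(factor(classes, levels = needed)) < folds))
    stop("each class needs at least ", folds, " members")
  n <- nrow(x)
  set.seed(seed)
  fold <- make_folds(classes, folds, stratified = TRUE)
  model_seeds <- matrix(sample.int(2147483646L, 2L * folds), nrow = folds)
  cancer_score <- numeric(n)
  type_call <- rep(NA_character_, n)
  for (f in seq_len(folds)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    is_cancer_tr <- classes[train_idx] %in% type_labels
    cfg1 <- dnn_cfg; cfg1$seed <- model_seeds[f, 1L]
    cancer_model <- train_model(x[train_idx, , drop = FALSE],
                                as.integer(is_cancer_tr), cfg1)
    type_tr <- train_idx[classes[train_idx] %in% type_labels]
    cfg2 <- dnn_cfg; cfg2$seed <- model_seeds[f, 2L]
    type_model <- train_model(
      x[type_tr, , drop = FALSE],
      as.integer(classes[type_tr] == type_labels[2L]), cfg2)
    sc <- score_samples(cancer_model, x[test_idx, , drop = FALSE])
    cancer_score[test_idx] <- sc
    fwd <- test_idx[sc > cancer_threshold]
    if (length(fwd) > 0L) {
      p2 <- score_samples(type_model, x[fwd, , drop = FALSE])
      type_call[fwd] <- ifelse(p2 > 0.5, type_labels[2L], type_labels[1L])
    }
  }
  calls <- data.frame(sample_id = rownames(x) %||% paste0("s", seq_len(n)),
                      truth = classes,
                      cancer_score = cancer_score,
                      cancer_call = !is.na(type_call),
                      type_call = type_call,
                      stringsAsFactors = FALSE)
  confusion <- table(
    truth = factor(calls$truth, levels = needed),
    called = factor(ifelse(is.na(calls$type_call), "not_detected",
                           calls$type_call),
                    levels = c(type_labels, "not_detected")))
  structure(list(calls = calls, confusion = unclass(confusion),
                 cancer_threshold = cancer_threshold,
                 control_label = control_label, type_labels = type_labels),
            class = "cso_report")
}

#' Cascade sensitivity and per-type true-positive rates
#'
#' Cascade sensitivity is the fraction of cancer samples called
#' cancer-positive by the gate; the per-type true-positive rate is, among
#' forwarded true positives of each type, the fraction whose type call is
#' correct. Undefined rates (no forwarded samples) are reported missing.
#'
#' @param report From [cso_crossval()], or a list with `n_cancer`,
#'   `n_detected` and optionally per-type forwarded/correct counts for
#'   worked-example arithmetic.
#' @return List: `cascade_sensitivity_pct`, `type_tpr_pct` (named vector).
#' @export
cso_summary <- function(report) {
  if (inherits(report, "cso_report")) {
    calls <- report$calls
    cancers <- calls$truth %in% report$type_labels
    n_cancer <- sum(cancers)
    n_detected <- sum(cancers & calls$cancer_call)
    tpr <- vapply(report$type_labels, function(tl) {
      fwd <- cancers & calls$cancer_call & calls$truth == tl
      if (!any(fwd)) return(NA_real_)
      100 * mean(calls$type_call[fwd] == tl)
    }, numeric(1))
  } else {
    n_cancer <- report$n_cancer
    n_detected <- report$n_detected
    tpr <- if (!is.null(report$type_forwarded)) {
      100 * report$type_correct / report$type_forwarded
    } else NA_real_
  }
  list(cascade_sensitivity_pct = 100 * n_detected / n_cancer,
       type_tpr_pct = tpr)
}
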