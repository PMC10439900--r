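# Repeated nested cross-validation. Each repetition makes a stratified
# outer 5-fold split; inside every outer-training set a stratified inner
# 5-fold split trains five models (each leaving one inner fold out as a
# validation part), and each outer-fold test sample is scored by all five
# inner models. With 20 repetitions this yields 100 out-of-training scores
# per sample; a sample is never scored by a model that saw it in training.

#' Cross-validation configuration
#'
#' @param n_repetitions Independent repetitions.
#' @param outer_folds,inner_folds Fold counts.
#' @param stratified Stratify folds by class.
#' @param seed Master seed driving splits and all model seeds.
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_repetitions = 20L, outer_folds = 5L, inner_folds = 5L,
                      stratified = TRUE, seed = 1L) {
  stopifnot(n_repetitions >= 1L, outer_folds >= 2L, inner_folds >= 2L)
  structure(list(n_repetitions = as.integer(n_repetitions),
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "cv_config")
}

# fold assignment (1..k per element); stratified round-robin within class
# after a shuffle, using the current RNG state
make_folds <- function(y, k, stratified = TRUE) {
  fold <- integer(length(y))
  groups <- if (stratified) split(seq_along(y), y) else list(seq_along(y))
  for (idx in groups) {
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated nested cross-validation producing out-of-training cancer scores
#'
#' @param x Samples x features matrix (normalized depths).
#' @param y Binary labels; see [train_model()].
#' @param dnn_cfg From [dnn_config()] (its `seed` is superseded by seeds
#'   derived from `cv_cfg$seed`).
#' @param cv_cfg From [cv_config()].
#' @return A `cancer_score_set`: `scores` (samples x
#'   `n_repetitions * inner_folds` matrix), `mean`, `iqr` (per sample),
#'   `labels`, and `fold_log` for the leakage audit — per model column, the
#'   training index set and the scored (outer test) index set.
#' @export
repeated_nested_cv <- function(x, y, dnn_cfg, cv_cfg = cv_config()) {
  x <- as.matrix(x)
  yb <- as_binary_labels(y)
  n <- nrow(x)
  cls_n <- table(yb)
  if (length(cls_n) < 2L)
    stop("degenerate training set: only one class present")
  if (any(cls_n < cv_cfg$outer_folds))
    stop("each class needs at least outer_folds (", cv_cfg$outer_folds,
         ") members; got ", paste(cls_n, collapse = "/"))
  n_models_per_rep <- cv_cfg$inner_folds
  n_cols <- cv_cfg$n_repetitions * n_models_per_rep
  scores <- matrix(NA_real_, n, n_cols,
                   dimnames = list(rownames(x), NULL))
  fold_log <- vector("list", cv_cfg$n_repetitions)

  set.seed(cv_cfg$seed)
  rep_seeds <- sample.int(2147483646L, cv_cfg$n_repetitions)
  model_seeds <- matrix(sample.int(2147483646L,
                                   cv_cfg$n_repetitions * cv_cfg$outer_folds *
                                     cv_cfg$inner_folds),
                        nrow = cv_cfg$n_repetitions)
  for (r in seq_len(cv_cfg$n_repetitions)) {
    set.seed(rep_seeds[r])
    outer <- make_folds(yb, cv_cfg$outer_folds, cv_cfg$stratified)
    rep_log <- vector("list", cv_cfg$outer_folds)
    for (f in seq_len(cv_cfg$outer_folds)) {
      test_idx <- which(outer == f)
      train_pool <- which(outer != f)
      inner <- make_folds(yb[train_pool], cv_cfg$inner_folds,
                          cv_cfg$stratified)
      fold_models <- vector("list", cv_cfg$inner_folds)
      for (j in seq_len(cv_cfg$inner_folds)) {
        train_idx <- train_pool[inner != j]
        valid_idx <- train_pool[inner == j]
        cfg <- dnn_cfg
        cfg$seed <- model_seeds[r, (f - 1L) * cv_cfg$inner_folds + j]
        model <- train_model(x[train_idx, , drop = FALSE], yb[train_idx], cfg)
        col <- (r - 1L) * n_models_per_rep + j
        scores[test_idx, col] <- score_samples(model,
                                               x[test_idx, , drop = FALSE])
        fold_models[[j]] <- list(train = train_idx, valid = valid_idx,
                                 scored = test_idx, column = col)
      }
      rep_log[[f]] <- fold_models
    }
    fold_log[[r]] <- rep_log
  }
  stopifnot(!anyNA(scores))
  structure(list(scores = scores,
                 mean = rowMeans(scores),
                 iqr = apply(scores, 1, function(s)
                   unname(diff(quantile(s, c(0.25, 0.75))))),
                 labels = yb,
                 fold_log = fold_log,
                 cv_cfg = cv_cfg),
            class = "cancer_score_set")
}

#' Exhaustive leakage audit of a cross-validation run
#'
#' Verifies, for every (sample, model) scoring pair recorded in the fold
#' log, that the sample was absent from that model's training index set.
#'
#' @param score_set From [repeated_nested_cv()].
#' @return `TRUE` if no leakage; otherwise stops with the offending pair.
#' @export
audit_no_leakage <- function(score_set) {
  for (rep_log in score_set$fold_log) {
    for (fold_models in rep_log) {
      for (m in fold_models) {
        bad <- intersect(m$scored, m$train)
        if (length(bad) > 0L)
          stop("leakage: sample ", bad[1], " scored by a model trained on it")
      }
    }
  }
  TRUE
}

#' Per-sample and per-class score summary
#'
#' The per-sample summary is the mean and interquartile range (Q3 - Q1,
#' linear-interpolation quantiles) of the out-of-training scores; the
#' class summary averages the IQR within each truth class as a stability
#' measure.
#'
#' @param score_set From [repeated_nested_cv()].
#' @param truth_class Optional character vector of class names per sample
#'   (defaults to the binary labels).
#' @return List with `per_sample` and `per_class` data.frames.
#' @export
score_summary <- function(score_set, truth_class = NULL) {
  if (is.null(truth_class)) truth_class <- as.character(score_set$labels)
  per_sample <- data.frame(
    sample_id = rownames(score_set$scores) %||%
      paste0("s", seq_len(nrow(score_set$scores))),
    truth = truth_class,
    mean_score = unname(score_set$mean),
    iqr = unname(score_set$iqr),
    n_scores = ncol(score_set$scores),
    stringsAsFactors = FALSE)
  agg <- stats::aggregate(cbind(mean_score, iqr) ~ truth, per_sample, mean)
  names(agg) <- c("truth", "mean_score", "average_iqr")
  list(per_sample = per_sample, per_class = agg)
}

#' Sample-size sweep of AUC and score stability
#'
#' For each requested ratio, draws a stratified subsample without
#' replacement, reruns the repeated nested cross-validation (typically with
#' fewer repetitions), and records the AUC of the mean scores and the
#' cohort-average IQR.
#'
#' @param x,y As in [repeated_nested_cv()].
#' @param ratios Subsample fractions in (0, 1].
#' @param dnn_cfg,cv_cfg Model and CV configuration.
#' @param seed Seed for the subsampling.
#' @return data.frame with one row per usable ratio: ratio, n, auc,
#'   average_iqr.
#' @export
sample_size_sweep <- function(x, y, ratios, dnn_cfg, cv_cfg = cv_config(),
                              seed = 1L) {
  x <- as.matrix(x)
  yb <- as_binary_labels(y)
  stopifnot(all(ratios > 0), all(ratios <= 1))
  set.seed(seed)
  sub_seeds <- sample.int(2147483646L, length(ratios))
  rows <- list()
  for (i in seq_along(ratios)) {
    r <- ratios[i]
    cvc <- cv_cfg
    if (r == 1) {
      # no-op subsample: identical to the full-cohort run at the same seed
      idx <- seq_along(yb)
    } else {
      set.seed(sub_seeds[i])
      idx <- sort(unlist(lapply(split(seq_along(yb), yb), function(g)
        sample(g, max(1L, round(r * length(g))))), use.names = FALSE))
      cvc$seed <- sub_seeds[i]
    }
    if (length(idx) < 2L * cv_cfg$outer_folds ||
        any(table(yb[idx]) < cv_cfg$outer_folds)) {
      warning("ratio ", r, " leaves too few samples; skipped")
      next
    }
    set_r <- repeated_nested_cv(x[idx, , drop = FALSE], yb[idx], dnn_cfg, cvc)
    rows[[length(rows) + 1L]] <- data.frame(
      ratio = r, n = length(idx),
      auc = roc_auc(set_r$mean, yb[idx])$auc,
      average_iqr = mean(set_r$iqr))
  }
  do.call(rbind, rows)
}
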