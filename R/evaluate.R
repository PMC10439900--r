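# ROC/AUC, anchored-specificity thresholding, and stratified sensitivity
# with Wilson 95% confidence intervals. The operating point is anchored by
# the number of allowed false positives among controls (1 of 126 gives the
# 99.2% specificity used throughout the cancer-detection evaluation).

#' ROC curve and AUC
#'
#' AUC is computed as the Mann-Whitney U statistic of the case scores over
#' the control scores divided by `n_pos * n_neg`, counting ties as 1/2 —
#' equivalently, trapezoidal integration of the ROC curve over all distinct
#' thresholds.
#'
#' @param scores Numeric scores (higher = more cancer-like).
#' @param labels Binary labels; see [train_model()].
#' @return List with `auc` and `points` (data.frame threshold, tpr, fpr,
#'   ordered by descending threshold).
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes required for ROC")
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  # Mann-Whitney with midranks
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  thr <- sort(unique(scores), decreasing = TRUE)
  points <- data.frame(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(t) mean(pos >= t), numeric(1))),
    fpr = c(0, vapply(thr, function(t) mean(neg >= t), numeric(1))))
  list(auc = auc, points = points)
}

#' Decision threshold anchored at k allowed false positives
#'
#' Places the threshold midway between the k-th and (k+1)-th largest
#' control scores so that exactly `k` controls strictly exceed it;
#' specificity is `(n - k) / n`. With `k = 0` the threshold is the maximum
#' control score (no control strictly exceeds it). If tied control scores
#' straddle the cut, the threshold moves up to the tied value so that false
#' positives stay at or below `k`, with a warning.
#'
#' @param control_scores Scores of the control samples.
#' @param k Allowed false positives, `0 <= k < n`.
#' @return List with `threshold`, `specificity`, `n_controls`,
#'   `false_positives` (recounted).
#' @export
threshold_at_k_false_positives <- function(control_scores, k = 1L) {
  n <- length(control_scores)
  stopifnot(n >= 1L, k >= 0L, k < n)
  s <- sort(unname(control_scores), decreasing = TRUE)
  if (k == 0L) {
    thr <- s[1L]
  } else if (s[k] == s[k + 1L]) {
    warning("tied control scores at the anchored cut; threshold moved up ",
            "to keep false positives <= ", k)
    thr <- s[k]
  } else {
    thr <- (s[k] + s[k + 1L]) / 2
  }
  fp <- sum(control_scores > thr)
  list(threshold = thr, specificity = (n - fp) / n,
       n_controls = n, false_positives = fp)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes,n Counts, `0 <= successes <= n`.
#' @param confidence Coverage (default 0.95).
#' @return Named vector `c(lo, hi)` of proportions in [0, 1].
#' @export
wilson_ci <- function(successes, n, confidence = 0.95) {
  stopifnot(n >= 1L, successes >= 0L, successes <= n)
  z <- qnorm((1 + confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, center - half), hi = min(1, center + half))
}

#' Stratified sensitivity report at an anchored threshold
#'
#' Sensitivity is computed on the per-sample mean cancer score: a case is
#' positive when its mean score strictly exceeds the threshold. One row is
#' produced overall and per stratum (e.g. clinical stage or subtype), each
#' with its Wilson 95% CI in percent; empty strata yield `n = 0` rows with
#' missing sensitivity.
#'
#' @param scores Mean scores of all samples.
#' @param labels Binary labels (1 = case).
#' @param strata Character vector of stratum labels for cases (`NA`
#'   allowed for controls); e.g. stage.
#' @param threshold From [threshold_at_k_false_positives()].
#' @return data.frame: stratum, n, n_positive, sensitivity_pct, ci_lo_pct,
#'   ci_hi_pct. The first row ("all") covers every case.
#' @export
sensitivity_report <- function(scores, labels, strata = NULL, threshold) {
  y <- as_binary_labels(labels)
  case <- y == 1L
  pos <- scores > threshold
  strat_levels <- if (is.null(strata)) character(0) else
    sort(unique(strata[case & !is.na(strata)]))
  one_row <- function(name, sel) {
    n <- sum(sel); np <- sum(pos[sel])
    if (n == 0L)
      return(data.frame(stratum = name, n = 0L, n_positive = 0L,
                        sensitivity_pct = NA_real_, ci_lo_pct = NA_real_,
                        ci_hi_pct = NA_real_))
    ci <- wilson_ci(np, n)
    data.frame(stratum = name, n = n, n_positive = np,
               sensitivity_pct = 100 * np / n,
               ci_lo_pct = 100 * ci[["lo"]], ci_hi_pct = 100 * ci[["hi"]])
  }
  rows <- c(list(one_row("all", case)),
            lapply(strat_levels, function(st)
              one_row(st, case & !is.na(strata) & strata == st)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
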