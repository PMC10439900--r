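# Marker discovery, model interpretation, and confounder diagnostics:
# per-site two-sample t tests, Shapley-style / permutation feature
# importance, genomic-region annotation of sites, PCA batch screening, and
# score-covariate association checks.

#' Per-site two-sample t tests between cancer and control
#'
#' Student's pooled-variance two-sided t test per site on the normalized
#' depths (Welch available via `var_equal = FALSE`). Sites are ranked by P;
#' the selected flag marks `P < threshold` (raw P against a fixed cutoff,
#' no multiplicity correction by default; Benjamini-Hochberg adjusted P is
#' reported alongside for convenience).
#'
#' @param x Samples x sites matrix of normalized depths.
#' @param labels Binary labels (1 = cancer).
#' @param threshold Selection cutoff on raw P (default 1e-7).
#' @param var_equal Pooled variance (Student) if `TRUE`, Welch otherwise.
#' @return data.frame per site: site_id, mean_case, mean_control, t, df, p,
#'   p_bh, rank, selected.
#' @export
marker_ttests <- function(x, labels, threshold = 1e-7, var_equal = TRUE) {
  y <- as_binary_labels(labels)
  x1 <- x[y == 1L, , drop = FALSE]
  x0 <- x[y == 0L, , drop = FALSE]
  n1 <- nrow(x1); n0 <- nrow(x0)
  if (n1 < 2L || n0 < 2L) stop("need at least 2 samples per group")
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  v0 <- colSums(sweep(x0, 2, m0)^2) / (n0 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, ncol(x))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  tstat <- (m1 - m0) / se
  degenerate <- se == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance sites: P set to 1")
    tstat[degenerate] <- 0
  }
  p <- 2 * pt(-abs(tstat), df)
  p[degenerate] <- 1
  out <- data.frame(site_id = colnames(x) %||% paste0("site_", seq_len(ncol(x))),
                    mean_case = m1, mean_control = m0,
                    t = tstat, df = df, p = p,
                    p_bh = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out$rank <- rank(out$p, ties.method = "first")
  out$selected <- out$p < threshold
  rownames(out) <- NULL
  out[order(out$rank), ]
}

#' Feature importance of a trained cancer-score model
#'
#' `method = "shap"` estimates Shapley values of the model's score function
#' by Monte-Carlo permutation sampling: for each sampled feature ordering,
#' features are switched one at a time from a background reference to the
#' explained sample, and the marginal score changes are accumulated; the
#' reported importance is the mean absolute attribution over the explained
#' samples. `method = "permutation"` shuffles one feature column at a time
#' and reports the mean absolute score change.
#'
#' @param model From [train_model()].
#' @param x Samples x features matrix to explain.
#' @param method "shap" or "permutation".
#' @param n_perm Sampled orderings (shap) or shuffles (permutation).
#' @param seed Seed.
#' @param background Background rows for "shap" (default: column means of
#'   `x`, a single reference row).
#' @return data.frame per feature: feature, importance, rank (descending
#'   importance, ties broken by feature order).
#' @export
feature_importance <- function(model, x, method = c("shap", "permutation"),
                               n_perm = 50L, seed = 1L, background = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x)
  d <- ncol(x)
  set.seed(seed)
  if (method == "shap") {
    bg <- if (is.null(background)) matrix(colMeans(x), nrow = 1L) else
      as.matrix(background)
    bg_row <- colMeans(bg)
    phi <- matrix(0, nrow(x), d)
    for (it in seq_len(n_perm)) {
      ord <- sample.int(d)
      cur <- matrix(bg_row, nrow(x), d, byrow = TRUE)
      prev_score <- score_samples(model, cur)
      for (j in ord) {
        cur[, j] <- x[, j]
        new_score <- score_samples(model, cur)
        phi[, j] <- phi[, j] + (new_score - prev_score)
        prev_score <- new_score
      }
    }
    imp <- colMeans(abs(phi / n_perm))
  } else {
    base_score <- score_samples(model, x)
    imp <- numeric(d)
    for (j in seq_len(d)) {
      delta <- 0
      for (it in seq_len(n_perm)) {
        xp <- x
        xp[, j] <- x[sample.int(nrow(x)), j]
        delta <- delta + mean(abs(score_samples(model, xp) - base_score))
      }
      imp[j] <- delta / n_perm
    }
  }
  out <- data.frame(feature = colnames(x) %||% paste0("f", seq_len(d)),
                    importance = imp, stringsAsFactors = FALSE)
  out$rank <- rank(-out$importance, ties.method = "first")
  out[order(out$rank), ]
}

#' Annotate SacII sites with genomic region classes
#'
#' Each site receives one region class with precedence
#' promoter > 5'UTR > exon > intron > intergenic. The promoter is
#' `[TSS - 2000, TSS + 500)` on the annotated strand of each transcript;
#' introns are transcript spans not covered by exons. Sites on contigs
#' absent from the annotation are intergenic (warned).
#'
#' @param sites Site table from [enumerate_sacii_sites()].
#' @param annotation A GFF3/BED path (imported with rtracklayer), a
#'   [GenomicRanges::GRanges], or a data.frame with columns chrom, start,
#'   end (1-based closed), strand, type (`transcript`/`mRNA`/`gene`,
#'   `exon`, `five_prime_UTR`).
#' @param promoter_upstream,promoter_downstream Promoter window around the
#'   TSS, in bp.
#' @return List: `per_site` (data.frame site_id, region) and
#'   `distribution` (data.frame region, n, pct).
#' @export
annotate_regions <- function(sites, annotation,
                             promoter_upstream = 2000L,
                             promoter_downstream = 500L) {
  gr <- annotation_as_granges(annotation)
  type <- tolower(as.character(gr$type))
  tx <- gr[type %in% c("transcript", "mrna", "gene")]
  exons <- gr[type == "exon"]
  utr5 <- gr[type %in% c("five_prime_utr", "5utr")]
  if (length(tx) == 0L) stop("annotation contains no transcript features")
  promoters <- GenomicRanges::promoters(tx, upstream = promoter_upstream,
                                        downstream = promoter_downstream)
  site_gr <- sites_as_granges(sites)
  ann_chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (!all(unique(sites$chrom) %in% ann_chroms))
    warning("sites on contigs absent from the annotation are intergenic")
  hits <- function(subject) {
    suppressWarnings(
      GenomicRanges::countOverlaps(site_gr, subject, ignore.strand = TRUE) > 0)
  }
  region <- rep("intergenic", nrow(sites))
  region[hits(tx)] <- "intron"  # refined by exon/UTR/promoter below
  region[hits(exons)] <- "exon"
  region[hits(utr5)] <- "five_prime_UTR"
  region[hits(promoters)] <- "promoter"
  lev <- c("promoter", "five_prime_UTR", "exon", "intron", "intergenic")
  dist <- as.data.frame(table(region = factor(region, levels = lev)),
                        responseName = "n")
  dist$pct <- 100 * dist$n / sum(dist$n)
  list(per_site = data.frame(site_id = sites$site_id, region = region,
                             stringsAsFactors = FALSE),
       distribution = dist)
}

annotation_as_granges <- function(annotation) {
  if (methods::is(annotation, "GRanges")) return(annotation)
  if (is.character(annotation) && length(annotation) == 1L) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("rtracklayer is required to import annotation files")
    return(rtracklayer::import(annotation))
  }
  if (is.data.frame(annotation)) {
    gr <- GenomicRanges::GRanges(
      seqnames = annotation$chrom,
      ranges = IRanges::IRanges(annotation$start, annotation$end),
      strand = annotation$strand)
    gr$type <- annotation$type
    return(gr)
  }
  stop("unsupported annotation input")
}

#' PCA batch-effect screen
#'
#' Principal components of the feature-centered normalized matrix;
#' per-sample outlier flags where PC1 exceeds a configurable threshold,
#' and a batch-association screen (one-way ANOVA of each of the top
#' components against batch).
#'
#' @param x Samples x sites normalized matrix.
#' @param batch Batch label per sample.
#' @param pc1_outlier_threshold Flag samples with PC1 above this value
#'   (default `Inf`: no outliers; any cutoff is data-specific).
#' @param k Number of components to return (capped by the matrix rank).
#' @return List: `coords` (samples x k), `outliers` (logical),
#'   `batch_anova` (data.frame component, p).
#' @export
pca_batch_check <- function(x, batch, pc1_outlier_threshold = Inf, k = 3L) {
  x <- as.matrix(x)
  k <- min(k, nrow(x) - 1L, ncol(x))
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  coords <- pc$x[, seq_len(k), drop = FALSE]
  outliers <- coords[, 1L] > pc1_outlier_threshold
  batch <- factor(batch)
  anova_p <- vapply(seq_len(k), function(j) {
    if (nlevels(batch) < 2L) return(NA_real_)
    fit <- aov(coords[, j] ~ batch)
    summary(fit)[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  list(coords = coords, outliers = outliers,
       batch_anova = data.frame(component = paste0("PC", seq_len(k)),
                                p = anova_p))
}

#' Screen cancer scores against clinical covariates
#'
#' Pearson correlation (with P) of the mean cancer score against each
#' numeric covariate; a two-sided two-group t test per 2-level categorical
#' covariate (one-way ANOVA if more levels); optionally a multivariable
#' linear model of score on all covariates.
#'
#' @param scores Mean cancer scores.
#' @param metadata data.frame of covariates (rows match `scores`).
#' @param multivariable Also fit `score ~ .` and return the coefficient
#'   table.
#' @return List: `associations` (covariate, type, estimate, p) and
#'   optionally `lm_coefficients`.
#' @export
confounder_screen <- function(scores, metadata, multivariable = FALSE) {
  stopifnot(nrow(metadata) == length(scores))
  rows <- lapply(names(metadata), function(nm) {
    v <- metadata[[nm]]
    if (is.numeric(v)) {
      if (sd(v) == 0 || all(is.na(v)))
        return(data.frame(covariate = nm, type = "pearson",
                          estimate = NA_real_, p = NA_real_))
      ct <- cor.test(scores, v, method = "pearson")
      data.frame(covariate = nm, type = "pearson",
                 estimate = unname(ct$estimate), p = ct$p.value)
    } else {
      f <- factor(v)
      if (nlevels(f) < 2L)
        return(data.frame(covariate = nm, type = "t_test",
                          estimate = NA_real_, p = NA_real_))
      if (nlevels(f) == 2L) {
        tt <- t.test(scores ~ f, var.equal = TRUE)
        data.frame(covariate = nm, type = "t_test",
                   estimate = unname(diff(rev(tt$estimate))), p = tt$p.value)
      } else {
        fit <- aov(scores ~ f)
        data.frame(covariate = nm, type = "anova", estimate = NA_real_,
                   p = summary(fit)[[1]][["Pr(>F)"]][1])
      }
    }
  })
  out <- list(associations = do.call(rbind, rows))
  if (multivariable) {
    fit <- lm(scores ~ ., data = metadata)
    out$lm_coefficients <- as.data.frame(summary(fit)$coefficients)
  }
  out
}
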