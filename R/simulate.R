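# Synthetic cohort generator. The generative model encodes the structure the
# classifier relies on: cancer genomes are globally hypomethylated relative to
# controls, each cancer class additionally loses methylation at its own set of
# marker sites, and a plasma sample is a tumor-fraction mixture of tumor and
# normal cfDNA. Depth at a SacII site reports the unmethylated fraction, since
# only unmethylated sites are cut and ligated.

#' Default per-class configuration for the methylation atlas
#'
#' Controls draw per-site methylation from Beta(8, 2) (mostly methylated CpG
#' islands, mean 0.8). Each cancer class applies a global hypomethylation
#' shift `delta` and forces its class-specific demethylated site set down to
#' Beta(1, 9) (mean 0.1). The two cancer classes' demethylated sets are
#' disjoint by construction so that cancer-type separation (cancer signal
#' origin) is identifiable.
#'
#' @param n_demethylated Number of class-specific demethylated sites per
#'   cancer class.
#' @param delta Global hypomethylation shift subtracted from every site's
#'   methylation probability (clipped at 0).
#' @return Named list of per-class configs usable by
#'   [build_methylation_atlas()].
#' @export
default_class_config <- function(n_demethylated = 50L, delta = 0.15) {
  list(
    control = list(beta_shape1 = 8, beta_shape2 = 2),
    crc     = list(delta = delta, n_demethylated = n_demethylated,
                   demeth_shape1 = 1, demeth_shape2 = 9),
    lung    = list(delta = delta, n_demethylated = n_demethylated,
                   demeth_shape1 = 1, demeth_shape2 = 9)
  )
}

#' Build a per-class, per-site methylation atlas
#'
#' The atlas is a `classes x sites` matrix of methylation probabilities.
#' The control row is drawn per site from the configured Beta distribution;
#' each cancer row copies the control row, subtracts its global shift
#' `delta` (clipped at 0), and sets its class-specific demethylated subset
#' to low methylation. Demethylated subsets of distinct cancer classes are
#' disjoint (sampled without replacement from the site universe).
#'
#' @param n_sites Number of sites (columns).
#' @param class_config As from [default_class_config()]; first entry must be
#'   the control class with Beta parameters, remaining entries cancer
#'   classes with `delta`, `n_demethylated`, and demethylated-set Beta
#'   parameters.
#' @param seed Integer seed; the atlas is deterministic given the seed.
#' @return List with `m` (matrix, rownames = classes), `demethylated_sites`
#'   (named list of column indices per cancer class), `delta` (named vector).
#' @export
build_methylation_atlas <- function(n_sites, class_config = default_class_config(),
                                    seed = 1L) {
  stopifnot(n_sites >= 1L)
  classes <- names(class_config)
  if (length(classes) < 1L || classes[1] != "control")
    stop("class_config must start with a 'control' entry")
  cancer_classes <- classes[-1]
  for (cl in cancer_classes) {
    cfg <- class_config[[cl]]
    if (cfg$delta < 0 || cfg$delta > 1)
      stop("config error: delta for class '", cl, "' must be in [0,1]")
    if (cfg$n_demethylated < 0 || cfg$n_demethylated > n_sites)
      stop("config error: n_demethylated for class '", cl,
           "' must be in [0, n_sites]")
  }
  set.seed(seed)
  ctrl_cfg <- class_config$control
  m_control <- rbeta(n_sites, ctrl_cfg$beta_shape1, ctrl_cfg$beta_shape2)
  m <- matrix(NA_real_, nrow = length(classes), ncol = n_sites,
              dimnames = list(classes, NULL))
  m["control", ] <- m_control
  # disjoint demethylated subsets across cancer classes
  pool <- sample.int(n_sites)
  offset <- 0L
  demeth <- list()
  for (cl in cancer_classes) {
    cfg <- class_config[[cl]]
    k <- as.integer(cfg$n_demethylated)
    if (offset + k > n_sites)
      stop("config error: demethylated sets exceed site universe")
    idx <- sort(pool[seq_len(k) + offset])
    offset <- offset + k
    row <- pmax(m_control - cfg$delta, 0)
    if (k > 0L)
      row[idx] <- rbeta(k, cfg$demeth_shape1, cfg$demeth_shape2)
    m[cl, ] <- row
    demeth[[cl]] <- idx
  }
  stopifnot(all(m >= 0 & m <= 1))
  list(m = m,
       demethylated_sites = demeth,
       delta = vapply(cancer_classes, function(cl) class_config[[cl]]$delta,
                      numeric(1)))
}

#' Default library configuration
#'
#' Mirrors the stated library design: 10 bp UMIs, paired-end 100 bp reads,
#' and 200-550 bp size selection. Mean on-target site depth, off-target
#' rate, PCR duplication and sequencing error are generator assumptions.
#'
#' @param mean_site_depth Expected deduplicated molecule count at a fully
#'   unmethylated site.
#' @param off_target_rate Expected off-target molecules per site slot, as a
#'   fraction of `mean_site_depth`.
#' @param umi_length UMI length in bp.
#' @param pcr_duplication_mean Mean reads emitted per molecule (>= 1).
#' @param seq_error_rate Per-base substitution error rate.
#' @param fragment_min,fragment_max Size-selection window in bp.
#' @param read_length Read length in bp.
#' @return Validated list of parameters.
#' @export
library_config <- function(mean_site_depth = 30,
                           off_target_rate = 0.05,
                           umi_length = 10L,
                           pcr_duplication_mean = 2,
                           seq_error_rate = 0.001,
                           fragment_min = 200L,
                           fragment_max = 550L,
                           read_length = 100L) {
  stopifnot(mean_site_depth > 0,
            off_target_rate >= 0, off_target_rate < 1,
            pcr_duplication_mean >= 1,
            seq_error_rate >= 0, seq_error_rate < 1,
            fragment_min < fragment_max,
            read_length >= 4L)
  list(mean_site_depth = mean_site_depth,
       off_target_rate = off_target_rate,
       umi_length = as.integer(umi_length),
       pcr_duplication_mean = pcr_duplication_mean,
       seq_error_rate = seq_error_rate,
       fragment_min = as.integer(fragment_min),
       fragment_max = as.integer(fragment_max),
       read_length = as.integer(read_length))
}

#' Simulate raw site depths for one sample
#'
#' Per-site cut probability is the tumor-fraction mixture
#' `p = (1 - tf) * (1 - m[control, s]) + tf * (1 - m[class, s])`;
#' the deduplicated depth is drawn Poisson with mean
#' `mean_site_depth * p`, plus a Poisson off-target background with mean
#' `mean_site_depth * off_target_rate` at every site.
#'
#' @param atlas From [build_methylation_atlas()].
#' @param truth_class Class label present in the atlas.
#' @param tumor_fraction Tumor fraction in [0, 1] (0 for controls).
#' @param lib From [library_config()].
#' @param seed Integer seed.
#' @return Integer vector of per-site depths.
#' @export
simulate_sample_depths <- function(atlas, truth_class, tumor_fraction, lib,
                                   seed) {
  if (!truth_class %in% rownames(atlas$m))
    stop("unknown class '", truth_class, "'; atlas classes: ",
         paste(rownames(atlas$m), collapse = ", "))
  stopifnot(tumor_fraction >= 0, tumor_fraction <= 1)
  set.seed(seed)
  tf <- tumor_fraction
  p_cut <- (1 - tf) * (1 - atlas$m["control", ]) +
    tf * (1 - atlas$m[truth_class, ])
  depth <- rpois(length(p_cut), lib$mean_site_depth * p_cut) +
    rpois(length(p_cut), lib$mean_site_depth * lib$off_target_rate)
  as.integer(depth)
}

#' Plan a synthetic cohort
#'
#' Stages map to tumor-fraction ranges with stage I lowest, so detectability
#' increases with stage. Ages, sexes and batches are drawn independently of
#' class so they are null covariates by construction.
#'
#' @param n_control,n_crc,n_lung Per-class sample counts.
#' @param tf_by_stage Named list of `c(min, max)` tumor-fraction ranges for
#'   stages I-IV.
#' @param stage_probs Probability of each stage among cancer samples.
#' @param n_batches Number of sequencing batches.
#' @return A `cohort_plan` list.
#' @export
cohort_plan <- function(n_control = 126L, n_crc = 96L, n_lung = 95L,
                        tf_by_stage = list(I = c(0.05, 0.15),
                                           II = c(0.10, 0.25),
                                           III = c(0.20, 0.45),
                                           IV = c(0.35, 0.70)),
                        stage_probs = c(I = 0.25, II = 0.25,
                                        III = 0.3, IV = 0.2),
                        n_batches = 4L) {
  structure(list(n = c(control = as.integer(n_control),
                       crc = as.integer(n_crc),
                       lung = as.integer(n_lung)),
                 tf_by_stage = tf_by_stage,
                 stage_probs = stage_probs,
                 n_batches = as.integer(n_batches)),
            class = "cohort_plan")
}

#' Simulate a cohort: metadata table and raw depth matrix
#'
#' One metadata row and one depth vector per sample, fully reproducible
#' given the seed. Controls have tumor fraction 0 and no stage; cancer
#' samples draw a stage, then a tumor fraction uniform in that stage's
#' range. Subtypes are assigned at random within each cancer class
#' (left/right colon for colorectal; LUAD/LUSC/SCLC for lung).
#'
#' @param atlas From [build_methylation_atlas()].
#' @param plan From [cohort_plan()]; classes with zero samples are dropped.
#' @param lib From [library_config()].
#' @param seed Integer master seed.
#' @param site_ids Optional site id vector for matrix column names.
#' @return List with `depth` (samples x sites integer matrix) and
#'   `metadata` (data.frame: sample_id, truth_class, stage, subtype,
#'   tumor_fraction, age, sex, batch_id).
#' @export
simulate_cohort <- function(atlas, plan = cohort_plan(), lib = library_config(),
                            seed = 1L, site_ids = NULL) {
  n <- plan$n[plan$n > 0L]
  if (length(n) == 0L) stop("empty cohort plan")
  if (!all(names(n) %in% rownames(atlas$m)))
    stop("plan classes missing from atlas: ",
         paste(setdiff(names(n), rownames(atlas$m)), collapse = ", "))
  set.seed(seed)
  stages <- names(plan$tf_by_stage)
  subtype_pool <- list(crc = c("left_colon", "right_colon"),
                       lung = c("LUAD", "LUSC", "SCLC"))
  rows <- list()
  for (cl in names(n)) {
    for (i in seq_len(n[[cl]])) {
      if (cl == "control") {
        stage <- NA_character_; tf <- 0; subtype <- NA_character_
      } else {
        stage <- sample(stages, 1L, prob = plan$stage_probs)
        rg <- plan$tf_by_stage[[stage]]
        tf <- runif(1L, rg[1], rg[2])
        pool <- subtype_pool[[cl]]
        subtype <- if (is.null(pool)) NA_character_ else sample(pool, 1L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_%03d", cl, i),
        truth_class = cl, stage = stage, subtype = subtype,
        tumor_fraction = tf,
        age = round(runif(1L, 35, 85)),
        sex = sample(c("M", "F"), 1L),
        batch_id = sprintf("batch%02d", sample.int(plan$n_batches, 1L)),
        stringsAsFactors = FALSE)
    }
  }
  metadata <- do.call(rbind, rows)
  sample_seeds <- sample.int(.Machine$integer.max, nrow(metadata))
  n_sites <- ncol(atlas$m)
  depth <- matrix(0L, nrow = nrow(metadata), ncol = n_sites,
                  dimnames = list(metadata$sample_id,
                                  site_ids %||% paste0("site_", seq_len(n_sites))))
  for (i in seq_len(nrow(metadata))) {
    depth[i, ] <- simulate_sample_depths(atlas, metadata$truth_class[i],
                                         metadata$tumor_fraction[i], lib,
                                         seed = sample_seeds[i])
  }
  list(depth = depth, metadata = metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
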