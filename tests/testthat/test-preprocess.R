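make_reads <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    defaults <- list(read_id = "r", seq1 = strrep("A", 100),
                     seq2 = paste0("ACGTACGTAC", strrep("A", 90)),
                     qual2 = strrep("I", 100), umi = "ACGTACGTAC",
                     chrom = "chrT", pos = 3L)
    defaults[names(r)] <- r
    as.data.frame(defaults, stringsAsFactors = FALSE)
  }))
}

test_that("QC drops short, single-end, and bad-UMI reads with reasons", {
  reads <- make_reads(
    list(read_id = "ok"),
    list(read_id = "short1", seq1 = strrep("A", 19)),
    list(read_id = "single", seq2 = NA_character_, qual2 = NA_character_),
    list(read_id = "umiN", umi = "ACGTNACGTA"),
    list(read_id = "umiQ0", qual2 = paste0("II!II", strrep("I", 95))),
    list(read_id = "noumi", umi = NA_character_))
  res <- qc_filter_reads(reads)
  expect_identical(res$reads$read_id, "ok")
  expect_equal(res$report$short, 1L)
  expect_equal(res$report$single_end, 1L)
  expect_equal(res$report$umi_N, 1L)
  expect_equal(res$report$umi_Q0, 1L)
  expect_equal(res$report$no_umi, 1L)
  expect_equal(res$report$kept, 1L)
  expect_equal(res$report$total, 6L)
})

test_that("reads are assigned to sites only at the exact cut position", {
  sites <- enumerate_sacii_sites(c(chrT = "ACCGCGGT"))  # motif_start 1, cut 3
  reads <- make_reads(list(read_id = "hit", pos = 3L),
                      list(read_id = "off", pos = 4L))
  out <- assign_reads_to_sites(reads, sites)
  expect_equal(out$site_id[out$read_id == "hit"], "chrT:1")
  expect_equal(out$site_id[out$read_id == "off"], "background")

  alien <- make_reads(list(read_id = "alien", chrom = "chrZ", pos = 3L))
  expect_warning(out2 <- assign_reads_to_sites(alien, sites), "background")
  expect_equal(out2$site_id, "background")
})

test_that("directional UMI clustering matches the exhaustive oracle", {
  # exact duplicate
  expect_equal(cluster_umis_directional(rep("ACGTACGTAC", 2))$n_molecules, 1L)
  # one-off error absorbed by a 10x parent
  umis <- c(rep("AAAAAAAAAA", 10), "AAAAAAAAAT")
  expect_equal(cluster_umis_directional(umis)$n_molecules, 1L)
  expect_equal(oracle_directional_clusters(umis), 1L)
  # distance 10: two molecules
  umis2 <- c(rep("AAAAAAAAAA", 5), rep("TTTTTTTTTT", 5))
  expect_equal(cluster_umis_directional(umis2)$n_molecules, 2L)
  # balanced counts at distance 1 must NOT merge (5 < 2*5 - 1)
  umis3 <- c(rep("AAAAAAAAAA", 5), rep("AAAAAAAAAT", 5))
  expect_equal(cluster_umis_directional(umis3)$n_molecules,
               oracle_directional_clusters(umis3))
  expect_equal(cluster_umis_directional(umis3)$n_molecules, 2L)

  # random UMI pools vs oracle, crossing the small-group fast path boundary
  set.seed(42)
  for (rep_i in 1:20) {
    pool <- mreseq:::random_umis(sample(3:20, 1), 10L)
    counts <- sample(1:6, length(pool), replace = TRUE)
    # perturb some UMIs by one base to create mergeable errors
    errd <- pool
    flip <- sample(seq_along(pool), max(1, length(pool) %/% 3))
    for (i in flip) {
      p <- sample(10L, 1)
      substr(errd[i], p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    umis <- c(rep(pool, counts), errd)
    expect_equal(cluster_umis_directional(umis)$n_molecules,
                 oracle_directional_clusters(umis))
  }
})

test_that("on-target classification uses the GCGG 5' signature", {
  expect_true(classify_on_target("GCGGATTT"))
  expect_false(classify_on_target("ACGGATTT"))
  expect_false(classify_on_target("GCG"))
  mol <- data.frame(seq1 = c("GCGGAAAA", "GCGGTTTT", "TTTTTTTT"))
  expect_equal(on_target_ratio(mol), 2 / 3)
})

test_that("on-target ratio tracks the generator's off-target rate", {
  genome <- planted_genome(30L, seed = 23L)
  sites <- enumerate_sacii_sites(genome)
  atlas <- build_methylation_atlas(nrow(sites), default_class_config(
    n_demethylated = 4L), seed = 2L)
  lib0 <- library_config(mean_site_depth = 8, off_target_rate = 0,
                         seq_error_rate = 0)
  sim0 <- simulate_reads(atlas, "control", 0, genome, sites, lib0, seed = 3L,
                         out_prefix = tempfile())
  pp0 <- preprocess_sample(sim0$r1, sim0$r2, sites, truth_tsv = sim0$truth_tsv)
  expect_equal(pp0$on_target_ratio, 1.0)

  lib_r <- library_config(mean_site_depth = 8, off_target_rate = 0.3,
                          seq_error_rate = 0)
  sim_r <- suppressWarnings(
    simulate_reads(atlas, "control", 0, genome, sites, lib_r, seed = 5L,
                   out_prefix = tempfile()))
  pp_r <- preprocess_sample(sim_r$r1, sim_r$r2, sites, truth_tsv = sim_r$truth_tsv)
  # expected on-target fraction = E[on] / (E[on] + E[off]); off molecules
  # rarely start with GCGG by chance, binomial tolerance applies
  p_cut <- 1 - atlas$m["control", ]
  e_on <- sum(lib_r$mean_site_depth * p_cut)
  e_off <- lib_r$mean_site_depth * lib_r$off_target_rate * nrow(sites)
  expected <- e_on / (e_on + e_off)
  n_mol <- sim_r$n_molecules
  tol <- 4 * sqrt(expected * (1 - expected) / n_mol) + 0.01
  expect_lt(abs(pp_r$on_target_ratio - expected), tol)
})

test_that("trimmed mean follows the sort-and-slice definition", {
  expect_equal(trimmed_mean_normalize(rep(10, 100))$trimmed_mean, 10)
  expect_equal(trimmed_mean_normalize(rep(10, 100))$normalized, rep(1, 100))
  # n = 20: floor(1) lowest and highest excluded -> mean(2..19) = 10.5
  r <- trimmed_mean_normalize(1:20)
  expect_equal(r$trimmed_mean, 10.5)
  expect_equal(r$normalized, (1:20) / 10.5)
  # a single extreme outlier is excluded, unlike the plain mean
  row <- c(rep(10, 99), 1e6)
  expect_equal(trimmed_mean_normalize(row)$trimmed_mean, 10)

  expect_error(trimmed_mean_normalize(rep(0, 50)), "degenerate")
  expect_warning(r5 <- trimmed_mean_normalize(c(1, 2, 3, 4, 5)), "plain mean")
  expect_equal(r5$trimmed_mean, 3)
})

test_that("trimmed-mean normalization is scale-invariant and bounded", {
  set.seed(77)
  for (i in 1:10) {
    row <- rpois(60, 20)
    row[row == 0] <- 1
    tm <- trimmed_mean_normalize(row)
    expect_gte(tm$trimmed_mean, min(row))
    expect_lte(tm$trimmed_mean, max(row))
    c_scale <- runif(1, 0.5, 5)
    expect_equal(trimmed_mean_normalize(row * c_scale)$normalized,
                 tm$normalized)
  }
})

test_that("depth matrix assembles, recomputes, and preprocessing is idempotent", {
  set.seed(5)
  raw <- matrix(rpois(36, 30) + 1L, 3, 12,
                dimnames = list(paste0("s", 1:3), paste0("site_", 1:12)))
  dm <- build_depth_matrix(raw)
  for (i in 1:3)
    expect_equal(dm$normalized[i, ], raw[i, ] / dm$trimmed_mean[i])
  expect_true(all(dm$coverage >= 0 & dm$coverage <= 1))

  # FASTQ path equals direct path for the same seed without errors
  genome <- planted_genome(25L, seed = 31L)
  sites <- enumerate_sacii_sites(genome)
  atlas <- build_methylation_atlas(nrow(sites), default_class_config(
    n_demethylated = 3L), seed = 3L)
  lib <- library_config(mean_site_depth = 10, off_target_rate = 0,
                        seq_error_rate = 0, pcr_duplication_mean = 2)
  sim <- simulate_reads(atlas, "crc", 0.4, genome, sites, lib, seed = 19L,
                        out_prefix = tempfile())
  pp <- preprocess_sample(sim$r1, sim$r2, sites, truth_tsv = sim$truth_tsv)
  direct <- simulate_sample_depths(atlas, "crc", 0.4, lib, seed = 19L)
  expect_identical(unname(pp$site_depths), direct)
  # dedup never increases counts
  expect_lte(sum(pp$site_depths), sim$n_reads)
  # idempotence
  pp2 <- preprocess_sample(sim$r1, sim$r2, sites, truth_tsv = sim$truth_tsv)
  expect_identical(pp, pp2)
})

test_that("positions can come from an external alignment file", {
  skip_if_not_installed("Rsamtools")
  genome <- planted_genome(10L, seed = 37L)
  sites <- enumerate_sacii_sites(genome)
  atlas <- build_methylation_atlas(nrow(sites), default_class_config(
    n_demethylated = 2L), seed = 5L)
  lib <- library_config(mean_site_depth = 6, off_target_rate = 0,
                        seq_error_rate = 0)
  sim <- simulate_reads(atlas, "control", 0, genome, sites, lib, seed = 7L,
                        out_prefix = tempfile())
  # write a SAM encoding the truth coordinates, as an aligner would
  truth <- sim$truth
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:chrP\tLN:", nchar(genome[["chrP"]])),
    sprintf("%s\t0\t%s\t%d\t60\t100M\t*\t0\t0\t*\t*",
            truth$read_id, truth$chrom, truth$pos + 1L)), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  pp_bam <- preprocess_sample(sim$r1, sim$r2, sites, bam = bam)
  pp_truth <- preprocess_sample(sim$r1, sim$r2, sites,
                                truth_tsv = sim$truth_tsv)
  expect_identical(pp_bam$site_depths, pp_truth$site_depths)
})
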