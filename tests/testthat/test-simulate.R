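test_that("atlas respects null, saturation, and hypomethylation structure", {
  cfg0 <- list(control = list(beta_shape1 = 8, beta_shape2 = 2),
               crc = list(delta = 0, n_demethylated = 0L,
                          demeth_shape1 = 1, demeth_shape2 = 9))
  a0 <- build_methylation_atlas(100L, cfg0, seed = 5L)
  expect_identical(a0$m["crc", ], a0$m["control", ])

  cfg1 <- cfg0
  cfg1$crc$delta <- 1
  a1 <- build_methylation_atlas(100L, cfg1, seed = 5L)
  expect_true(all(a1$m["crc", ] == 0))

  a <- build_methylation_atlas(1000L, default_class_config(delta = 0.15),
                               seed = 7L)
  expect_lt(mean(a$m["crc", ]), mean(a$m["control", ]))
  # the global shift plus the demethylated subset account for the gap
  gap <- mean(a$m["control", ]) - mean(a$m["crc", ])
  expect_gt(gap, 0.1)
  # deterministic given seed
  a2 <- build_methylation_atlas(1000L, default_class_config(delta = 0.15),
                                seed = 7L)
  expect_identical(a$m, a2$m)
  # CSO separability: the cancer classes' demethylated sets differ
  expect_false(setequal(a$demethylated_sites$crc, a$demethylated_sites$lung))

  bad <- default_class_config()
  bad$crc$delta <- 1.5
  expect_error(build_methylation_atlas(100L, bad), "config error")
})

test_that("depth model honors mixture endpoints and closed-form mean", {
  atlas <- build_methylation_atlas(200L, default_class_config(), seed = 3L)
  lib <- library_config()
  d_tf0 <- simulate_sample_depths(atlas, "crc", 0, lib, seed = 9L)
  d_ctl <- simulate_sample_depths(atlas, "control", 0, lib, seed = 9L)
  expect_identical(d_tf0, d_ctl)

  sat <- list(m = rbind(control = rep(1, 50), crc = rep(1, 50)))
  lib0 <- library_config(off_target_rate = 0)
  expect_true(all(simulate_sample_depths(sat, "crc", 0.5, lib0, 1L) == 0))

  expect_error(simulate_sample_depths(atlas, "breast", 0.1, lib, 1L),
               "unknown class")

  # closed form: m_control = 0.2, m_crc = 0, tf = 0.5, D = 100 -> mean 90
  one <- list(m = rbind(control = 0.2, crc = 0))
  libm <- library_config(mean_site_depth = 100, off_target_rate = 0)
  draws <- vapply(seq_len(10000L), function(s)
    simulate_sample_depths(one, "crc", 0.5, libm, seed = s), integer(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 90), 3 * se)
})

test_that("expected depth at a demethylated site is monotone in tumor fraction", {
  one <- list(m = rbind(control = 0.9, crc = 0.05))
  lib <- library_config(mean_site_depth = 60, off_target_rate = 0)
  mean_at_tf <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(tf) {
    mean(vapply(seq_len(2000L), function(s)
      simulate_sample_depths(one, "crc", tf, lib, seed = 40000L + s),
      integer(1)))
  }, numeric(1))
  expect_true(all(diff(mean_at_tf) > 0))
})

test_that("depth totals scale linearly with configured mean depth", {
  atlas <- build_methylation_atlas(500L, default_class_config(), seed = 13L)
  totals <- vapply(c(10, 20, 40), function(D) {
    lib <- library_config(mean_site_depth = D)
    mean(vapply(1:20, function(s)
      sum(simulate_sample_depths(atlas, "control", 0, lib, seed = s)),
      numeric(1)))
  }, numeric(1))
  expect_equal(totals[2] / totals[1], 2, tolerance = 0.05)
  expect_equal(totals[3] / totals[2], 2, tolerance = 0.05)
})

test_that("cohort simulation reproduces the plan and is seed-deterministic", {
  atlas <- build_methylation_atlas(50L, default_class_config(n_demethylated = 5L),
                                   seed = 2L)
  plan <- cohort_plan(n_control = 126L, n_crc = 96L, n_lung = 95L)
  co <- simulate_cohort(atlas, plan, library_config(), seed = 8L)
  expect_equal(nrow(co$metadata), 317L)
  expect_equal(as.vector(table(co$metadata$truth_class)[c("control", "crc", "lung")]),
               c(126L, 96L, 95L))
  # controls: tf 0 and no stage; cancers: stage present
  ctl <- co$metadata$truth_class == "control"
  expect_true(all(co$metadata$tumor_fraction[ctl] == 0))
  expect_true(all(is.na(co$metadata$stage[ctl])))
  expect_true(all(!is.na(co$metadata$stage[!ctl])))

  co2 <- simulate_cohort(atlas, plan, library_config(), seed = 8L)
  expect_identical(co$depth, co2$depth)
  co3 <- simulate_cohort(atlas, plan, library_config(), seed = 9L)
  expect_false(identical(co$depth, co3$depth))

  expect_error(simulate_cohort(atlas, cohort_plan(0L, 0L, 0L)), "empty")
})

test_that("read simulator honors cut signature, duplication, and truth log", {
  genome <- planted_genome(40L, seed = 17L)
  sites <- enumerate_sacii_sites(genome)
  atlas <- build_methylation_atlas(nrow(sites), default_class_config(
    n_demethylated = 5L), seed = 1L)
  lib <- library_config(mean_site_depth = 5, seq_error_rate = 0,
                        off_target_rate = 0, pcr_duplication_mean = 1)
  sim <- simulate_reads(atlas, "crc", 0.3, genome, sites, lib, seed = 4L,
                        out_prefix = tempfile("sim_"))
  # pcr_duplication_mean = 1: reads == molecules
  expect_equal(sim$n_reads, sim$n_molecules)
  # with no sequencing error every on-target read 1 starts with GCGG
  r1 <- readLines(sim$r1)
  seqs <- r1[seq(2, length(r1), by = 4)]
  on_target <- sim$truth$site_id != "background"
  expect_true(all(substr(seqs[on_target], 1, 4) == "GCGG"))

  # per-site molecule counts in the truth TSV match an independent tally
  lib2 <- library_config(mean_site_depth = 5, pcr_duplication_mean = 2,
                         off_target_rate = 0.05)
  sim2 <- suppressWarnings(
    simulate_reads(atlas, "crc", 0.3, genome, sites, lib2, seed = 6L,
                   out_prefix = tempfile("sim_")))
  truth <- read.delim(sim2$truth_tsv, stringsAsFactors = FALSE)
  tally <- tapply(truth$molecule_id, truth$site_id,
                  function(m) length(unique(m)))
  recount <- tapply(sim2$truth$molecule_id, sim2$truth$site_id,
                    function(m) length(unique(m)))
  expect_equal(tally, recount)
  expect_equal(sum(tally), sim2$n_molecules)
})
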