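# Shared fixtures and independent oracles, all built in code at test time.

random_sequence <- function(len, seed) {
  set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# independent brute-force oracle: O(n * 6) sliding-window motif scan
naive_motif_positions <- function(seq, motif = "CCGCGG") {
  L <- nchar(motif)
  n <- nchar(seq)
  if (n < L) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - L + 1L)) {
    if (substr(seq, i, i + L - 1L) == motif) hits <- c(hits, i - 1L)
  }
  hits
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# independent oracle for directional UMI clustering: explicit distance
# matrix plus the same merge rule, no bucketing
oracle_directional_clusters <- function(umis) {
  counts <- table(umis)
  uniq <- names(counts)
  cnt <- as.integer(counts)
  n <- length(uniq)
  if (n == 0L) return(0L)
  dist <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dist[i, j] <- sum(strsplit(uniq[i], "")[[1]] != strsplit(uniq[j], "")[[1]])
  }
  assigned <- rep(FALSE, n)
  k <- 0L
  for (i in order(-cnt)) {
    if (assigned[i]) next
    k <- k + 1L
    frontier <- i
    assigned[i] <- TRUE
    while (length(frontier) > 0L) {
      u <- frontier[1L]; frontier <- frontier[-1L]
      for (v in seq_len(n)) {
        if (!assigned[v] && dist[u, v] <= 1L && cnt[u] >= 2L * cnt[v] - 1L) {
          assigned[v] <- TRUE
          frontier <- c(frontier, v)
        }
      }
    }
  }
  k
}

# genome with motifs planted at regular spacing (plus incidental random
# hits, which enumeration discovers); spacing > fragment_max so simulated
# fragments fit
planted_genome <- function(n_planted, spacer = 700L, seed = 1L) {
  set.seed(seed)
  chunks <- character(n_planted)
  for (i in seq_len(n_planted)) {
    chunks[i] <- paste0(
      paste0(sample(c("A", "C", "G", "T"), spacer, replace = TRUE),
             collapse = ""),
      "CCGCGG")
  }
  c(chrP = paste0(paste0(chunks, collapse = ""),
                  strrep("A", 600L)))
}

# small two-class cohort matrix with a controlled class signal
toy_cohort <- function(n_per_class = 20L, n_sites = 30L, delta = 0.3,
                       tf_range = c(0.2, 0.6), seed = 1L,
                       depth = 50) {
  atlas <- build_methylation_atlas(
    n_sites,
    list(control = list(beta_shape1 = 8, beta_shape2 = 2),
         crc = list(delta = delta, n_demethylated = max(1L, n_sites %/% 10L),
                    demeth_shape1 = 1, demeth_shape2 = 9)),
    seed = seed)
  lib <- library_config(mean_site_depth = depth)
  set.seed(seed + 1L)
  seeds <- sample.int(1e6, 2L * n_per_class)
  tfs <- runif(n_per_class, tf_range[1], tf_range[2])
  raw <- matrix(0L, 2L * n_per_class, n_sites,
                dimnames = list(
                  c(sprintf("ctrl_%02d", seq_len(n_per_class)),
                    sprintf("crc_%02d", seq_len(n_per_class))),
                  paste0("site_", seq_len(n_sites))))
  for (i in seq_len(n_per_class)) {
    raw[i, ] <- simulate_sample_depths(atlas, "control", 0, lib, seeds[i])
    raw[n_per_class + i, ] <- simulate_sample_depths(
      atlas, "crc", tfs[i], lib, seeds[n_per_class + i])
  }
  dm <- build_depth_matrix(raw)
  list(x = dm$normalized, y = rep(0:1, each = n_per_class), atlas = atlas)
}

write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  close(con)
  path
}
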