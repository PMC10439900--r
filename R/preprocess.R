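# From reads (or raw counts) to the normalized site-depth matrix:
# QC filtering, site assignment, directional UMI deduplication, on-target
# classification, and trimmed-mean normalization.

#' QC-filter a read table
#'
#' Drops, in order of precedence: single-end reads (missing mate 2), reads
#' with either mate shorter than 20 bp, reads without a UMI, reads whose
#' UMI contains any `N`, and reads with any quality-0 base within the UMI
#' cycles of read 2 (phred `!` at ASCII offset 33).
#'
#' @param reads data.frame from [read_library()].
#' @param min_length Minimum mate length in bp.
#' @param umi_length UMI length in bp.
#' @return List with `reads` (kept rows) and `report` (named drop counts,
#'   plus `kept` and `total`).
#' @export
qc_filter_reads <- function(reads, min_length = 20L, umi_length = 10L) {
  reason <- rep(NA_character_, nrow(reads))
  single_end <- is.na(reads$seq2)
  reason[single_end] <- "single_end"
  short <- !single_end &
    (nchar(reads$seq1) < min_length | nchar(reads$seq2) < min_length)
  reason[is.na(reason) & short] <- "short"
  no_umi <- is.na(reads$umi) | nchar(reads$umi) != umi_length
  reason[is.na(reason) & no_umi] <- "no_umi"
  umi_n <- grepl("N", reads$umi, fixed = TRUE)
  reason[is.na(reason) & umi_n] <- "umi_N"
  umi_qual <- substr(reads$qual2, 1L, umi_length)
  umi_q0 <- !is.na(umi_qual) & grepl("!", umi_qual, fixed = TRUE)
  reason[is.na(reason) & umi_q0] <- "umi_Q0"
  keep <- is.na(reason)
  report <- as.list(table(factor(reason[!keep],
    levels = c("single_end", "short", "no_umi", "umi_N", "umi_Q0"))))
  report$kept <- sum(keep)
  report$total <- nrow(reads)
  list(reads = reads[keep, , drop = FALSE], report = report)
}

#' Assign reads to SacII sites by cut position
#'
#' A read belongs to site `s` iff its 5'-most base sits exactly at
#' `s$motif_start + s$cut_offset` on the same chromosome; all other reads
#' (including off-by-one positions and unknown contigs) fall into the
#' background pool.
#'
#' @param reads QC-passed read table (needs `chrom`, `pos`).
#' @param sites Site table.
#' @return `reads` with a `site_id` column (`"background"` when unassigned).
#' @export
assign_reads_to_sites <- function(reads, sites) {
  cut_key <- paste0(sites$chrom, ":", sites$motif_start + sites$cut_offset)
  read_key <- paste0(reads$chrom, ":", reads$pos)
  idx <- match(read_key, cut_key)
  unknown <- !is.na(reads$chrom) & !(reads$chrom %in% sites$chrom)
  if (any(unknown))
    warning(sum(unknown), " reads on contigs absent from the site table ",
            "pooled as background")
  reads$site_id <- ifelse(is.na(idx), "background", sites$site_id[idx])
  reads
}

hamming1_neighbors <- function(umis) {
  # adjacency (Hamming distance <= 1) among unique UMIs, as an index list;
  # UMIs sharing a sequence with one position wildcarded are neighbors
  n <- length(umis)
  adj <- replicate(n, integer(0), simplify = FALSE)
  if (n <= 1L) return(adj)
  L <- nchar(umis[1])
  if (n <= 12L) {
    # few UMIs: direct pairwise comparison is cheaper than bucketing
    mat <- matrix(unlist(strsplit(umis, ""), use.names = FALSE), nrow = L)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (sum(mat[, i] != mat[, j]) <= 1L) {
          adj[[i]] <- c(adj[[i]], j)
          adj[[j]] <- c(adj[[j]], i)
        }
      }
    }
    return(adj)
  }
  for (p in seq_len(L)) {
    key <- paste0(substr(umis, 1L, p - 1L), ".", substr(umis, p + 1L, L))
    for (grp in split(seq_len(n), key)) {
      if (length(grp) > 1L) {
        for (i in grp) adj[[i]] <- c(adj[[i]], grp[grp != i])
      }
    }
  }
  lapply(adj, unique)
}

#' Cluster UMIs at one site with the directional method
#'
#' Unique UMIs are nodes weighted by read count; a directed edge `u -> v`
#' exists when `Hamming(u, v) <= 1` and `count(u) >= 2 * count(v) - 1`.
#' Starting from the highest-count unvisited node, all nodes reachable
#' along directed edges are absorbed into one cluster (one original
#' molecule whose UMI accumulated sequencing/PCR errors).
#'
#' @param umis Character vector of UMIs (one entry per read).
#' @return List with `n_molecules` and `assignment` (cluster index per
#'   unique UMI, names = UMIs).
#' @export
cluster_umis_directional <- function(umis) {
  if (length(umis) == 0L)
    return(list(n_molecules = 0L, assignment = integer(0)))
  counts <- table(umis)
  uniq <- names(counts)
  cnt <- as.integer(counts)
  ord <- order(-cnt)
  adj <- hamming1_neighbors(uniq)
  cluster <- rep(NA_integer_, length(uniq))
  k <- 0L
  for (i in ord) {
    if (!is.na(cluster[i])) next
    k <- k + 1L
    queue <- i
    cluster[i] <- k
    while (length(queue) > 0L) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in adj[[u]]) {
        if (is.na(cluster[v]) && cnt[u] >= 2L * cnt[v] - 1L) {
          cluster[v] <- k
          queue <- c(queue, v)
        }
      }
    }
  }
  names(cluster) <- uniq
  list(n_molecules = k, assignment = cluster)
}

#' Deduplicate reads per site using UMIs
#'
#' Applies directional UMI clustering within each site group; the molecule
#' count at a site is its number of UMI clusters. The representative read
#' of a cluster is the first read carrying the cluster's highest-count UMI.
#'
#' @param reads Read table with `site_id` from [assign_reads_to_sites()].
#' @return List with `site_counts` (named integer vector of molecules per
#'   site, background excluded), `molecules` (data.frame of representative
#'   reads with site_id, umi, seq1), and `dedup_ratio` (total molecules /
#'   total reads, background included in both).
#' @export
deduplicate_umis <- function(reads) {
  if (nrow(reads) == 0L)
    return(list(site_counts = integer(0),
                molecules = data.frame(), dedup_ratio = NA_real_))
  groups <- split(seq_len(nrow(reads)), reads$site_id)
  mol_rows_list <- vector("list", length(groups))
  site_counts <- stats::setNames(integer(length(groups)), names(groups))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    umis <- reads$umi[rows]
    uniq <- unique(umis)
    if (length(uniq) == 1L) {
      site_counts[g] <- 1L
      mol_rows_list[[g]] <- rows[1L]
      next
    }
    cl <- cluster_umis_directional(umis)
    site_counts[g] <- cl$n_molecules
    cnt <- as.integer(table(umis)[names(cl$assignment)])
    # representative = first read with the cluster's most frequent UMI
    reps <- vapply(seq_len(cl$n_molecules), function(k) {
      members <- which(cl$assignment == k)
      top <- names(cl$assignment)[members[which.max(cnt[members])]]
      rows[match(top, umis)]
    }, integer(1))
    mol_rows_list[[g]] <- reps
  }
  mol_rows <- unlist(mol_rows_list, use.names = FALSE)
  molecules <- reads[mol_rows, c("read_id", "site_id", "umi", "seq1"),
                     drop = FALSE]
  total_molecules <- sum(site_counts)
  on_site <- setdiff(names(site_counts), "background")
  list(site_counts = site_counts[on_site],
       molecules = molecules,
       dedup_ratio = total_molecules / nrow(reads))
}

#' On-target classification of a molecule's genome-facing read
#'
#' A molecule is on-target iff the first four bases of read 1 are exactly
#' `GCGG`, the ligation signature of a SacII cut; reads shorter than 4 bp
#' are off-target.
#'
#' @param seq1 Character vector of read-1 sequences.
#' @return Logical vector.
#' @export
classify_on_target <- function(seq1) {
  !is.na(seq1) & nchar(seq1) >= 4L & substr(seq1, 1L, 4L) == "GCGG"
}

#' On-target ratio of a deduplicated sample
#'
#' @param molecules Representative-molecule table from
#'   [deduplicate_umis()].
#' @return On-target molecules / total molecules.
#' @export
on_target_ratio <- function(molecules) {
  if (nrow(molecules) == 0L) return(NA_real_)
  mean(classify_on_target(molecules$seq1))
}

#' Trimmed-mean normalization of a depth row
#'
#' The per-sample scaling factor is the mean depth over all sites after
#' excluding 10% outliers, implemented symmetrically: the `floor(0.05 n)`
#' lowest and `floor(0.05 n)` highest values are removed before averaging.
#' Normalized depth is raw depth divided by this trimmed mean.
#'
#' @param row Non-negative numeric vector of raw site depths.
#' @return List with `trimmed_mean` and `normalized`.
#' @export
trimmed_mean_normalize <- function(row) {
  if (all(row == 0)) stop("degenerate sample: all-zero depth row")
  n <- length(row)
  if (n < 10L) {
    warning("fewer than 10 sites: using plain mean")
    tm <- mean(row)
  } else {
    k <- floor(0.05 * n)
    s <- sort(row)
    kept <- if (k > 0L) s[(k + 1L):(n - k)] else s
    tm <- mean(kept)
  }
  if (tm <= 0) stop("degenerate sample: trimmed mean is zero")
  list(trimmed_mean = tm, normalized = row / tm)
}

#' Assemble a cohort depth matrix with QC metrics
#'
#' @param raw Samples x sites integer matrix of deduplicated depths (e.g.
#'   from [simulate_cohort()] or stacked [preprocess_sample()] outputs).
#' @param qc Optional per-sample data.frame (on_target_ratio, dedup_ratio);
#'   row order must match `raw`.
#' @return A `depth_matrix` list: `raw`, `normalized`, `trimmed_mean`
#'   (per-sample), `coverage` (fraction of sites with depth >= 1), `qc`.
#' @export
build_depth_matrix <- function(raw, qc = NULL) {
  stopifnot(is.matrix(raw), !is.null(rownames(raw)), !is.null(colnames(raw)))
  if (!is.null(qc) && nrow(qc) != nrow(raw))
    stop("QC table does not match sample count")
  tm <- numeric(nrow(raw))
  normalized <- matrix(NA_real_, nrow(raw), ncol(raw),
                       dimnames = dimnames(raw))
  for (i in seq_len(nrow(raw))) {
    res <- tryCatch(trimmed_mean_normalize(raw[i, ]),
                    error = function(e) stop("sample '", rownames(raw)[i],
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
    tm[i] <- res$trimmed_mean
    normalized[i, ] <- res$normalized
  }
  structure(list(raw = raw, normalized = normalized,
                 trimmed_mean = stats::setNames(tm, rownames(raw)),
                 coverage = rowMeans(raw >= 1), qc = qc),
            class = "depth_matrix")
}

#' Preprocess one sample from FASTQ to site depths
#'
#' Full per-sample pipeline: parse the paired library, QC filter,
#' assign reads to sites (simulator truth positions or external BAM),
#' deduplicate UMIs, and compute QC metrics.
#'
#' @param r1,r2,truth_tsv,bam See [read_library()].
#' @param sites Site table.
#' @return List: `site_depths` (integer vector over all sites, zeros
#'   filled), `on_target_ratio`, `dedup_ratio`, `qc_report`.
#' @export
preprocess_sample <- function(r1, r2, sites, truth_tsv = NULL, bam = NULL) {
  reads <- read_library(r1, r2, truth_tsv = truth_tsv, bam = bam)
  qc <- qc_filter_reads(reads)
  assigned <- assign_reads_to_sites(qc$reads, sites)
  dedup <- deduplicate_umis(assigned)
  depths <- stats::setNames(integer(nrow(sites)), sites$site_id)
  depths[names(dedup$site_counts)] <- dedup$site_counts
  list(site_depths = depths,
       on_target_ratio = on_target_ratio(dedup$molecules),
       dedup_ratio = dedup$dedup_ratio,
       qc_report = qc$report)
}
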