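# In-silico MRE-Seq library generator. Each on-target molecule is a fragment
# whose 5' terminus sits at motif_start + 2 of a SacII site (so read 1 begins
# "GCGG", the ligation signature), size-selected uniformly within the
# configured window. Read 2 carries the 10 bp UMI in its first cycles, as in
# the real library design. PCR duplicates share the molecule's UMI.

DNA_BASES <- c("A", "C", "G", "T")

random_umis <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste0, collapse = "")
}

revcomp <- function(x) {
  suppressWarnings(
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  hit_reads <- which(n_err > 0L)
  for (i in hit_reads) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
    }
  }
  seqs
}

#' Simulate a paired-end MRE-Seq FASTQ library for one sample
#'
#' Draws per-site on-target molecule counts from the same Poisson depth
#' model as [simulate_sample_depths()]; off-target molecules start at
#' uniform random genome positions. Each molecule receives a random UMI and
#' is emitted `1 + k` times with `k ~ Poisson(pcr_duplication_mean - 1)` as
#' PCR duplicates sharing the UMI. Fragment length is uniform on the
#' size-selection window; fragments that would run past the contig end are
#' resampled at another site/position (counted and warned). Read 1 is the
#' fragment 5' end; read 2 is the UMI followed by the reverse complement of
#' the fragment 3' end. Per-base substitution errors are applied at
#' `seq_error_rate`.
#'
#' @param atlas From [build_methylation_atlas()].
#' @param truth_class,tumor_fraction Sample truth (class in atlas; tf in
#'   [0,1]).
#' @param genome Named character vector from [read_genome_fasta()].
#' @param sites Site table from [enumerate_sacii_sites()].
#' @param lib From [library_config()].
#' @param seed Integer seed.
#' @param out_prefix Path prefix; writes `<prefix>_R1.fastq`,
#'   `<prefix>_R2.fastq` and `<prefix>_truth.tsv` (add `.gz` via `gzip`).
#' @param gzip Compress FASTQ output.
#' @return Invisible list with file paths, the truth table, and the number
#'   of resampled fragments.
#' @export
simulate_reads <- function(atlas, truth_class, tumor_fraction, genome, sites,
                           lib = library_config(), seed = 1L,
                           out_prefix = tempfile("mreseq_"), gzip = FALSE) {
  if (!truth_class %in% rownames(atlas$m))
    stop("unknown class '", truth_class, "'; atlas classes: ",
         paste(rownames(atlas$m), collapse = ", "))
  if (nrow(sites) != ncol(atlas$m))
    stop("site table does not match atlas width")
  set.seed(seed)
  tf <- tumor_fraction
  p_cut <- (1 - tf) * (1 - atlas$m["control", ]) +
    tf * (1 - atlas$m[truth_class, ])
  n_mol_site <- rpois(nrow(sites), lib$mean_site_depth * p_cut)
  n_bg <- rpois(1L, lib$mean_site_depth * lib$off_target_rate * nrow(sites))

  chrom_len <- nchar(genome)
  # molecule table: origin site (NA = background) and 5' position
  origin_site <- rep.int(seq_len(nrow(sites)), n_mol_site)
  mol <- data.frame(
    site_idx = c(origin_site, rep(NA_integer_, n_bg)),
    stringsAsFactors = FALSE)
  mol$chrom <- ifelse(is.na(mol$site_idx), NA_character_,
                      sites$chrom[mol$site_idx])
  mol$pos <- ifelse(is.na(mol$site_idx), NA_integer_,
                    sites$motif_start[mol$site_idx] + sites$cut_offset[mol$site_idx])
  if (n_bg > 0L) {
    bg_rows <- which(is.na(mol$site_idx))
    bg_chrom <- sample(names(genome), n_bg, replace = TRUE,
                       prob = chrom_len / sum(chrom_len))
    mol$chrom[bg_rows] <- bg_chrom
    mol$pos[bg_rows] <- vapply(bg_chrom, function(ch) {
      as.integer(floor(runif(1L, 0, max(1L, chrom_len[[ch]] - lib$fragment_min))))
    }, integer(1), USE.NAMES = FALSE)
  }
  n_resampled <- 0L
  len_avail <- chrom_len[mol$chrom] - mol$pos
  frag_len <- as.integer(floor(runif(nrow(mol), lib$fragment_min,
                                     lib$fragment_max + 1L)))
  bad <- which(frag_len > len_avail)
  for (i in bad) {
    repeat {
      # fragment would run past the contig end: resample
      n_resampled <- n_resampled + 1L
      if (mol$pos[i] + lib$fragment_min > chrom_len[[mol$chrom[i]]]) {
        if (is.na(mol$site_idx[i])) {
          mol$pos[i] <- as.integer(floor(runif(1L, 0,
            max(1L, chrom_len[[mol$chrom[i]]] - lib$fragment_min))))
        } else {
          # on-target molecule pinned near the contig end: truncate
          frag_len[i] <- max(lib$read_length,
                             chrom_len[[mol$chrom[i]]] - mol$pos[i])
          break
        }
      }
      L <- as.integer(floor(runif(1L, lib$fragment_min, lib$fragment_max + 1L)))
      if (mol$pos[i] + L <= chrom_len[[mol$chrom[i]]]) { frag_len[i] <- L; break }
    }
  }
  if (n_resampled > 0L)
    warning(n_resampled, " fragments resampled/truncated at contig ends")

  mol$umi <- random_umis(nrow(mol), lib$umi_length)
  mol$molecule_id <- sprintf("m%06d", seq_len(nrow(mol)))
  n_dups <- 1L + rpois(nrow(mol), lib$pcr_duplication_mean - 1)

  read_rows <- rep.int(seq_len(nrow(mol)), n_dups)
  dup_idx <- sequence(n_dups)
  frag_seq <- substr(genome[mol$chrom[read_rows]],
                     mol$pos[read_rows] + 1L,
                     mol$pos[read_rows] + frag_len[read_rows])
  r1 <- substr(frag_seq, 1L, lib$read_length)
  tail_len <- lib$read_length - lib$umi_length
  r2_genomic <- revcomp(substr(frag_seq,
                               pmax(1L, nchar(frag_seq) - tail_len + 1L),
                               nchar(frag_seq)))
  r2 <- paste0(mol$umi[read_rows], r2_genomic)
  r1 <- inject_errors(r1, lib$seq_error_rate)
  r2 <- inject_errors(r2, lib$seq_error_rate)
  read_id <- sprintf("%s_d%02d", mol$molecule_id[read_rows], dup_idx)

  open_out <- function(path) if (gzip) gzfile(path, "w") else file(path, "w")
  suffix <- if (gzip) ".gz" else ""
  f1 <- paste0(out_prefix, "_R1.fastq", suffix)
  f2 <- paste0(out_prefix, "_R2.fastq", suffix)
  ft <- paste0(out_prefix, "_truth.tsv")
  con1 <- open_out(f1); con2 <- open_out(f2)
  writeLines(paste0("@", read_id, " UMI:Z:", mol$umi[read_rows], "\n",
                    r1, "\n+\n", strrep("I", nchar(r1))), con1)
  writeLines(paste0("@", read_id, " UMI:Z:", mol$umi[read_rows], "\n",
                    r2, "\n+\n", strrep("I", nchar(r2))), con2)
  close(con1); close(con2)

  truth <- data.frame(read_id = read_id,
                      chrom = mol$chrom[read_rows],
                      pos = mol$pos[read_rows],
                      site_id = ifelse(is.na(mol$site_idx[read_rows]),
                                       "background",
                                       sites$site_id[mol$site_idx[read_rows]]),
                      molecule_id = mol$molecule_id[read_rows],
                      umi = mol$umi[read_rows],
                      stringsAsFactors = FALSE)
  write.table(truth, ft, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(r1 = f1, r2 = f2, truth_tsv = ft, truth = truth,
                 n_molecules = nrow(mol), n_reads = length(read_id),
                 n_resampled = n_resampled))
}

#' Read a simulated paired-end library into a read table
#'
#' Parses the two FASTQ mates and joins genomic positions either from the
#' simulator's truth TSV or from a coordinate-sorted BAM produced by an
#' external aligner (the pipeline does not align reads itself). The UMI is
#' taken from the `UMI:Z:` header tag when present, otherwise from the
#' first `umi_length` cycles of read 2.
#'
#' @param r1,r2 FASTQ paths (mate 2 may be `NULL` for a single-end library,
#'   whose reads are then dropped by QC).
#' @param truth_tsv Truth table path from [simulate_reads()].
#' @param bam Alternative position source: BAM path (requires Rsamtools);
#'   positions are the 5'-most aligned base of read 1, 0-based.
#' @param umi_length UMI length for fallback extraction from read 2.
#' @return data.frame with read_id, seq1, seq2, qual2, umi, chrom, pos.
#' @export
read_library <- function(r1, r2 = NULL, truth_tsv = NULL, bam = NULL,
                         umi_length = 10L) {
  fq1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1))
  ids <- sub("\\s.*$", "", names(fq1))
  umi_tag <- ifelse(grepl("UMI:Z:", names(fq1)),
                    sub(".*UMI:Z:(\\S+).*", "\\1", names(fq1)), NA_character_)
  reads <- data.frame(read_id = ids,
                      seq1 = as.character(fq1),
                      seq2 = NA_character_, qual2 = NA_character_,
                      umi = umi_tag, stringsAsFactors = FALSE)
  if (!is.null(r2)) {
    fq2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2))
    ids2 <- sub("\\s.*$", "", names(fq2))
    idx <- match(reads$read_id, ids2)
    reads$seq2 <- as.character(fq2)[idx]
    reads$qual2 <- as.character(Biostrings::quality(fq2))[idx]
    fallback <- is.na(reads$umi) & !is.na(reads$seq2)
    reads$umi[fallback] <- substr(reads$seq2[fallback], 1L, umi_length)
  }
  reads$chrom <- NA_character_
  reads$pos <- NA_integer_
  if (!is.null(truth_tsv)) {
    truth <- read.delim(truth_tsv, stringsAsFactors = FALSE)
    idx <- match(reads$read_id, truth$read_id)
    reads$chrom <- truth$chrom[idx]
    reads$pos <- as.integer(truth$pos[idx])
  } else if (!is.null(bam)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("Rsamtools is required to read BAM input")
    aln <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "flag")))[[1]]
    first_mate <- bitwAnd(aln$flag, 128L) == 0L
    idx <- match(reads$read_id, aln$qname[first_mate])
    reads$chrom <- as.character(aln$rname[first_mate])[idx]
    reads$pos <- as.integer(aln$pos[first_mate])[idx] - 1L  # BAM 1-based
  }
  reads
}
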