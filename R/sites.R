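#' @importFrom stats rbeta rpois rbinom runif rnorm quantile sd aov cor.test
#'   lm model.matrix p.adjust pnorm prcomp pt qnorm t.test predict
#' @importFrom utils read.delim write.table head
"_PACKAGE"

SACII_MOTIF <- "CCGCGG"
SACII_CUT_OFFSET <- 2L

#' Read a reference genome from FASTA
#'
#' Loads all records of a (plain or bgzip) FASTA file as a named character
#' vector of upper-case sequences. Multi-line records are concatenated and
#' lowercase (soft-masked) bases are folded to upper case so that masking
#' cannot suppress restriction sites.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (alphabet A,C,G,T,N).
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L) stop("FASTA file '", path, "' contains no records")
  out <- toupper(as.character(seqs))
  # headers may carry descriptions after the first token
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(out)))
    stop("duplicate sequence names in FASTA: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  if (any(nchar(out) == 0L)) stop("empty sequence record in FASTA")
  out
}

#' Enumerate SacII recognition sites in a genome
#'
#' Scans every sequence for the palindromic SacII motif CCGCGG and returns
#' the ordered site table that defines the marker universe. Because the
#' motif equals its own reverse complement, a single forward-strand scan
#' finds every site exactly once, and a 6-mer CCGCGG cannot overlap itself,
#' so sites are overlap-free by construction.
#'
#' Coordinates are 0-based half-open internally (BED convention on disk);
#' `motif_start` is the offset of the first C and `cut_offset` is fixed at
#' +2 so that reads beginning at `motif_start + 2` start with "GCGG", the
#' on-target signature of a SacII cut.
#'
#' @param genome Named character vector from [read_genome_fasta()].
#' @param autosomes_only Keep only chromosomes listed in `autosome_names`.
#' @param autosome_names Chromosome names treated as autosomes
#'   (default `chr1`..`chr22`).
#' @return A `data.frame` with columns `chrom`, `motif_start` (0-based),
#'   `cut_offset`, `site_id` ("chrom:motif_start"), sorted by
#'   (chrom, motif_start) in the genome's sequence order.
#' @export
enumerate_sacii_sites <- function(genome, autosomes_only = FALSE,
                                  autosome_names = paste0("chr", 1:22)) {
  if (length(genome) == 0L) {
    warning("empty genome: returning empty site table")
    return(empty_site_table())
  }
  if (autosomes_only) {
    missing_chr <- setdiff(autosome_names, names(genome))
    keep <- intersect(names(genome), autosome_names)
    if (length(keep) == 0L) {
      warning("no autosomes found in genome: returning empty site table")
      return(empty_site_table())
    }
    genome <- genome[keep]
  }
  per_chrom <- lapply(names(genome), function(chrom) {
    m <- Biostrings::matchPattern(SACII_MOTIF,
                                  Biostrings::DNAString(genome[[chrom]]))
    starts0 <- BiocGenerics::start(m) - 1L  # to 0-based
    if (length(starts0) == 0L) return(NULL)
    data.frame(chrom = chrom, motif_start = sort(starts0),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_chrom)
  if (is.null(tab)) {
    warning("no SacII sites found: returning empty site table")
    return(empty_site_table())
  }
  tab$cut_offset <- SACII_CUT_OFFSET
  tab$site_id <- paste0(tab$chrom, ":", tab$motif_start)
  stopifnot(!anyDuplicated(tab$site_id))
  rownames(tab) <- NULL
  class(tab) <- c("sacii_sites", "data.frame")
  tab
}

empty_site_table <- function() {
  tab <- data.frame(chrom = character(0), motif_start = integer(0),
                    cut_offset = integer(0), site_id = character(0),
                    stringsAsFactors = FALSE)
  class(tab) <- c("sacii_sites", "data.frame")
  tab
}

#' Write a SacII site table as BED6
#'
#' Writes one 0-based half-open interval `[motif_start, motif_start + 6)`
#' per site, with the site id in the name column and strand "+" (the motif
#' is palindromic, so strand is nominal).
#'
#' @param sites Site table from [enumerate_sacii_sites()].
#' @param path Output path.
#' @export
write_sites_bed <- function(sites, path) {
  if (nrow(sites) == 0L) {
    warning("writing empty BED file: site table has no rows")
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = sites$chrom,
                    start = sites$motif_start,
                    end = sites$motif_start + nchar(SACII_MOTIF),
                    name = sites$site_id,
                    score = 0L,
                    strand = "+")
  ok <- tryCatch({
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write BED file: ", path)
  invisible(path)
}

#' Read a SacII site table from BED6
#'
#' Inverse of [write_sites_bed()].
#'
#' @param path BED file path.
#' @return Site table as from [enumerate_sacii_sites()].
#' @export
read_sites_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty BED file")
    return(empty_site_table())
  }
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  tab <- data.frame(chrom = as.character(bed[[1]]),
                    motif_start = as.integer(bed[[2]]),
                    stringsAsFactors = FALSE)
  tab$cut_offset <- SACII_CUT_OFFSET
  tab$site_id <- as.character(bed[[4]])
  class(tab) <- c("sacii_sites", "data.frame")
  tab
}

#' Convert a site table to GRanges
#'
#' @param sites Site table.
#' @return A [GenomicRanges::GRanges] of the 6 bp motif intervals (1-based).
#' @export
sites_as_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$motif_start + 1L,
                              width = nchar(SACII_MOTIF)),
    strand = "+",
    site_id = sites$site_id
  )
}
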