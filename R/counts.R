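# Strand-specific base counts: derivation from SAM/BAM and TSV round-trip.

#' Strand-specific base counts from SAM/BAM alignments
#'
#' Tallies, per reference position and transcript strand, the A/C/G/T bases
#' observed in mapped reads meeting a base-quality floor. Unmapped,
#' secondary and supplementary records are skipped, and read bases inside
#' indels contribute nothing. Counts are stored in *transcript sense*:
#' observations assigned to the minus strand are complemented, so a C-to-U
#' edit is always a stored C -> T regardless of strand.
#'
#' `strandedness` gives the library convention mapping read strand to
#' transcript strand: `"forward"` (read strand = transcript strand) or
#' `"reverse"` (opposite, as in dUTP stranded protocols).
#'
#' @param file Path to a SAM or BAM file (SAM is converted on the fly).
#' @param min_base_quality Minimum Phred base quality to count a base.
#' @param strandedness `"forward"` or `"reverse"`.
#' @param sample_name Sample label stored in the table (defaults to the file
#'   name without extension).
#' @param max_depth Pileup depth cap per position (set high; the default
#'   pileup cap of 250 would truncate deep RNA-seq).
#' @return A `base_counts` data.frame with columns `sequence`, `position`
#'   (1-based), `strand`, `n_A`, `n_C`, `n_G`, `n_T`, `sample`. Absent
#'   positions mean zero coverage.
#' @export
count_bases <- function(file, min_base_quality = 0L,
                        strandedness = c("forward", "reverse"),
                        sample_name = NULL, max_depth = 1000000L) {
  strandedness <- match.arg(strandedness)
  if (is.null(sample_name)) {
    sample_name <- tools::file_path_sans_ext(basename(file))
  }
  bam <- file
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(file, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
  } else if (!file.exists(paste0(file, ".bai")) &&
             !file.exists(sub("\\.bam$", ".bai", file))) {
    Rsamtools::indexBam(file)
  }
  pparam <- Rsamtools::PileupParam(
    max_depth = as.integer(max_depth),
    min_base_quality = as.integer(min_base_quality),
    min_mapq = 0L, min_nucleotide_depth = 1L,
    distinguish_strands = TRUE, distinguish_nucleotides = TRUE,
    include_deletions = FALSE, include_insertions = FALSE
  )
  sparam <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  p <- Rsamtools::pileup(bam, pileupParam = pparam, scanBamParam = sparam)
  p <- p[p$nucleotide %in% c("A", "C", "G", "T"), , drop = FALSE]
  if (!nrow(p)) return(empty_base_counts(sample_name))
  read_strand <- as.character(p$strand)
  tx_strand <- if (strandedness == "forward") read_strand else
    ifelse(read_strand == "+", "-", "+")
  base <- as.character(p$nucleotide)
  # pileup reports bases in reference-forward orientation; transcript sense
  # on the minus strand is the complement
  flip <- tx_strand == "-"
  base[flip] <- comp_chr(base[flip])
  key <- paste(p$seqnames, p$pos, tx_strand)
  tab <- rowsum(p$count, paste(key, base))
  parts <- strsplit(rownames(tab), " ", fixed = TRUE)
  df <- data.frame(
    sequence = vapply(parts, `[`, "", 1L),
    position = as.integer(vapply(parts, `[`, "", 2L)),
    strand = vapply(parts, `[`, "", 3L),
    base = vapply(parts, `[`, "", 4L),
    count = as.integer(tab[, 1L]),
    stringsAsFactors = FALSE
  )
  wide <- empty_base_counts(sample_name)
  ukey <- unique(df[, c("sequence", "position", "strand")])
  ukey <- ukey[order(ukey$sequence, ukey$position, ukey$strand), , drop = FALSE]
  idx <- match(paste(df$sequence, df$position, df$strand),
               paste(ukey$sequence, ukey$position, ukey$strand))
  counts <- matrix(0L, nrow = nrow(ukey), ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[cbind(idx, match(df$base, c("A", "C", "G", "T")))] <- df$count
  wide <- data.frame(ukey,
                     n_A = counts[, "A"], n_C = counts[, "C"],
                     n_G = counts[, "G"], n_T = counts[, "T"],
                     sample = sample_name,
                     stringsAsFactors = FALSE)
  rownames(wide) <- NULL
  class(wide) <- c("base_counts", "data.frame")
  wide
}

#' @noRd
empty_base_counts <- function(sample_name = character(0)) {
  df <- data.frame(sequence = character(), position = integer(),
                   strand = character(), n_A = integer(), n_C = integer(),
                   n_G = integer(), n_T = integer(), sample = character(),
                   stringsAsFactors = FALSE)
  class(df) <- c("base_counts", "data.frame")
  df
}

#' Read and write base-count tables
#'
#' Tab-separated with header `sequence, position, strand, n_A, n_C, n_G,
#' n_T, sample`; positions are 1-based and counts are transcript-sense (see
#' [count_bases()]).
#'
#' @param file Path to a counts TSV.
#' @return `read_base_counts` returns a `base_counts` data.frame;
#'   `write_base_counts` returns `file`, invisibly.
#' @export
read_base_counts <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  required <- c("sequence", "position", "strand", "n_A", "n_C", "n_G", "n_T")
  if (!all(required %in% names(df))) {
    stop("counts table must have columns: ", paste(required, collapse = ", "))
  }
  if (!"sample" %in% names(df)) df$sample <- NA_character_
  validate_base_counts(df)
  class(df) <- c("base_counts", "data.frame")
  df
}

#' @rdname read_base_counts
#' @param counts A `base_counts` data.frame.
#' @export
write_base_counts <- function(counts, file) {
  write.table(counts, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @noRd
validate_base_counts <- function(df) {
  cnt <- as.matrix(df[, c("n_A", "n_C", "n_G", "n_T")])
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop("base counts must be non-negative integers")
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  invisible(TRUE)
}
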