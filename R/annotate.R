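# Coding-consequence annotation of editing calls against GFF3 gene models.

#' Annotate the coding consequence of C-to-U editing calls
#'
#' Projects each edited C into the codon of any CDS containing it on the
#' same strand and reports the codon and amino acid before and after the
#' C -> U (stored C -> T) substitution under the standard genetic code
#' (used also for plastid sites). Calls outside coding sequence are
#' labelled by their feature context: `intron` when inside a gene/mRNA span
#' but not in any exon, otherwise `UTR/intergenic`. CDS models with an
#' invalid phase or a spliced length that is not a multiple of three are
#' skipped with a warning.
#'
#' @param calls data.frame with columns `sequence`, `position`, `strand`
#'   (e.g. [detect_editing()] output).
#' @param annotations Path to a GFF3 file, or a `GRanges` with `type`
#'   (CDS/exon/gene/mRNA), `phase` and `Parent`/`ID` metadata.
#' @param reference The reference sequences (`DNAStringSet`, FASTA path, or
#'   named character).
#' @return `calls` with added columns `category` (one of `synonymous`,
#'   `nonsynonymous`, `intron`, `UTR/intergenic`), `gene`, `codon_before`,
#'   `codon_after`, `aa_before`, `aa_after`, `codon_position`.
#' @export
annotate_effect <- function(calls, annotations, reference) {
  reference <- as_dnastringset(reference)
  gr <- if (inherits(annotations, "GRanges")) annotations else
    rtracklayer::import(annotations, format = "gff3")
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  n <- nrow(calls)
  category <- rep("UTR/intergenic", n)
  gene <- rep(NA_character_, n)
  codon_before <- rep(NA_character_, n)
  codon_after <- rep(NA_character_, n)
  aa_before <- rep(NA_character_, n)
  aa_after <- rep(NA_character_, n)
  codon_position <- rep(NA_integer_, n)
  if (!n) {
    return(cbind(calls, data.frame(category = character(0),
                                   gene = character(0),
                                   codon_before = character(0),
                                   codon_after = character(0),
                                   aa_before = character(0),
                                   aa_after = character(0),
                                   codon_position = integer(0))))
  }

  type <- as.character(gr$type)
  cds <- gr[type == "CDS"]
  exons <- gr[type %in% c("exon", "CDS")]
  spans <- gr[type %in% c("gene", "mRNA", "transcript")]
  cds_parent <- feature_parent(cds)
  models <- split(seq_along(cds), cds_parent)

  pos_gr <- GenomicRanges::GRanges(
    calls$sequence, IRanges::IRanges(calls$position, calls$position),
    strand = calls$strand
  )
  chars <- lapply(seq_along(reference),
                  function(k) split1(norm_bases(as.character(reference[[k]]))))
  names(chars) <- names(reference)

  for (model in models) {
    pieces <- cds[model]
    strand <- unique(as.character(GenomicRanges::strand(pieces)))
    seqname <- unique(as.character(GenomicRanges::seqnames(pieces)))
    if (length(strand) != 1L || length(seqname) != 1L) {
      warning("CDS model spans strands/sequences; skipped")
      next
    }
    ord <- order(GenomicRanges::start(pieces),
                 decreasing = (strand == "-"))
    pieces <- pieces[ord]
    phase <- pieces$phase
    ph1 <- if (length(phase) && !is.na(phase[1])) as.integer(phase[1]) else 0L
    if (is.na(ph1) || ph1 < 0L || ph1 > 2L) {
      warning("CDS model with invalid phase; skipped")
      next
    }
    # spliced coding coordinates, 5'->3' in transcript orientation
    coding_coords <- unlist(lapply(seq_along(pieces), function(i) {
      s <- GenomicRanges::start(pieces)[i]
      e <- GenomicRanges::end(pieces)[i]
      if (strand == "-") rev(s:e) else s:e
    }))
    coding_coords <- coding_coords[(ph1 + 1L):length(coding_coords)]
    if (length(coding_coords) %% 3L != 0L) {
      warning("CDS model '", feature_parent(pieces)[1],
              "' has spliced length not a multiple of 3; skipped")
      next
    }
    sq <- chars[[seqname]]
    if (is.null(sq)) next
    coding_seq <- sq[coding_coords]
    if (strand == "-") coding_seq <- comp_chr_vec(coding_seq)

    hits <- which(calls$sequence == seqname & calls$strand == strand &
                    calls$position %in% coding_coords)
    for (i in hits) {
      cpos <- match(calls$position[i], coding_coords)
      codon_i <- (cpos - 1L) %/% 3L
      within <- (cpos - 1L) %% 3L + 1L
      cod <- coding_seq[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
      before <- paste(cod, collapse = "")
      cod[within] <- "T"  # transcript-sense C -> U
      after <- paste(cod, collapse = "")
      aa1 <- Biostrings::GENETIC_CODE[[before]]
      aa2 <- Biostrings::GENETIC_CODE[[after]]
      category[i] <- if (identical(aa1, aa2)) "synonymous" else "nonsynonymous"
      gene[i] <- feature_parent(pieces)[1]
      codon_before[i] <- before
      codon_after[i] <- after
      aa_before[i] <- aa1
      aa_after[i] <- aa2
      codon_position[i] <- within
    }
  }

  # feature context for the remaining calls: intron vs UTR/intergenic
  uncoded <- which(category == "UTR/intergenic")
  if (length(uncoded) && length(spans)) {
    in_span <- IRanges::overlapsAny(pos_gr[uncoded], spans)
    in_exon <- if (length(exons)) {
      IRanges::overlapsAny(pos_gr[uncoded], exons)
    } else rep(FALSE, length(uncoded))
    category[uncoded[in_span & !in_exon]] <- "intron"
  }

  calls$category <- category
  calls$gene <- gene
  calls$codon_before <- codon_before
  calls$codon_after <- codon_after
  calls$aa_before <- aa_before
  calls$aa_after <- aa_after
  calls$codon_position <- codon_position
  calls
}

#' @noRd
feature_parent <- function(gr) {
  n <- length(gr)
  if (!n) return(character(0))
  parent <- rep(NA_character_, n)
  if (!is.null(gr$Parent)) {
    p <- gr$Parent
    if (methods::is(p, "CharacterList")) {
      has <- lengths(p) > 0
      parent[has] <- vapply(p[has], `[`, "", 1L)
    } else {
      parent <- as.character(p)
    }
  }
  if (!is.null(gr$ID)) {
    parent[is.na(parent)] <- as.character(gr$ID)[is.na(parent)]
  }
  miss <- is.na(parent)
  parent[miss] <- paste0("model_", as.character(GenomicRanges::seqnames(gr))[miss],
                         "_", GenomicRanges::start(gr)[miss])
  parent
}
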