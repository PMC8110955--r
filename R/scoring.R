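# Binding scoring: PPR-code scoring tables, alignment scoring, genome scans.

#' PPR-code scoring tables
#'
#' A scoring table maps a (5th residue, last residue, nucleotide) triple to a
#' dimensionless real score; the total predicted binding score of a
#' factor/RNA alignment is the exact sum of per-motif scores. Pairs absent
#' from the table score `default_score` (neutral 0 by default) -- never an
#' error. The file format is tab-separated with columns
#' `fifth`, `last`, `A`, `C`, `G`, `U` and round-trips losslessly.
#'
#' A simplified default table encoding the canonical code preferences ships
#' with the package
#' (`system.file("extdata", "ppr_scoring_default.tsv", package = "ppredit")`);
#' users working from published empirical tables (e.g. those distributed
#' with PPRmatcher) can load them through the same format.
#'
#' @param entries data.frame with columns `fifth`, `last`, `A`, `C`, `G`, `U`.
#' @param default_score Score for (fifth, last) pairs absent from the table.
#' @return An object of class `ppr_scoring`.
#' @export
scoring_table <- function(entries, default_score = 0) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  required <- c("fifth", "last", "A", "C", "G", "U")
  if (!all(required %in% names(entries))) {
    stop("scoring table must have columns: ", paste(required, collapse = ", "))
  }
  entries <- entries[, required]
  for (b in c("A", "C", "G", "U")) {
    entries[[b]] <- as.numeric(entries[[b]])
    if (any(!is.finite(entries[[b]]))) stop("scores must be finite reals")
  }
  if (!is.numeric(default_score) || length(default_score) != 1L ||
      !is.finite(default_score)) {
    stop("default_score must be a single finite number")
  }
  if (anyDuplicated(paste(entries$fifth, entries$last))) {
    stop("scoring table has duplicated (fifth, last) keys")
  }
  structure(list(entries = entries, default_score = default_score),
            class = "ppr_scoring")
}

#' @rdname scoring_table
#' @param file Path to a tab-separated scoring table.
#' @export
read_scoring_table <- function(file, default_score = 0) {
  tab <- read.delim(file, stringsAsFactors = FALSE, comment.char = "#",
                    check.names = FALSE)
  scoring_table(tab, default_score = default_score)
}

#' @rdname scoring_table
#' @param table A `ppr_scoring` object to write.
#' @export
write_scoring_table <- function(table, file) {
  stopifnot(inherits(table, "ppr_scoring"))
  write.table(table$entries, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

# per-motif score rows over bases A,C,G,T(=U): matrix n_motif x 4
#' @noRd
motif_score_matrix <- function(factor, table) {
  stopifnot(inherits(factor, "ppr_factor"), inherits(table, "ppr_scoring"))
  m <- factor$motifs[is_contacting(factor), , drop = FALSE]
  key <- paste(m$fifth, m$last)
  idx <- match(key, paste(table$entries$fifth, table$entries$last))
  out <- matrix(table$default_score, nrow = nrow(m), ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  hit <- !is.na(idx)
  if (any(hit)) {
    out[hit, ] <- as.matrix(table$entries[idx[hit], c("A", "C", "G", "U")])
  }
  out
}

# index of the motif whose aligned base anchors the edit offset:
# the S2 motif, or the last contacting motif when no S2 exists
#' @noRd
anchor_index <- function(factor) {
  types <- factor$motifs$type[is_contacting(factor)]
  i <- which(types == "S2")
  if (length(i)) i[1] else length(types)
}

#' Score a factor/RNA window alignment
#'
#' Contacting motifs align one-to-one, 5' to 3', with the window (first
#' contacting motif to first base); E1/E2/DYW contact nothing. Each motif
#' scores `table[(fifth, last, base)]`, or the table's `default_score` for
#' pairs absent from the table; the total is the exact sum. The predicted
#' edited C lies 4 nucleotides 3' of the base aligned with the S2 motif (or
#' with the last contacting motif when no S2 exists), i.e. at window-relative
#' position `s2_index + 4` -- 4 bases past the window end for a factor
#' ending in S2.
#'
#' @param factor A [ppr_factor()].
#' @param rna_window Nucleotide string, one base per contacting motif
#'   (A/C/G/U; T accepted as U).
#' @param table A [scoring_table()].
#' @return A list of class `site_alignment` with elements
#'   `factor_name`, `window`, `per_motif_scores`, `total_score`, and
#'   `edit_offset` (1-based window-relative position of the predicted
#'   edited C).
#' @export
score_alignment <- function(factor, rna_window, table) {
  stopifnot(inherits(factor, "ppr_factor"))
  nc <- n_contacting(factor)
  w <- norm_bases(rna_window)
  bases <- split1(w)
  if (length(bases) != nc) {
    stop("window length (", length(bases), ") must equal the number of ",
         "contacting motifs (", nc, ")")
  }
  bi <- match(bases, c("A", "C", "G", "T"))
  if (anyNA(bi)) {
    stop("invalid base(s) in window: ",
         paste(unique(bases[is.na(bi)]), collapse = ", "))
  }
  msc <- motif_score_matrix(factor, table)
  per <- msc[cbind(seq_len(nc), bi)]
  structure(
    list(factor_name = factor$name,
         window = w,
         per_motif_scores = per,
         total_score = sum(per),
         edit_offset = anchor_index(factor) + EDIT_OFFSET),
    class = "site_alignment"
  )
}

#' @export
print.site_alignment <- function(x, ...) {
  cat("<site_alignment> ", x$factor_name, " on ", x$window,
      "  total=", format(x$total_score), "\n", sep = "")
  invisible(x)
}

#' @noRd
as_dnastringset <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
    return(Biostrings::DNAStringSet(norm_bases(genome)))
  }
  stop("genome must be a DNAStringSet, a FASTA path, or named sequences")
}

#' Scan sequences for candidate binding/editing sites
#'
#' Slides the factor's contacting-motif window along each sequence (and its
#' reverse complement for the minus strand), scoring every placement with
#' the scoring table. Each placement predicts an edited C 4 nt 3' of the
#' S2-aligned base, so the full window span is `n_contacting + 4` bases in
#' transcript orientation. With `anchor = "edited_C_only"` only placements
#' whose predicted edit position carries a transcript-sense C are returned
#' (on the minus strand that is a plus-strand reference G).
#'
#' Coordinates are 1-based on the forward reference strand: `window_start`
#' is the leftmost aligned base of the contact window and `edit_position`
#' the predicted edited base. With `circular = TRUE` the sequence is
#' extended by the window span (replicating its start) before scanning and
#' output coordinates are folded modulo the sequence length, so sites
#' spanning the origin of a circular genome are not lost.
#'
#' @param factor A [ppr_factor()].
#' @param genome A `DNAStringSet`, FASTA path, or named character sequences.
#' @param table A [scoring_table()].
#' @param strands `"both"` (default), `"forward"` or `"reverse"`.
#' @param anchor `"edited_C_only"` (default) or `"all_positions"`.
#' @param min_score Drop placements with `total_score` below this.
#' @param circular Treat each sequence as circular (see Details).
#' @return data.frame of class `site_scan`, sorted by `total_score`
#'   descending (ties: sequence name, window_start, strand), with columns
#'   `factor`, `sequence`, `strand`, `window_start`, `edit_position`,
#'   `per_motif_scores` (comma-joined) and `total_score`.
#' @export
scan_sequence <- function(factor, genome, table,
                          strands = c("both", "forward", "reverse"),
                          anchor = c("edited_C_only", "all_positions"),
                          min_score = -Inf, circular = FALSE) {
  strands <- match.arg(strands)
  anchor <- match.arg(anchor)
  genome <- as_dnastringset(genome)
  nc <- n_contacting(factor)
  span <- nc + EDIT_OFFSET
  msc <- motif_score_matrix(factor, table)
  a_idx <- anchor_index(factor)

  scan_strand <- function(tchars, L_out, strand, seqname) {
    # tchars: transcript-sense characters (already extended if circular)
    L <- length(tchars)
    if (L < span) return(NULL)
    bi <- match(tchars, c("A", "C", "G", "T"))
    if (anyNA(bi)) {
      stop("invalid base(s) in sequence '", seqname, "': ",
           paste(unique(tchars[is.na(bi)]), collapse = ", "))
    }
    starts <- seq_len(L - span + 1L)
    total <- numeric(length(starts))
    for (j in seq_len(nc)) {
      total <- total + msc[j, bi[starts + j - 1L]]
    }
    edit_t <- starts + a_idx + EDIT_OFFSET - 1L  # transcript coordinate
    keep <- rep(TRUE, length(starts))
    if (anchor == "edited_C_only") keep <- tchars[edit_t] == "C"
    keep <- keep & total >= min_score
    if (!any(keep)) return(NULL)
    starts <- starts[keep]
    total <- total[keep]
    edit_t <- edit_t[keep]
    per <- vapply(starts, function(s) {
      paste(msc[cbind(seq_len(nc), bi[s:(s + nc - 1L)])], collapse = ",")
    }, "")
    if (strand == "+") {
      ws <- starts
      ep <- edit_t
    } else {
      # transcript position t maps to forward coordinate L - t + 1;
      # window_start is the leftmost forward coordinate of the window
      ws <- L - (starts + nc - 1L) + 1L
      ep <- L - edit_t + 1L
    }
    if (circular) {
      ws <- (ws - 1L) %% L_out + 1L
      ep <- (ep - 1L) %% L_out + 1L
    }
    data.frame(factor = factor$name, sequence = seqname, strand = strand,
               window_start = as.integer(ws), edit_position = as.integer(ep),
               per_motif_scores = per, total_score = total,
               stringsAsFactors = FALSE)
  }

  out <- list()
  for (k in seq_along(genome)) {
    seqname <- names(genome)[k]
    fwd <- split1(norm_bases(as.character(genome[[k]])))
    L0 <- length(fwd)
    ext <- fwd
    if (circular && L0 >= span) ext <- c(fwd, fwd[seq_len(span - 1L)])
    if (strands %in% c("both", "forward")) {
      out[[length(out) + 1L]] <- scan_strand(ext, L0, "+", seqname)
    }
    if (strands %in% c("both", "reverse")) {
      rc <- rev(comp_chr_vec(ext))
      out[[length(out) + 1L]] <- scan_strand(rc, L0, "-", seqname)
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(factor = character(), sequence = character(),
               strand = character(), window_start = integer(),
               edit_position = integer(), per_motif_scores = character(),
               total_score = numeric(), stringsAsFactors = FALSE)
  ord <- order(-res$total_score, res$sequence, res$window_start, res$strand)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("site_scan", "data.frame")
  res
}

#' @noRd
comp_chr_vec <- function(x) chartr("ACGT", "TGCA", x)

#' Write a site scan to a tab-separated file
#'
#' @param scan A `site_scan` data.frame from [scan_sequence()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_scan_table <- function(scan, file) {
  write.table(scan, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Score known editing sites with a factor
#'
#' For each site (the coordinate of an edited C, 1-based, with its strand),
#' scores the factor against the window whose S2-aligned base lies 4 nt 5'
#' of the edited C in transcript orientation -- the binding placement
#' implied by the editing-site offset rule. Sites whose window overruns the
#' sequence start are flagged (`scored = FALSE`, NA scores) rather than
#' scored.
#'
#' @param factor A [ppr_factor()].
#' @param sites data.frame with columns `sequence`, `position` (1-based
#'   coordinate of the edited C on the forward strand) and `strand`.
#' @param genome A `DNAStringSet`, FASTA path, or named character sequences.
#' @param table A [scoring_table()].
#' @param circular Treat sequences as circular when extracting windows.
#' @return `sites` with added columns `window_start`, `per_motif_scores`,
#'   `total_score` and `scored`.
#' @export
score_site_table <- function(factor, sites, genome, table, circular = FALSE) {
  genome <- as_dnastringset(genome)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  required <- c("sequence", "position", "strand")
  if (!all(required %in% names(sites))) {
    stop("sites must have columns: ", paste(required, collapse = ", "))
  }
  nc <- n_contacting(factor)
  a_idx <- anchor_index(factor)
  n <- nrow(sites)
  ws <- rep(NA_integer_, n)
  per <- rep(NA_character_, n)
  total <- rep(NA_real_, n)
  scored <- rep(FALSE, n)
  chars <- lapply(seq_along(genome),
                  function(k) split1(norm_bases(as.character(genome[[k]]))))
  names(chars) <- names(genome)
  for (i in seq_len(n)) {
    sq <- chars[[sites$sequence[i]]]
    if (is.null(sq)) stop("unknown sequence: ", sites$sequence[i])
    L <- length(sq)
    pos <- sites$position[i]
    if (pos < 1L || pos > L) stop("site position out of range: ", pos)
    if (sites$strand[i] == "+") {
      # window covers forward coords [pos - 4 - nc + a_idx, ...]; motif j
      # aligns to forward coord pos - 4 - a_idx + j
      coords <- pos - EDIT_OFFSET - a_idx + seq_len(nc)
    } else {
      # transcript runs right-to-left; motif j aligns to pos + 4 + a_idx - j
      coords <- pos + EDIT_OFFSET + a_idx - seq_len(nc)
    }
    if (circular) coords <- (coords - 1L) %% L + 1L
    if (any(coords < 1L | coords > L)) next  # overruns: flagged, not scored
    wchars <- sq[coords]
    if (sites$strand[i] == "-") wchars <- comp_chr_vec(wchars)
    al <- score_alignment(factor, paste(wchars, collapse = ""), table)
    ws[i] <- min(coords)
    per[i] <- paste(al$per_motif_scores, collapse = ",")
    total[i] <- al$total_score
    scored[i] <- TRUE
  }
  sites$window_start <- ws
  sites$per_motif_scores <- per
  sites$total_score <- total
  sites$scored <- scored
  sites
}
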