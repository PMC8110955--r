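# Editing detection: candidate enumeration, contrasts, calling.

#' Define a treatment-vs-control editing contrast
#'
#' Holds the statistical parameters of an editing comparison: significance
#' level, log-odds-ratio threshold for "highlighted" calls, the pseudocount
#' added to all four contingency cells, and the log base. The shipped
#' defaults are alpha 0.05, threshold 2 on the natural-log odds ratio, and
#' pseudocount 0.5.
#'
#' @param treatment,control Sample labels (bookkeeping only).
#' @param alpha Significance level in (0, 1) applied to adjusted p-values.
#' @param lor_threshold Calls are `significant` only when the log odds
#'   ratio also exceeds this threshold.
#' @param pseudocount Positive pseudocount for the odds ratio.
#' @param log_base `"natural"` (default), `2` or `10`.
#' @return An object of class `editing_contrast`.
#' @export
editing_contrast <- function(treatment = "treatment", control = "control",
                             alpha = 0.05, lor_threshold = 2,
                             pseudocount = 0.5, log_base = "natural") {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be positive")
  }
  base <- if (identical(log_base, "natural")) exp(1) else as.numeric(log_base)
  if (!is.finite(base) || base <= 0 || base == 1) {
    stop("log_base must be 'natural' or a positive number != 1")
  }
  structure(list(treatment = treatment, control = control, alpha = alpha,
                 lor_threshold = lor_threshold, pseudocount = pseudocount,
                 log_base = base),
            class = "editing_contrast")
}

#' Enumerate candidate C-to-U editing sites in a reference
#'
#' Candidates are every position/strand whose *transcript-sense* reference
#' base is C: plus-strand reference Cs, and minus-strand reference Gs
#' (which read as C on the minus-strand transcript).
#'
#' @param reference A `DNAStringSet`, FASTA path, or named sequences.
#' @return data.frame with columns `sequence`, `position` (1-based),
#'   `strand`.
#' @export
candidate_sites <- function(reference) {
  reference <- as_dnastringset(reference)
  out <- list()
  for (k in seq_along(reference)) {
    chars <- split1(norm_bases(as.character(reference[[k]])))
    plus <- which(chars == "C")
    minus <- which(chars == "G")
    out[[k]] <- data.frame(
      sequence = names(reference)[k],
      position = c(plus, minus),
      strand = rep(c("+", "-"), c(length(plus), length(minus))),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sequence, res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect C-to-U editing against a negative control
#'
#' For every candidate site (transcript-sense reference C on either strand,
#' see [candidate_sites()]) with combined coverage of at least
#' `min_coverage`, builds the 2x2 table a = edited (T) reads in treatment,
#' b = unedited (C) reads in treatment, c/d likewise in the control, and
#' computes: the two-sided Fisher exact p-value over the whole candidate
#' family, Hochberg-adjusted p-values over the same family, the
#' pseudocounted odds ratio and its log, and the percent of edited
#' treatment reads (`NA` when the site has no treatment coverage). A call
#' is `significant` when `p_adj < alpha` *and* the log odds ratio exceeds
#' the contrast's threshold.
#'
#' Optionally annotates each candidate with the predicted binding score of
#' an editing factor at the placement implied by the editing-offset rule
#' ([score_site_table()]).
#'
#' @param treat,ctrl `base_counts` tables for treatment and control over
#'   the same reference (see [count_bases()], [read_base_counts()]).
#' @param reference The reference sequences (`DNAStringSet`, FASTA path, or
#'   named character).
#' @param contrast An [editing_contrast()].
#' @param factor,table Optional [ppr_factor()] and [scoring_table()] for
#'   binding-score annotation.
#' @param min_coverage Minimum combined (treat + control) read count for a
#'   candidate to enter the testing family (default 1, i.e. any coverage).
#' @param circular Passed to [score_site_table()] for binding annotation.
#' @return data.frame of class `editing_calls`, one row per tested
#'   candidate, ordered by sequence, position, strand.
#' @export
detect_editing <- function(treat, ctrl, reference,
                           contrast = editing_contrast(),
                           factor = NULL, table = NULL,
                           min_coverage = 1L, circular = FALSE) {
  stopifnot(inherits(contrast, "editing_contrast"))
  reference <- as_dnastringset(reference)
  for (nm in c("treat", "ctrl")) {
    counts <- get(nm)
    validate_base_counts(counts)
    bad <- !counts$sequence %in% names(reference)
    if (any(bad)) {
      stop(nm, " counts reference unknown sequence(s): ",
           paste(unique(counts$sequence[bad]), collapse = ", "))
    }
  }
  cand <- candidate_sites(reference)
  if (!nrow(cand)) return(empty_editing_calls())
  key <- paste(cand$sequence, cand$position, cand$strand)
  pull <- function(counts, col) {
    i <- match(key, paste(counts$sequence, counts$position, counts$strand))
    out <- ifelse(is.na(i), 0L, counts[[col]][i])
    as.integer(out)
  }
  a <- pull(treat, "n_T"); b <- pull(treat, "n_C")
  c_ <- pull(ctrl, "n_T"); d <- pull(ctrl, "n_C")
  keep <- (a + b + c_ + d) >= max(1L, min_coverage)
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty_editing_calls())
  a <- a[keep]; b <- b[keep]; c_ <- c_[keep]; d <- d[keep]

  p_raw <- fisher_exact(a, b, c_, d)
  p_adj <- hochberg_adjust(p_raw)
  or <- pseudo_odds_ratio(a, b, c_, d, pseudocount = contrast$pseudocount,
                          log_base = contrast$log_base)
  percent <- ifelse(a + b > 0, 100 * a / (a + b), NA_real_)
  calls <- data.frame(
    cand,
    edited_treat = a, unedited_treat = b,
    edited_ctrl = c_, unedited_ctrl = d,
    p_raw = p_raw, p_adj = p_adj,
    odds_ratio = or$odds_ratio, log_odds_ratio = or$log_odds_ratio,
    percent_edited_treat = percent,
    stringsAsFactors = FALSE
  )
  if (!is.null(factor)) {
    if (is.null(table)) stop("binding annotation needs a scoring table")
    sc <- score_site_table(factor, calls[, c("sequence", "position", "strand")],
                           reference, table, circular = circular)
    calls$binding_score <- sc$total_score
  } else {
    calls$binding_score <- NA_real_
  }
  calls$significant <- calls$p_adj < contrast$alpha &
    calls$log_odds_ratio > contrast$lor_threshold
  rownames(calls) <- NULL
  class(calls) <- c("editing_calls", "data.frame")
  calls
}

#' @noRd
empty_editing_calls <- function() {
  df <- data.frame(sequence = character(), position = integer(),
                   strand = character(), edited_treat = integer(),
                   unedited_treat = integer(), edited_ctrl = integer(),
                   unedited_ctrl = integer(), p_raw = numeric(),
                   p_adj = numeric(), odds_ratio = numeric(),
                   log_odds_ratio = numeric(),
                   percent_edited_treat = numeric(),
                   binding_score = numeric(), significant = logical(),
                   stringsAsFactors = FALSE)
  class(df) <- c("editing_calls", "data.frame")
  df
}

#' Write editing calls to a tab-separated file
#'
#' Stable column order: sequence, position, strand, the four contingency
#' counts, p_raw, p_adj, odds_ratio, log_odds_ratio,
#' percent_edited_treat, binding_score, significant.
#'
#' @param calls An `editing_calls` data.frame from [detect_editing()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_editing_calls <- function(calls, file) {
  write.table(calls, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
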