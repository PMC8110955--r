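# Statistics: Fisher exact test, Hochberg step-up adjustment, pseudocounted
# odds ratios, median-of-ratios size factors.

#' Vectorised Fisher exact test for 2x2 tables
#'
#' Conditional on the table margins, the count `a` follows a hypergeometric
#' distribution. The two-sided p-value is the sum of the probabilities of
#' all tables with the observed margins whose probability does not exceed
#' that of the observed table (within relative tolerance 1e-7) -- the
#' standard two-sided rule used by `stats::fisher.test` and the mainstream
#' Python stacks. Arguments recycle, so thousands of candidate sites can be
#' tested in one call.
#'
#' @param a,b,c,d Non-negative integer counts of the 2x2 table(s)
#'   `rbind(c(a, b), c(c, d))`, e.g. edited/unedited x treatment/control.
#' @param alternative `"two.sided"` (default), `"greater"` (first row
#'   enriched in the first column) or `"less"`.
#' @return Numeric vector of p-values in (0, 1].
#' @export
#' @examples
#' fisher_exact(5, 5, 5, 5)      # identical proportions: p = 1
#' fisher_exact(1, 9, 11, 3)
fisher_exact <- function(a, b, c, d,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  counts <- cbind(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  m <- a + b     # row-1 margin
  nn <- c + d    # row-2 margin
  k <- a + c     # column-1 margin
  if (alternative == "greater") {
    return(pmin(1, phyper(a - 1, m, nn, k, lower.tail = FALSE)))
  }
  if (alternative == "less") {
    return(pmin(1, phyper(a, m, nn, k)))
  }
  lo <- pmax(0, k - nn)
  hi <- pmin(k, m)
  sizes <- as.integer(hi - lo + 1)
  idx <- rep.int(seq_len(n), sizes)
  x <- sequence(sizes, from = as.integer(lo))
  p_all <- dhyper(x, m[idx], nn[idx], k[idx])
  p_obs <- dhyper(a, m, nn, k)
  keep <- p_all <= p_obs[idx] * (1 + 1e-7)
  p <- as.numeric(rowsum(p_all * keep, idx, reorder = TRUE))
  pmin(p, 1)
}

#' Hochberg (Simes-Hochberg) step-up p-value adjustment
#'
#' With raw p-values sorted ascending p(1) <= ... <= p(m), the adjusted
#' value for rank i is `min(1, min over j >= i of (m - j + 1) * p(j))`,
#' mapped back to the input order. Controls the family-wise error rate
#' under the usual independence/positive-dependence conditions. Thin
#' validating wrapper around `stats::p.adjust(method = "hochberg")`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order and length as `p`.
#' @export
#' @examples
#' hochberg_adjust(c(0.01, 0.02, 0.03))
hochberg_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (!length(p)) return(numeric(0))
  p.adjust(p, method = "hochberg")
}

#' Pseudocounted odds ratio for a 2x2 table
#'
#' The odds ratio is computed after adding a pseudocount (default 0.5) to
#' all four observations, `OR = ((a + pi) (d + pi)) / ((b + pi) (c + pi))`,
#' so it is finite and positive for every non-negative table, including
#' all-zero tables (OR = 1, log OR = 0). The log is taken in `log_base`
#' (natural by default). Arguments recycle.
#'
#' @param a,b,c,d Non-negative counts (edited treat, unedited treat, edited
#'   control, unedited control).
#' @param pseudocount Positive pseudocount added to all four cells.
#' @param log_base Base of the reported log; `exp(1)`, `2` or `10`.
#' @return data.frame with columns `odds_ratio` and `log_odds_ratio`.
#' @export
#' @examples
#' pseudo_odds_ratio(24, 2654, 0, 2654)   # OR = 49, ln OR ~ 3.89
pseudo_odds_ratio <- function(a, b, c, d, pseudocount = 0.5,
                              log_base = exp(1)) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount <= 0) {
    stop("pseudocount must be a single positive number")
  }
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(cbind(a, b, c, d) < 0)) stop("counts must be non-negative")
  or <- ((a + pseudocount) * (d + pseudocount)) /
    ((b + pseudocount) * (c + pseudocount))
  data.frame(odds_ratio = or, log_odds_ratio = log(or, base = log_base))
}

#' Median-of-ratios size factors with a geometric-mean pseudo-reference
#'
#' The pseudo-reference for each gene is its geometric mean across samples;
#' a sample's size factor is the median over genes of its count divided by
#' the pseudo-reference, using only genes with strictly positive counts in
#' every sample. Normalised counts are counts divided by the size factor.
#' When a `baseline` sample is named, per-gene log2 fold-differences of
#' each sample's normalised counts versus the baseline are also returned.
#'
#' @param counts Numeric matrix of non-negative counts, genes x samples
#'   (>= 2 samples, with column names).
#' @param baseline Optional name (or index) of the baseline sample for
#'   log2 fold-differences.
#' @return A list with `size_factors` (named numeric), `normalised`
#'   (matrix), and, if `baseline` is given, `log2_fold_vs_baseline`.
#' @export
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' size_factors(m)$size_factors   # (1/sqrt(2), sqrt(2))
size_factors <- function(counts, baseline = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) {
    stop("no gene has positive counts in every sample; cannot form the ",
         "pseudo-reference")
  }
  lc <- log(counts[keep, , drop = FALSE])
  ref <- rowMeans(lc)
  sf <- apply(lc, 2, function(x) exp(median(x - ref)))
  normalised <- sweep(counts, 2, sf, "/")
  out <- list(size_factors = sf, normalised = normalised)
  if (!is.null(baseline)) {
    if (is.numeric(baseline)) baseline <- colnames(counts)[baseline]
    if (!baseline %in% colnames(counts)) {
      stop("baseline sample not found: ", baseline)
    }
    out$log2_fold_vs_baseline <-
      log2(normalised / normalised[, baseline])
  }
  out
}
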