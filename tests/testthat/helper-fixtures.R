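# Fixtures built in code: code/scoring tables, scaffolds, factors, SAM
# records, and the brute-force Fisher oracle.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

# canonical-code fixture: A -> TN, C -> NS, G -> TD, U -> ND for all six
# contacting motif types
fixture_code <- function() {
  types <- c("P1", "L1", "S1", "P2", "L2", "S2")
  grid <- expand.grid(motif_type = types,
                      nucleotide = c("A", "C", "G", "U"),
                      stringsAsFactors = FALSE)
  pair <- list(A = c("T", "N"), C = c("N", "S"),
               G = c("T", "D"), U = c("N", "D"))
  grid$fifth <- vapply(grid$nucleotide, function(b) pair[[b]][1], "")
  grid$last <- vapply(grid$nucleotide, function(b) pair[[b]][2], "")
  code_table(grid)
}

# scoring table consistent with fixture_code: each coded pair scores
# `match` on its own base and `mismatch` on the other three
fixture_scoring <- function(match = 1, mismatch = 0, default_score = 0) {
  rows <- data.frame(
    fifth = c("T", "N", "T", "N"),
    last = c("N", "S", "D", "D"),
    A = mismatch, C = mismatch, G = mismatch, U = mismatch,
    stringsAsFactors = FALSE
  )
  rows$A[1] <- match  # TN -> A
  rows$C[2] <- match  # NS -> C
  rows$G[3] <- match  # TD -> G
  rows$U[4] <- match  # ND -> U
  scoring_table(rows, default_score = default_score)
}

# random scores for the four coded pairs, seeded
random_scoring <- function(seed = 1, default_score = 0) {
  set.seed(seed)
  rows <- data.frame(fifth = c("T", "N", "T", "N"),
                     last = c("N", "S", "D", "D"),
                     A = runif(4, -1, 1), C = runif(4, -1, 1),
                     G = runif(4, -1, 1), U = runif(4, -1, 1),
                     stringsAsFactors = FALSE)
  scoring_table(rows, default_score = default_score)
}

# random consensus scaffold for a (P1-L1-S1)3-P2-L2-S2-E1-E2-DYW factor
fixture_scaffold <- function(seed = 1,
                             types = c(rep(c("P1", "L1", "S1"), 3),
                                       "P2", "L2", "S2", "E1", "E2", "DYW"),
                             lengths = NULL) {
  if (is.null(lengths)) {
    lens_by_type <- c(P1 = 35, L1 = 36, S1 = 31, P2 = 35, L2 = 36, S2 = 32,
                      E1 = 34, E2 = 34, DYW = 136)
    lengths <- unname(lens_by_type[types])
  }
  set.seed(seed)
  data.frame(
    type = types,
    triplet_index = NA_integer_,
    consensus = vapply(lengths, function(n) {
      paste(sample(AA20, n, replace = TRUE), collapse = "")
    }, ""),
    stringsAsFactors = FALSE
  )
}

fixture_factor <- function(target = "GAUUCGAAUCGA", seed = 1,
                           name = "dsn3PLS-DYW") {
  design_factor(target, fixture_scaffold(seed = seed), fixture_code(),
                name = name)
}

# minimal single-reference SAM builder; reads: data.frame(pos, flag, seq,
# optional qual)
make_sam <- function(ref_name, ref_len, reads) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", ref_name, "\tLN:", ref_len))
  if (!nrow(reads)) return(header)
  if (is.null(reads$qual)) reads$qual <- strrep("I", nchar(reads$seq))
  recs <- sprintf("r%03d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                  seq_len(nrow(reads)), reads$flag, ref_name, reads$pos,
                  nchar(reads$seq), reads$seq, reads$qual)
  c(header, recs)
}

counts_from_sam_lines <- function(lines, ...) {
  f <- tempfile(fileext = ".sam")
  writeLines(lines, f)
  on.exit(unlink(f))
  count_bases(f, ...)
}

# independent two-sided Fisher oracle: explicit enumeration of all tables
# with the observed margins, probabilities from choose()
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; nn <- c + d; k <- a + c
  support <- max(0, k - nn):min(k, m)
  pr <- choose(m, support) * choose(nn, k - support) / choose(m + nn, k)
  pobs <- choose(m, a) * choose(nn, c) / choose(m + nn, k)
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# re-derive the code lookup independently of design_factor's internals
code_lookup_public <- function(code, type, base) {
  base <- chartr("U", "T", base)
  idx <- match(paste(type, base), paste(code$motif_type, code$nucleotide))
  data.frame(fifth = code$fifth[idx], last = code$last[idx])
}

# base-count table with explicit counts at given sites, zero elsewhere
manual_counts <- function(sequence, position, strand, n_C, n_T,
                          sample = "s") {
  df <- data.frame(sequence = sequence, position = as.integer(position),
                   strand = strand, n_A = 0L, n_C = as.integer(n_C),
                   n_G = 0L, n_T = as.integer(n_T), sample = sample,
                   stringsAsFactors = FALSE)
  class(df) <- c("base_counts", "data.frame")
  df
}
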