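# Motif model: PPR motifs, factors, code tables and motif alignments.

#' Construct a PPR editing factor
#'
#' A factor is an ordered list of PPR motifs, each with a type label and the
#' two specificity-determining residues (5th and last position of the
#' motif), plus an N-terminal cap peptide. Motif order must follow the
#' PLS-class grammar: a run of P1-L1-S1 triplets (possibly truncated after
#' the last complete motif), then optionally P2, L2, S2, E1, E2 and DYW in
#' that order. The DYW domain carries no contact residues (wildcard `"-"`
#' only).
#'
#' @param name Factor name.
#' @param motifs A data.frame with columns `type` (see [ppr_motif_types()]),
#'   `fifth` and `last` (one-letter amino-acid codes, or `"-"` for
#'   unspecified), and optionally `triplet_index` (position of the parent
#'   P1-L1-S1 triplet; auto-assigned when absent) and `sequence` (full
#'   amino-acid string of the motif).
#' @param cap Amino-acid string prepended before the first motif. The
#'   shipped default is the Met-Gly-Asn-Ser cap (`"MGNS"`); a Met-Gly-Asp-Ser
#'   variant (`"MGDS"`) is also in circulation and can be supplied instead.
#' @return An object of class `ppr_factor`.
#' @seealso [read_ppr_factor()], [design_factor()]
#' @export
#' @examples
#' ppr_factor("toy", data.frame(type = "P1", fifth = "T", last = "D"))
ppr_factor <- function(name, motifs, cap = "MGNS") {
  stopifnot(is.character(name), length(name) == 1L)
  motifs <- as.data.frame(motifs, stringsAsFactors = FALSE)
  required <- c("type", "fifth", "last")
  missing_cols <- setdiff(required, names(motifs))
  if (length(missing_cols)) {
    stop("motifs is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(motifs) == 0L) stop("a factor needs at least one motif")
  bad <- !motifs$type %in% MOTIF_TYPES
  if (any(bad)) {
    stop("unknown motif type(s): ", paste(unique(motifs$type[bad]), collapse = ", "))
  }
  check_motif_order(motifs$type)
  for (col in c("fifth", "last")) {
    ok <- motifs[[col]] %in% c(AA_ALPHABET, "-")
    if (!all(ok)) {
      stop("invalid ", col, " residue(s): ",
           paste(unique(motifs[[col]][!ok]), collapse = ", "))
    }
  }
  dyw <- motifs$type == "DYW"
  if (any(dyw & (motifs$fifth != "-" | motifs$last != "-"))) {
    stop("DYW motifs carry no contact residues; use '-' for fifth/last")
  }
  if (!"triplet_index" %in% names(motifs)) {
    motifs$triplet_index <- NA_integer_
  }
  pls1 <- motifs$type %in% c("P1", "L1", "S1")
  motifs$triplet_index[pls1] <- cumsum(motifs$type == "P1")[pls1]
  motifs$triplet_index <- as.integer(motifs$triplet_index)
  if (!"sequence" %in% names(motifs)) motifs$sequence <- NA_character_
  if (sum(motifs$type %in% CONTACT_TYPES) < 1L) {
    stop("a factor needs at least one nucleotide-contacting motif")
  }
  if (!is.character(cap) || length(cap) != 1L ||
      !all(split1(cap) %in% AA_ALPHABET)) {
    stop("cap must be a single amino-acid string")
  }
  structure(
    list(name = name,
         motifs = motifs[, c("type", "fifth", "last", "triplet_index", "sequence")],
         cap = cap),
    class = "ppr_factor"
  )
}

# PLS-class motif order grammar: cyclic P1-L1-S1 block (must start at P1),
# then a subsequence of P2, L2, S2, E1, E2, DYW in order.
#' @noRd
check_motif_order <- function(types) {
  n <- length(types)
  cyc <- c("P1", "L1", "S1")
  i <- 1L
  j <- 0L
  while (i <= n && types[i] %in% cyc) {
    expected <- cyc[j %% 3L + 1L]
    if (types[i] != expected) {
      stop("motif order violation at motif ", i, ": expected ", expected,
           " in the P1-L1-S1 block, got ", types[i])
    }
    j <- j + 1L
    i <- i + 1L
  }
  if (j == 0L) stop("motif order violation: factor must begin with a P1 motif")
  tail_order <- c("P2", "L2", "S2", "E1", "E2", "DYW")
  pos <- 0L
  while (i <= n) {
    k <- match(types[i], tail_order)
    if (is.na(k)) {
      stop("motif order violation at motif ", i, ": ", types[i],
           " cannot follow the C-terminal block")
    }
    if (k <= pos) {
      stop("motif order violation at motif ", i, ": ", types[i],
           " out of order in the C-terminal block")
    }
    pos <- k
    i <- i + 1L
  }
  invisible(TRUE)
}

#' @export
print.ppr_factor <- function(x, ...) {
  cat("<ppr_factor> ", x$name, "\n", sep = "")
  cat("  cap: ", x$cap, "\n", sep = "")
  cat("  motifs: ", paste(x$motifs$type, collapse = "-"),
      " (", n_contacting(x), " contacting)\n", sep = "")
  pairs <- paste0(x$motifs$fifth, x$motifs$last)
  cat("  5/last pairs: ", paste(pairs, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Which motifs of a factor contact RNA
#'
#' P1, L1, S1, P2, L2 and S2 motifs each contact exactly one base; E1, E2 and
#' DYW contact none.
#'
#' @param factor A [ppr_factor()].
#' @return Logical vector over the factor's motifs (`is_contacting`), or the
#'   number of contacting motifs (`n_contacting`).
#' @export
is_contacting <- function(factor) {
  stopifnot(inherits(factor, "ppr_factor"))
  factor$motifs$type %in% CONTACT_TYPES
}

#' @rdname is_contacting
#' @export
n_contacting <- function(factor) sum(is_contacting(factor))

#' Assemble the full protein sequence of a factor
#'
#' Concatenates the cap and the per-motif amino-acid sequences. All motifs
#' must carry a `sequence` (as produced by [design_factor()]).
#'
#' @param factor A [ppr_factor()].
#' @return A single amino-acid string.
#' @export
factor_protein <- function(factor) {
  stopifnot(inherits(factor, "ppr_factor"))
  if (anyNA(factor$motifs$sequence)) {
    stop("factor '", factor$name, "' has motifs without sequences")
  }
  paste0(factor$cap, paste(factor$motifs$sequence, collapse = ""))
}

# Factor definition files ----------------------------------------------------

#' Read and write PPR factor definition files
#'
#' Plain-text format: one motif per line as `TYPE<TAB>FIFTH<TAB>LAST`
#' (any whitespace accepted), `#` comments, and optional header lines
#' `name=...` and `cap=...`. Motif order is validated on read.
#'
#' @param file Path to a factor definition file.
#' @return `read_ppr_factor` returns a [ppr_factor()];
#'   `write_ppr_factor` returns `file`, invisibly.
#' @export
read_ppr_factor <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  name <- tools::file_path_sans_ext(basename(file))
  cap <- "MGNS"
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^name\\s*=", ln)) {
      name <- trimws(sub("^name\\s*=", "", ln))
      next
    }
    if (grepl("^cap\\s*=", ln)) {
      cap <- trimws(sub("^cap\\s*=", "", ln))
      next
    }
    fields <- strsplit(ln, "\\s+")[[1]]
    if (length(fields) < 3L) {
      stop(file, " line ", lineno[i],
           ": expected 'TYPE FIFTH LAST', got '", ln, "'")
    }
    rows[[length(rows) + 1L]] <-
      data.frame(type = fields[1], fifth = fields[2], last = fields[3],
                 stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop(file, ": no motif lines found")
  motifs <- do.call(rbind, rows)
  tryCatch(
    ppr_factor(name, motifs, cap = cap),
    error = function(e) stop(file, ": ", conditionMessage(e), call. = FALSE)
  )
}

#' @rdname read_ppr_factor
#' @param factor A [ppr_factor()] to write.
#' @export
write_ppr_factor <- function(factor, file) {
  stopifnot(inherits(factor, "ppr_factor"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste0("name=", factor$name), paste0("cap=", factor$cap)), con)
  writeLines(paste(factor$motifs$type, factor$motifs$fifth,
                   factor$motifs$last, sep = "\t"), con)
  invisible(file)
}

# Code tables -----------------------------------------------------------------

#' Read a PPR code table
#'
#' The code table is the inverse recognition map used for design: for each
#' (motif type, target nucleotide) it gives the (5th, last) residue pair to
#' program into that motif. Delimited file with columns `motif_type`,
#' `nucleotide`, `fifth`, `last`. A default table encoding the canonical
#' code (TD -> G, TN -> A, ND -> U, NS -> C) ships with the package:
#' `system.file("extdata", "ppr_code_default.tsv", package = "ppredit")`.
#'
#' @param file Path to a tab-separated code table.
#' @return A data.frame of class `ppr_code`.
#' @export
read_code_table <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("motif_type", "nucleotide", "fifth", "last")
  if (!all(required %in% names(tab))) {
    stop("code table must have columns: ", paste(required, collapse = ", "))
  }
  tab$nucleotide <- norm_bases(tab$nucleotide)
  bad <- !tab$motif_type %in% MOTIF_TYPES
  if (any(bad)) stop("code table has unknown motif type(s): ",
                     paste(unique(tab$motif_type[bad]), collapse = ", "))
  if (anyDuplicated(paste(tab$motif_type, tab$nucleotide))) {
    stop("code table has duplicated (motif_type, nucleotide) keys")
  }
  class(tab) <- c("ppr_code", "data.frame")
  tab
}

#' Build a code table from a data.frame
#'
#' @param entries data.frame with columns `motif_type`, `nucleotide`
#'   (A/C/G/U, T accepted), `fifth`, `last`.
#' @return A data.frame of class `ppr_code`.
#' @export
code_table <- function(entries) {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write.table(entries, f, sep = "\t", quote = FALSE, row.names = FALSE)
  read_code_table(f)
}

# lookup; error (listing the missing pairs) when a key is absent
#' @noRd
code_lookup <- function(code, motif_type, nucleotide) {
  stopifnot(inherits(code, "ppr_code"))
  nucleotide <- norm_bases(nucleotide)
  key <- paste(motif_type, nucleotide)
  idx <- match(key, paste(code$motif_type, code$nucleotide))
  if (anyNA(idx)) {
    miss <- unique(key[is.na(idx)])
    stop("code table has no entry for: ",
         paste(sub(" ", "/", miss), collapse = ", "))
  }
  data.frame(fifth = code$fifth[idx], last = code$last[idx],
             stringsAsFactors = FALSE)
}

# Motif alignment collections -------------------------------------------------

#' Read an aligned motif collection from FASTA
#'
#' Aligned amino-acid FASTA in which each record's description encodes the
#' motif type and (for P1/L1/S1) the triplet index as `type=P1 triplet=2`.
#' Records are grouped by (type, triplet index); each group is one aligned
#' collection from which [build_consensus()] can derive a position-specific
#' consensus.
#'
#' @param file Path to an aligned FASTA file.
#' @return A named list of character vectors of aligned sequences; names are
#'   `"P1.2"`-style `type.triplet` keys (`type` alone when no triplet).
#' @export
read_motif_alignment <- function(file) {
  aa <- Biostrings::readAAStringSet(file)
  if (!length(aa)) stop(file, ": empty alignment file")
  desc <- names(aa)
  type <- sub(".*type=([A-Z0-9]+).*", "\\1", desc)
  bad <- !grepl("type=", desc) | !type %in% MOTIF_TYPES
  if (any(bad)) {
    stop(file, ": record(s) without a valid 'type=' tag: ",
         paste(head(desc[bad], 3), collapse = "; "))
  }
  triplet <- rep(NA_integer_, length(desc))
  has_tr <- grepl("triplet=", desc)
  triplet[has_tr] <- as.integer(sub(".*triplet=([0-9]+).*", "\\1", desc[has_tr]))
  key <- ifelse(is.na(triplet), type, paste(type, triplet, sep = "."))
  split(as.character(aa), key)
}

#' Plurality consensus of aligned amino-acid sequences
#'
#' Per column, returns the residue with the highest count over the aligned
#' sequences -- a plurality call with no minimum threshold ("plurality 0").
#' Gaps (`-`) are excluded from the counts and never win a column; a column
#' consisting only of gaps is dropped from the output. Ties are broken by
#' the fixed canonical one-letter amino-acid order (alphabetical), so the
#' result is deterministic.
#'
#' @param aligned Character vector of equal-length aligned amino-acid
#'   strings (letters and `-` gaps).
#' @return The consensus amino-acid string (length = alignment length minus
#'   all-gap columns).
#' @export
#' @examples
#' build_consensus(c("AAD", "ACD", "ACD"))
build_consensus <- function(aligned) {
  if (!is.character(aligned) || length(aligned) < 1L) {
    stop("need at least one aligned sequence")
  }
  aligned <- toupper(aligned)
  widths <- nchar(aligned)
  if (length(unique(widths)) != 1L) {
    stop("aligned sequences must all have the same length")
  }
  if (widths[1] == 0L) stop("aligned sequences must be non-empty")
  mat <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  ok <- mat %in% c(AA_ALPHABET, "-")
  if (!all(ok)) {
    stop("invalid residue character(s): ",
         paste(unique(mat[!ok]), collapse = ", "))
  }
  cols <- apply(mat, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(NA_character_)
    counts <- table(factor(col, levels = AA_ALPHABET))
    names(counts)[which.max(counts)]  # ties: first in canonical A<C<D<... order
  })
  paste(cols[!is.na(cols)], collapse = "")
}

# Factor design ---------------------------------------------------------------

#' Design a PPR editing factor against a target RNA
#'
#' Programs the 5th/last residues of the scaffold's contacting motifs so the
#' factor binds `target_rna`, using the code table; motifs listed in
#' `fixed_tail` are not programmed from the target and instead carry the
#' supplied residues (the classic design fixes L2, S2, E1 and E2 to the
#' residues of a natural factor). The residues are substituted into each
#' motif's consensus sequence at the 5th and final positions, and the cap is
#' prepended.
#'
#' Contacting motifs (P1/L1/S1/P2/L2/S2) align one-to-one, 5' to 3', with
#' the target window; `target_rna` supplies one base per *programmed*
#' contacting motif, in order. The design target for the full contacting
#' window is recorded in the `design_target` attribute of the result (for
#' fixed-tail contacting motifs the aligned base is unspecified and recorded
#' as `N`).
#'
#' @param target_rna Nucleotide string (A/C/G/U; T accepted), one base per
#'   programmed contacting motif.
#' @param scaffold data.frame with columns `type`, `triplet_index` (NA for
#'   non-triplet motifs) and `consensus` (amino-acid string per motif, at
#'   least 5 residues), in factor order.
#' @param code A `ppr_code` table ([read_code_table()]).
#' @param fixed_tail Named list mapping motif types to `c(fifth, last)`
#'   residue pairs for motifs not programmed from the target.
#' @param cap Cap peptide, prepended to the first motif (default `"MGNS"`).
#' @param name Name for the designed factor.
#' @return A [ppr_factor()] with per-motif sequences and a `design_target`
#'   attribute.
#' @export
design_factor <- function(target_rna, scaffold, code, fixed_tail = list(),
                          cap = "MGNS", name = "designed") {
  scaffold <- as.data.frame(scaffold, stringsAsFactors = FALSE)
  required <- c("type", "consensus")
  if (!all(required %in% names(scaffold))) {
    stop("scaffold must have columns: ", paste(required, collapse = ", "))
  }
  if (!"triplet_index" %in% names(scaffold)) {
    scaffold$triplet_index <- NA_integer_
  }
  check_motif_order(scaffold$type)
  if (any(nchar(scaffold$consensus) < 5L & scaffold$type != "DYW")) {
    stop("motif consensus sequences must have at least 5 residues")
  }
  if (length(fixed_tail)) {
    badft <- !names(fixed_tail) %in% MOTIF_TYPES
    if (any(badft)) {
      stop("fixed_tail has unknown motif type(s): ",
           paste(names(fixed_tail)[badft], collapse = ", "))
    }
  }
  contacting <- scaffold$type %in% CONTACT_TYPES
  fixed <- scaffold$type %in% names(fixed_tail)
  programmed <- contacting & !fixed

  target <- norm_bases(target_rna)
  bases <- if (nchar(target)) split1(target) else character(0)
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("target_rna must use the A/C/G/U alphabet")
  }
  if (length(bases) != sum(programmed)) {
    stop("target length (", length(bases), ") must equal the number of ",
         "programmed contacting motifs (", sum(programmed), ")")
  }

  n <- nrow(scaffold)
  fifth <- rep("-", n)
  last <- rep("-", n)
  if (any(programmed)) {
    pairs <- code_lookup(code, scaffold$type[programmed], bases)
    fifth[programmed] <- pairs$fifth
    last[programmed] <- pairs$last
  }
  for (i in which(fixed)) {
    pair <- fixed_tail[[scaffold$type[i]]]
    if (length(pair) != 2L) {
      stop("fixed_tail entries must be length-2 (fifth, last) pairs")
    }
    fifth[i] <- pair[1]
    last[i] <- pair[2]
  }
  # unfixed non-contacting motifs keep their consensus residues
  passive <- !contacting & !fixed & scaffold$type != "DYW"
  fifth[passive] <- substr(scaffold$consensus[passive], 5L, 5L)
  last[passive] <- vapply(scaffold$consensus[passive],
                          function(s) substr(s, nchar(s), nchar(s)), "")

  seqs <- scaffold$consensus
  set_pair <- which(fifth != "-" | last != "-")
  for (i in set_pair) {
    s <- seqs[i]
    if (fifth[i] != "-") substr(s, 5L, 5L) <- fifth[i]
    if (last[i] != "-") substr(s, nchar(s), nchar(s)) <- last[i]
    seqs[i] <- s
  }

  fac <- ppr_factor(name,
                    data.frame(type = scaffold$type, fifth = fifth, last = last,
                               triplet_index = scaffold$triplet_index,
                               sequence = seqs, stringsAsFactors = FALSE),
                    cap = cap)
  full_target <- character(sum(contacting))
  full_target[programmed[contacting]] <- bases
  full_target[!programmed[contacting]] <- "N"
  attr(fac, "design_target") <- paste(full_target, collapse = "")
  fac
}
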