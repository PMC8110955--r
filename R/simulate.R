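# Synthetic data with recorded ground truth: genomes with planted binding
# and editing sites, strand-specific base-count tables, SAM read sets, and
# aligned motif collections.

# role-specific RNG substreams derived from the truth seed
#' @noRd
role_seed <- function(seed, role = c("treatment", "control"), extra = 0L) {
  role <- match.arg(role)
  off <- c(treatment = 101L, control = 202L)[[role]]
  (as.integer(seed) + off + as.integer(extra)) %% .Machine$integer.max
}

#' Simulate a chloroplast-like reference genome
#'
#' Generates a single named sequence with i.i.d. bases at the requested GC
#' content, plus an empty `synthetic_truth` record that downstream planting
#' and count simulation fill in. Fully deterministic under `seed`.
#'
#' The truth object records everything needed to regenerate the dataset:
#' the seed, planted binding/editing sites with their efficiencies, the
#' mean per-strand coverage, the per-base miscall rate, and the optional
#' multiplicative efficiency penalty applied when the base 5' of the edited
#' C (position -1) is a purine -- purines there inhibit editing; the
#' penalty is off (`NULL`) by default.
#'
#' @param length Sequence length (bases).
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed.
#' @param name Sequence name.
#' @param coverage Mean per-position, per-strand read depth (Poisson mean)
#'   used by [simulate_counts()]. The default 500 reflects the deep
#'   organellar RNA-seq this generator emulates.
#' @param error_rate Per-base miscall probability (default 0.001).
#' @param minus_one_purine_penalty Optional multiplier in \[0, 1\] applied
#'   to editing efficiency when the -1 base is a purine; `NULL` disables.
#' @return A list of class `ppr_simulation` with elements `genome`
#'   (a named `DNAStringSet`) and `truth` (class `synthetic_truth`).
#' @export
simulate_genome <- function(length, gc = 0.5, seed = 1L,
                            name = "synthetic_plastid", coverage = 500,
                            error_rate = 0.001,
                            minus_one_purine_penalty = NULL) {
  stopifnot(length >= 1, gc > 0, gc < 1)
  set.seed(as.integer(seed))
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- name
  truth <- structure(
    list(seed = as.integer(seed), sequence_name = name,
         length = as.integer(length), gc = gc,
         coverage = coverage, error_rate = error_rate,
         minus_one_purine_penalty = minus_one_purine_penalty,
         binding_sites = data.frame(position = integer(), strand = character(),
                                    window = character(),
                                    stringsAsFactors = FALSE),
         editing_sites = data.frame(position = integer(), strand = character(),
                                    efficiency_treatment = numeric(),
                                    efficiency_control = numeric(),
                                    stringsAsFactors = FALSE)),
    class = "synthetic_truth"
  )
  structure(list(genome = genome, truth = truth), class = "ppr_simulation")
}

#' Plant a factor's target site into a simulated genome
#'
#' Replaces background bases with the factor's designed target window
#' (one base per contacting motif), a 3-base spacer, and a C at the
#' editing-offset position (4 nt 3' of the S2-aligned base), then records
#' both the binding site and the editing site (with the given efficiencies)
#' in the truth. On the minus strand the reverse complement is inserted and
#' the recorded coordinates refer to the forward strand.
#'
#' @param sim A `ppr_simulation` from [simulate_genome()].
#' @param target The target window for the contacting motifs (A/C/G/U
#'   string), e.g. the `design_target` attribute of a designed factor.
#' @param at 1-based forward-strand coordinate for the leftmost planted
#'   base.
#' @param strand `"+"` or `"-"`.
#' @param efficiency_treatment,efficiency_control True editing fractions
#'   in \[0, 1\] for the planted site in each sample role.
#' @param spacer 3-base spacer between the window and the edited C; the
#'   default ends in a pyrimidine at -1 so the purine penalty, if enabled,
#'   does not apply.
#' @return The updated `ppr_simulation`.
#' @export
plant_target <- function(sim, target, at, strand = "+",
                         efficiency_treatment = 0.4,
                         efficiency_control = 0, spacer = "TCT") {
  stopifnot(inherits(sim, "ppr_simulation"))
  target <- norm_bases(target)
  if (grepl("N", target, fixed = TRUE)) {
    stop("target window contains unspecified (N) bases; supply a fully ",
         "specified window")
  }
  if (nchar(spacer) != EDIT_OFFSET - 1L) {
    stop("spacer must have ", EDIT_OFFSET - 1L, " bases")
  }
  insert <- paste0(target, norm_bases(spacer), "C")
  len <- nchar(insert)
  L <- sim$truth$length
  if (at < 1L || at + len - 1L > L) {
    stop("planted site [", at, ", ", at + len - 1L,
         "] does not fit in the sequence (length ", L, ")")
  }
  fwd <- if (strand == "+") insert else revcomp_chr(insert)
  seqchars <- split1(as.character(sim$genome[[1]]))
  seqchars[at:(at + len - 1L)] <- split1(fwd)
  genome <- Biostrings::DNAStringSet(paste(seqchars, collapse = ""))
  names(genome) <- sim$truth$sequence_name
  sim$genome <- genome
  edit_pos <- if (strand == "+") at + len - 1L else at
  sim$truth$binding_sites <- rbind(
    sim$truth$binding_sites,
    data.frame(position = if (strand == "+") at else at + len - 1L,
               strand = strand, window = target, stringsAsFactors = FALSE)
  )
  sim$truth$editing_sites <- rbind(
    sim$truth$editing_sites,
    data.frame(position = as.integer(edit_pos), strand = strand,
               efficiency_treatment = efficiency_treatment,
               efficiency_control = efficiency_control,
               stringsAsFactors = FALSE)
  )
  sim
}

#' Plant differential editing at existing C positions
#'
#' Selects `n` transcript-sense C positions (plus-strand Cs or minus-strand
#' Gs) not already used and records them as editing sites with the given
#' efficiencies. Selection is deterministic under the truth seed.
#'
#' @param sim A `ppr_simulation`.
#' @param n Number of sites to plant.
#' @param efficiency_treatment,efficiency_control Editing fractions.
#' @param strand Strand of the planted sites.
#' @return The updated `ppr_simulation`.
#' @export
plant_editing_sites <- function(sim, n, efficiency_treatment,
                                efficiency_control = 0, strand = "+") {
  stopifnot(inherits(sim, "ppr_simulation"))
  chars <- split1(as.character(sim$genome[[1]]))
  want <- if (strand == "+") "C" else "G"
  avail <- which(chars == want)
  used <- sim$truth$editing_sites$position[
    sim$truth$editing_sites$strand == strand]
  avail <- setdiff(avail, used)
  if (length(avail) < n) stop("not enough candidate C positions to plant")
  set.seed(role_seed(sim$truth$seed, "treatment", extra = 7777L))
  pos <- sort(sample(avail, n))
  sim$truth$editing_sites <- rbind(
    sim$truth$editing_sites,
    data.frame(position = as.integer(pos), strand = strand,
               efficiency_treatment = efficiency_treatment,
               efficiency_control = efficiency_control,
               stringsAsFactors = FALSE)
  )
  sim
}

# per-position editing fraction applied to transcript-sense C positions,
# with the optional -1 purine penalty
#' @noRd
effective_efficiency <- function(sim, role) {
  es <- sim$truth$editing_sites
  if (!nrow(es)) return(es)
  eff <- if (role == "treatment") es$efficiency_treatment else
    es$efficiency_control
  pen <- sim$truth$minus_one_purine_penalty
  if (!is.null(pen)) {
    chars <- split1(as.character(sim$genome[[1]]))
    L <- sim$truth$length
    minus1 <- ifelse(es$strand == "+", es$position - 1L, es$position + 1L)
    ok <- minus1 >= 1L & minus1 <= L
    m1base <- rep(NA_character_, nrow(es))
    m1base[ok] <- chars[minus1[ok]]
    sel <- es$strand == "-" & ok
    m1base[sel] <- comp_chr_vec(m1base[sel])
    purine <- !is.na(m1base) & m1base %in% c("A", "G")
    eff[purine] <- eff[purine] * pen
  }
  data.frame(position = es$position, strand = es$strand, efficiency = eff,
             stringsAsFactors = FALSE)
}

#' Simulate a strand-specific base-count table
#'
#' Per position and strand, read depth is Poisson with the truth's mean
#' coverage. At transcript-sense C positions the edited fraction is the
#' planted efficiency for the sample role (0 elsewhere), modulated by the
#' optional -1 purine penalty; each read is then miscalled with the truth's
#' error rate, uniformly over the three other bases. All draws come from a
#' seeded, role-dependent substream, so regenerating from the same truth
#' and role is byte-identical.
#'
#' @param sim A `ppr_simulation`.
#' @param role `"treatment"` or `"control"`.
#' @return A `base_counts` data.frame (see [count_bases()]) covering every
#'   position on both strands.
#' @export
simulate_counts <- function(sim, role = c("treatment", "control")) {
  role <- match.arg(role)
  stopifnot(inherits(sim, "ppr_simulation"))
  truth <- sim$truth
  set.seed(role_seed(truth$seed, role))
  chars <- split1(as.character(sim$genome[[1]]))
  L <- truth$length
  e <- truth$error_rate
  eff_tab <- effective_efficiency(sim, role)
  out <- list()
  for (strand in c("+", "-")) {
    tx_ref <- if (strand == "+") chars else comp_chr_vec(chars)
    depth <- rpois(L, truth$coverage)
    eff <- numeric(L)
    es <- eff_tab[eff_tab$strand == strand, , drop = FALSE]
    eff[es$position] <- es$efficiency
    # per-read base probabilities in transcript sense
    p <- matrix(e / 3, nrow = L, ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    ref_i <- match(tx_ref, c("A", "C", "G", "T"))
    p[cbind(seq_len(L), ref_i)] <- 1 - e
    isC <- tx_ref == "C"
    p[isC, "T"] <- eff[isC] * (1 - e) + (1 - eff[isC]) * (e / 3)
    p[isC, "C"] <- (1 - eff[isC]) * (1 - e) + eff[isC] * (e / 3)
    # sequential binomial thinning = multinomial draw, vectorised
    n_T <- rbinom(L, depth, p[, "T"])
    rem <- depth - n_T
    p_C <- p[, "C"] / pmax(1 - p[, "T"], .Machine$double.eps)
    n_C <- rbinom(L, rem, pmin(p_C, 1))
    rem <- rem - n_C
    p_A <- p[, "A"] / pmax(1 - p[, "T"] - p[, "C"], .Machine$double.eps)
    n_A <- rbinom(L, rem, pmin(p_A, 1))
    n_G <- rem - n_A
    out[[strand]] <- data.frame(
      sequence = truth$sequence_name, position = seq_len(L), strand = strand,
      n_A = n_A, n_C = n_C, n_G = n_G, n_T = n_T, sample = role,
      stringsAsFactors = FALSE
    )
  }
  res <- rbind(out[["+"]], out[["-"]])
  res <- res[order(res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("base_counts", "data.frame")
  res
}

#' Simulate stranded SAM reads consistent with the truth
#'
#' Places `n_reads` ungapped single-end reads uniformly along the genome on
#' both strands. Each read reports transcript-sense bases drawn with the
#' same editing/error model as [simulate_counts()], stored in the SAM
#' record in reference-forward orientation (flag 16 for minus-strand
#' reads), so [count_bases()] on the output recovers the planted editing
#' fractions. Byte-identical under a fixed seed.
#'
#' @param sim A `ppr_simulation`.
#' @param n_reads Number of reads.
#' @param read_length Read length (<= genome length).
#' @param role `"treatment"` or `"control"`.
#' @param seed Optional seed override; defaults to a role-dependent
#'   substream of the truth seed.
#' @return Character vector of SAM lines (header plus alignments); write
#'   with [write_sam()].
#' @export
simulate_sam <- function(sim, n_reads, read_length = 75L,
                         role = c("treatment", "control"), seed = NULL) {
  role <- match.arg(role)
  stopifnot(inherits(sim, "ppr_simulation"))
  truth <- sim$truth
  L <- truth$length
  if (read_length > L) stop("read_length exceeds genome length")
  if (is.null(seed)) seed <- role_seed(truth$seed, role, extra = 5000L)
  set.seed(as.integer(seed))
  chars <- split1(as.character(sim$genome[[1]]))
  e <- truth$error_rate
  eff_tab <- effective_efficiency(sim, role)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", truth$sequence_name, "\tLN:", L))
  if (n_reads == 0L) return(header)
  starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  qual <- strrep("I", read_length)
  cigar <- paste0(read_length, "M")
  recs <- character(n_reads)
  eff_key <- paste(eff_tab$position, eff_tab$strand)
  for (i in seq_len(n_reads)) {
    coords <- starts[i]:(starts[i] + read_length - 1L)
    w <- chars[coords]
    if (strands[i] == "-") {
      tx <- comp_chr_vec(rev(w))
      tx_coords <- rev(coords)
    } else {
      tx <- w
      tx_coords <- coords
    }
    # editing: transcript-sense C at a planted site flips to T w.p. eff
    hit <- match(paste(tx_coords, strands[i]), eff_key)
    eff <- ifelse(is.na(hit), 0, eff_tab$efficiency[hit])
    can_edit <- tx == "C" & eff > 0
    if (any(can_edit)) {
      flip <- runif(sum(can_edit)) < eff[can_edit]
      tx[can_edit][flip] <- "T"
    }
    # sequencing errors, uniform over the three other bases
    err <- runif(read_length) < e
    if (any(err)) {
      tx[err] <- vapply(tx[err], function(bse) {
        sample(setdiff(c("A", "C", "G", "T"), bse), 1L)
      }, "")
    }
    seqf <- if (strands[i] == "-") paste(comp_chr_vec(rev(tx)), collapse = "")
            else paste(tx, collapse = "")
    flag <- if (strands[i] == "-") 16L else 0L
    recs[i] <- paste(sprintf("read%06d", i), flag, truth$sequence_name,
                     starts[i], 60L, cigar, "*", 0L, 0L, seqf, qual,
                     sep = "\t")
  }
  c(header, recs)
}

#' Write SAM lines to a file
#'
#' @param sam Character vector of SAM lines (from [simulate_sam()]).
#' @param file Output path (conventionally `.sam`).
#' @return `file`, invisibly.
#' @export
write_sam <- function(sam, file) {
  writeLines(sam, file)
  invisible(file)
}

#' Simulate an aligned motif collection around a consensus
#'
#' Each sequence is the consensus with independent per-column substitutions
#' at probability `divergence` (to a uniformly chosen different residue) --
#' a miniature of the large multi-species motif alignments from which
#' position-specific consensuses are built. For `divergence < 0.5` the
#' plurality consensus of the collection converges to the input consensus
#' as `n` grows.
#'
#' @param n Number of sequences.
#' @param consensus Amino-acid string (the generating consensus).
#' @param divergence Per-column substitution probability in \[0, 0.5).
#' @param seed Integer seed.
#' @param type,triplet Optional motif type and triplet index encoded into
#'   the FASTA descriptions as `type=P1 triplet=2`.
#' @return Named character vector of aligned sequences; write with
#'   [write_motif_collection()].
#' @export
simulate_motif_collection <- function(n, consensus, divergence = 0.2,
                                      seed = 1L, type = NULL,
                                      triplet = NULL) {
  stopifnot(divergence >= 0, divergence < 0.5, n >= 1)
  set.seed(as.integer(seed))
  cons <- split1(toupper(consensus))
  stopifnot(all(cons %in% AA_ALPHABET))
  len <- length(cons)
  seqs <- vapply(seq_len(n), function(i) {
    s <- cons
    mut <- runif(len) < divergence
    if (any(mut)) {
      s[mut] <- vapply(s[mut], function(r) {
        sample(setdiff(AA_ALPHABET, r), 1L)
      }, "")
    }
    paste(s, collapse = "")
  }, "")
  tag <- ""
  if (!is.null(type)) {
    tag <- paste0(" type=", type,
                  if (!is.null(triplet)) paste0(" triplet=", triplet) else "")
  }
  names(seqs) <- paste0(sprintf("motif%04d", seq_len(n)), tag)
  seqs
}

#' @rdname simulate_motif_collection
#' @param seqs Named character vector of aligned sequences.
#' @param file Output FASTA path.
#' @export
write_motif_collection <- function(seqs, file) {
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, file)
  invisible(file)
}

# Truth serialisation ---------------------------------------------------------

#' Serialise and restore synthetic ground truth
#'
#' YAML round-trip of a `synthetic_truth` record. Regenerating counts from
#' the restored truth (plus the genome) reproduces the originals
#' byte-identically, since all draws are keyed on the recorded seed.
#'
#' @param truth A `synthetic_truth` (the `truth` element of a
#'   `ppr_simulation`).
#' @param file Path to a YAML file.
#' @return `read_truth` returns a `synthetic_truth`; `write_truth` returns
#'   `file`, invisibly.
#' @export
write_truth <- function(truth, file) {
  stopifnot(inherits(truth, "synthetic_truth"))
  obj <- unclass(truth)
  obj$binding_sites <- as.list(truth$binding_sites)
  obj$editing_sites <- as.list(truth$editing_sites)
  yaml::write_yaml(obj, file, precision = 15)
  invisible(file)
}

#' @rdname write_truth
#' @export
read_truth <- function(file) {
  obj <- yaml::read_yaml(file)
  bs <- obj$binding_sites
  es <- obj$editing_sites
  obj$binding_sites <- data.frame(
    position = as.integer(unlist(bs$position)),
    strand = as.character(unlist(bs$strand)),
    window = as.character(unlist(bs$window)),
    stringsAsFactors = FALSE
  )
  obj$editing_sites <- data.frame(
    position = as.integer(unlist(es$position)),
    strand = as.character(unlist(es$strand)),
    efficiency_treatment = as.numeric(unlist(es$efficiency_treatment)),
    efficiency_control = as.numeric(unlist(es$efficiency_control)),
    stringsAsFactors = FALSE
  )
  obj$seed <- as.integer(obj$seed)
  obj$length <- as.integer(obj$length)
  structure(obj, class = "synthetic_truth")
}
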