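---
title: "Designing PPR editing factors and detecting C-to-U editing"
author: "ppredit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing PPR editing factors and detecting C-to-U editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppredit)
```

## The biology and the model

PLS-class pentatricopeptide repeat (PPR) proteins direct cytidine-to-uridine
RNA editing in plant organelles. A factor is a tandem array of ~31-36 amino
acid helix-turn-helix motifs arranged as repeating P1-L1-S1 triplets followed
by P2-L2-S2, the PPR-like E1 and E2 motifs, and a catalytic DYW
(cytidine-deaminase-like) domain. Each of the six P/L/S motif types contacts
exactly one RNA base, 5' to 3' in register with the motif order; E1, E2 and
DYW contact none. Specificity is carried largely by two residues per motif --
the 5th and the last position ("5/35 combination") -- through the PPR code:
TD pairs favour G, TN favour A, ND favour U, NS favour C. Natural editing
factors place the edited C with remarkable precision: it lies 4 nucleotides
3' of the base aligned with the S2 motif. `ppredit` treats this offset as a
fixed convention (`edit_offset = s2_index + 4`, falling back to the last
contacting motif for arrays without S2).

The package covers the complete dry-lab loop around a synthetic editing
factor:

1. **Consensus design** (`build_consensus`, `design_factor`): position-specific
   plurality consensuses are built from aligned motif collections, and the
   5th/last residues of the contacting motifs are programmed from a target
   RNA through a configurable code table.
2. **Binding prediction** (`score_alignment`, `scan_sequence`,
   `score_site_table`): additive per-motif scoring of factor/RNA alignments
   from a configurable scoring table, and exhaustive genome scans for
   candidate binding/editing sites.
3. **Editing detection** (`count_bases`, `detect_editing`): strand-specific
   nucleotide counts are compared between a treatment and a negative control
   with a Fisher exact test per candidate C, Hochberg step-up correction over
   the whole candidate family, and pseudocounted odds ratios.
4. **Synthetic data** (`simulate_*`): seeded generators for genomes, counts,
   reads and motif collections with recorded ground truth.

## Consensus construction

`build_consensus` is a plurality call with no minimum threshold ("plurality
0"): per column, the residue with the highest count wins. The design space
left open by that rule is resolved as follows, and these choices are fixed:

* **Ties** are broken by the canonical alphabetical order of the one-letter
  amino-acid codes (A < C < D < ...). Any fixed order would do; this one
  makes the output reproducible across platforms and is easy to state.
* **Gaps** are excluded from the counts and can never win a column; a column
  that is all gap is dropped from the output. Consensus length therefore
  equals alignment length minus all-gap columns.
* Counts are raw sequence counts, not substitution-matrix-weighted
  plurality scores. With the large, diverse motif collections this tool is
  aimed at, the plurality residue is essentially never decided by a
  weighting scheme; raw counts keep the operation transparent and exactly
  testable.

`build_consensus` is idempotent, and `simulate_motif_collection` provides
the matching generator: at 20% per-column divergence, 200 sequences recover
a 35-residue generating consensus with near certainty (this is checked in
the test suite).

## Factor design

`design_factor` takes a scaffold (motif types plus per-motif consensus
sequences), a code table, and a target RNA with one base per *programmed*
contacting motif. Programmed motifs receive `code[(type, base)]` at their
5th and last positions; motifs named in `fixed_tail` (classically L2, S2,
E1 and E2, copied from a natural factor) keep supplied residues; missing
code-table keys are a hard error naming the offending (type, base) pair --
silent defaults would silently mis-program a protein.

The N-terminal cap defaults to `MGNS` (Met-Gly-Asn-Ser). A Met-Gly-Asp-Ser
variant (`MGDS`) is also in circulation for the same scaffold family; both
spellings appear in the literature describing the same design, so the cap is
a configurable argument rather than a constant, and no attempt is made to
adjudicate between them.

Code and scoring tables are deliberately *data, not code*: the package
ships simplified defaults under `inst/extdata/` that encode the canonical
qualitative preferences, and any published empirical table in the same
format (for example the tables distributed with the PPRmatcher tool) can be
dropped in. The package's own tests never treat the shipped values as
ground truth; they use fixture tables constructed in the test code.

## Binding scores and genome scanning

A scoring table maps (5th residue, last residue, base) to a dimensionless
real; an alignment's total score is the exact floating-point sum of its
per-motif scores, with no intermediate rounding. Unseen residue pairs score
a configurable `default_score` (0 = neutral) rather than raising an error,
because natural factors routinely contain pairs absent from empirical
tables. A single table keyed purely on (5th, last, base) is used for all
six contacting motif types; per-type tables would be a straightforward
extension but are not implemented, as the available empirical tables are
keyed the same way.

`scan_sequence` enumerates every placement of the contact window on both
strands (minus-strand windows are read from the reverse complement, so a
plus-strand reference G can be a minus-strand edited C), anchored either at
all positions or only where the predicted edit position carries a
transcript-sense C. Output is deterministically ordered (score descending,
then sequence, coordinate, strand). Coordinates are 1-based inclusive on
the forward strand throughout -- the native convention of the R/Bioconductor
containers this package builds on -- and match the 1-based positions used in
site names such as *rpoA-78691*.

Chloroplast genomes are circular; `circular = TRUE` replicates the first
window-span bases at the end of the sequence before scanning and folds
output coordinates modulo the sequence length, so origin-spanning sites are
neither lost nor double-counted. The same idea (reference extension before
mapping) is standard practice when aligning reads to circular organellar
references.

## Editing detection

Candidates are every position/strand whose transcript-sense reference base
is C. Counts are stored in transcript sense -- minus-strand observations are
complemented at counting time -- so "edited" is always a stored C→T and the
2x2 table per site is (edited, unedited) x (treatment, control).

* **Test**: two-sided Fisher exact test, with the standard
  "probability-mass ≤ observed" two-sided rule (relative tolerance 1e-7),
  implemented as a vectorised hypergeometric enumeration so that tens of
  thousands of candidate sites are tested in milliseconds; a one-sided mode
  is available by flag. The implementation is checked in the test suite
  against `stats::fisher.test` and against an independent brute-force
  enumeration over all 2x2 tables with margins up to 30.
* **Multiplicity**: Hochberg (Simes-Hochberg) step-up adjustment over the
  full candidate family (every covered transcript-sense C, minimum combined
  coverage 1 by default). The family is deliberately *not* restricted to
  sites with observed events; restricting it would invalidate the FWER
  guarantee.
* **Effect size**: odds ratio with a 0.5 pseudocount added to all four
  cells, so the estimate is finite for every table (an all-zero table gives
  OR = 1, log OR = 0). The log is natural by default; the significance rule
  is `p_adj < alpha` (default 0.05) *and* `log OR > 2` (both configurable).
  The threshold of 2 on the natural log odds ratio is the conventional
  cutoff for highlighting off-target events in this assay family; alpha
  0.05 is the usual default where no explicit level is stated.
* **Reporting**: percent edited in the treatment is
  `100 * edited / (edited + unedited)` and is `NA` (not 0) for sites with
  no treatment coverage. Note that published per-site percentages in this
  field are sometimes computed with a denominator that includes reads
  carrying third bases, so small (< 0.02 percentage point) discrepancies
  against printed values are expected; this package always reports
  edited/(edited+unedited).

`count_bases` derives the count tables from SAM/BAM through `Rsamtools`
pileups: unmapped/secondary/supplementary records are skipped, bases below
the quality floor and bases inside indels contribute nothing, and the
library strandedness convention ("forward" or "reverse") maps read strand
to transcript strand.

`size_factors` implements median-of-ratios normalisation against a
per-gene geometric-mean pseudo-reference (genes with any zero count are
excluded from the reference set), with log2 fold-differences against a
named baseline sample; it agrees with `DESeq2::estimateSizeFactorsForMatrix`
to numerical precision (tested).

`annotate_effect` projects calls into GFF3 gene models: same-strand CDS
hits get codon before/after and amino-acid change under the standard
genetic code (also used for plastid sites), calls inside a gene span but
outside exons are `intron`, everything else `UTR/intergenic`. CDS models
with invalid phase or non-multiple-of-3 spliced length are skipped with a
warning rather than mis-annotated.

## The synthetic-data generator

`simulate_genome` / `plant_target` / `plant_editing_sites` /
`simulate_counts` / `simulate_sam` generate the study-shaped inputs with
recorded truth:

* i.i.d. background bases at a chosen GC fraction on a single
  chloroplast-like reference;
* planted binding sites that exactly match a designed target window, with
  the edited C at the +4 offset and a pyrimidine at -1 by default;
* per-position, per-strand depths that are Poisson with mean `coverage`
  (default 500 -- organellar RNA-seq in this assay family is deep; the
  worked example site alone carries ~2,700 reads);
* per-read editing with the planted efficiency and uniform miscalls at
  `error_rate` (default 0.001, a typical Illumina substitution rate after
  quality filtering);
* an optional multiplicative efficiency penalty when the -1 base is a
  purine (off by default), encoding the known inhibitory effect of purines
  at that position.

What the generator does *not* emulate: realistic quality profiles, PCR
duplicates, splice-aware reads, coverage heterogeneity along transcripts,
or transcript-abundance structure. Passing the recovery and FWER tests
therefore demonstrates the statistical machinery under clean binomial
sampling, not performance on real libraries with alignment artefacts.

Determinism is strict: every draw comes from a seeded substream derived
from the truth seed and the sample role, truth records serialise to YAML
and round-trip losslessly, and regenerating counts from a restored truth is
byte-identical.

## Simulation sizes and statistical behaviour of the test suite

The suite's simulation scenarios are sized to the statistics they probe:

* Null/FWER runs use a 1 kb genome at GC 0.5 (~500 candidate Cs across
  both strands) at depth 200. At these depths a null site carries at most a
  handful of error-derived T reads, and the discreteness of the Fisher test
  keeps achievable p-values far above the Hochberg cutoff, so the realised
  family-wise error is effectively below the nominal 5%.
* Recovery runs use depth 500. A 40% site yields ~200 edited reads against
  ~0 and is unconditionally recovered; a 5% site yields ~25 edited reads,
  whose two-sided p (~1e-7) survives Hochberg correction over hundreds of
  candidates with large margin. Depth is the binding constraint for faint
  sites: at depth 200 a 5%-efficiency site (~10 edited reads, p ~2e-3)
  would *not* reliably survive a several-hundred-fold correction -- a real
  power limit of the assay, not an implementation artefact -- which is why
  the faint-site recovery scenario is specified at the deep-coverage
  setting this generator defaults to.
* The exhaustive Fisher oracle covers all ~180,000 2x2 tables with margins
  up to 30 in a few seconds thanks to the vectorised implementation.

## Pipeline and reproducibility

`run_offtarget_analysis` chains load → detect → annotate → report under a
single validated YAML config and writes plain-text outputs: the full
per-candidate table, the highlighted subset (significant and log OR above
threshold, ranked by log OR), scatter data (binding score vs log OR) for
re-plotting the off-target landscape, and a JSON run log with package/R
versions and all parameters. The log deliberately contains no timestamps,
so an identical config and seed reproduce the entire bundle byte for byte.
Stage failures abort with a stage-named error and remove partial outputs.
A thin command-line dispatcher (`exec/ppredit`) exposes the same functions
as `design / scan / simulate / count / detect / normalise / annotate / run`
subcommands; the R functions remain the primary interface.

## Known limitations

* Binding is additive per motif; no thermodynamics, no RNA secondary
  structure, no MORF-cofactor modelling. Highly structured regions (e.g.
  group II introns) can bind very differently from their score.
* The genetic code used for effect annotation is the standard table;
  organelle-specific deviations are not modelled (appropriate for plastids,
  where the standard table applies).
* U-to-C "reverse" editing is not called; the counts retain A/G/C tallies
  at T positions, so a user can screen for it manually.
* The shipped code/scoring tables are qualitative defaults, not empirical
  measurements; quantitative work should load a published table.
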