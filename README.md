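# ppredit

Design and off-target analysis of synthetic PPR RNA editing factors.

## What this package is for

PLS-class pentatricopeptide repeat (PPR) proteins are the specificity
factors of C-to-U RNA editing in plant organelles. Each PPR motif in the
(P1-L1-S1)<sub>n</sub>-P2-L2-S2-E1-E2-DYW array contacts one RNA base, with
specificity set mainly by the amino acids at the 5th and last positions of
the motif (the "PPR code", e.g. TD→G, TN→A, ND→U, NS→C), and the edited
cytidine sits 4 nucleotides 3′ of the base aligned with the S2 motif. That
regularity makes PPR scaffolds programmable: one can build consensus motifs
from large motif alignments, write a target site into the code positions,
and obtain a synthetic editing factor.

`ppredit` is a toolbox for scientists doing exactly that kind of work:

* **Design** — plurality ("plurality 0") consensus construction from
  aligned motif collections and code-table programming of new factors
  against a target RNA (`build_consensus()`, `design_factor()`).
* **Binding prediction** — additive PPR-code scoring of factor/RNA
  alignments with configurable scoring tables, and genome scanning for
  candidate binding/editing sites on both strands, with circular-genome
  support (`score_alignment()`, `scan_sequence()`, `score_site_table()`).
* **Editing detection** — strand-specific nucleotide counts from SAM/BAM,
  per-site 2×2 Fisher exact tests of treatment vs negative control,
  Hochberg step-up correction over the full candidate family, odds ratios
  with a 0.5 pseudocount, median-of-ratios normalisation, and
  coding-consequence annotation against GFF3
  (`count_bases()`, `detect_editing()`, `size_factors()`,
  `annotate_effect()`).
* **Synthetic data** — seeded generators for chloroplast-like genomes with
  planted binding/editing sites, base-count tables, SAM read sets and motif
  collections, with ground truth recorded and serialisable
  (`simulate_genome()`, `plant_target()`, `simulate_counts()`,
  `simulate_sam()`, `simulate_motif_collection()`).
* **Pipeline** — a configured end-to-end off-target analysis producing a
  reproducible report bundle (`run_offtarget_analysis()`), plus a thin CLI
  (`exec/ppredit`) with `design/scan/simulate/count/detect/normalise/
  annotate/run` subcommands.

The statistical core per candidate site is the 2×2 table of
(edited, unedited) × (treatment, control) reads: a two-sided Fisher exact
p-value, Hochberg-adjusted over every transcript-sense reference C with
coverage, and the pseudocounted odds ratio
OR = ((a+½)(d+½)) / ((b+½)(c+½)). A site is *highlighted* when
p<sub>adj</sub> < α (default 0.05) **and** ln OR > 2 (both configurable).

## Worked example

Design a factor against a 12-nt target, plant its site in a synthetic
10 kb plastid-like genome, scan, and detect editing at 40% efficiency
against an unedited control:

```r
library(ppredit)

code    <- read_code_table(system.file("extdata", "ppr_code_default.tsv",
                                       package = "ppredit"))
scoring <- read_scoring_table(system.file("extdata", "ppr_scoring_default.tsv",
                                          package = "ppredit"))

# scaffold: motif types + per-motif consensus sequences (here random stand-ins;
# in real use, build_consensus() output from aligned motif collections)
set.seed(1)
scaffold <- data.frame(
  type = c(rep(c("P1", "L1", "S1"), 3), "P2", "L2", "S2", "E1", "E2", "DYW"),
  triplet_index = NA,
  consensus = vapply(c(rep(c(35, 36, 31), 3), 35, 36, 32, 34, 34, 136),
                     function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                       "")[[1]], n, TRUE),
                                       collapse = ""), "")
)
fac <- design_factor("GAUUCGAAUCGA", scaffold, code, name = "dsn3PLS-DYW")
fac
#> <ppr_factor> dsn3PLS-DYW
#>   cap: MGNS
#>   motifs: P1-L1-S1-P1-L1-S1-P1-L1-S1-P2-L2-S2-E1-E2-DYW (12 contacting)
#>   5/last pairs: TD TN ND ND NS TD TN TN ND NS TD TN NS AL --

sim  <- simulate_genome(10000, seed = 1, coverage = 500, error_rate = 0.001)
sim  <- plant_target(sim, attr(fac, "design_target"), at = 4001,
                     efficiency_treatment = 0.4)
hits <- scan_sequence(fac, sim$genome, scoring)
head(hits[, c("sequence", "strand", "window_start", "edit_position",
              "total_score")], 3)
#>            sequence strand window_start edit_position total_score
#> 1 synthetic_plastid      +         4001          4016       12.00
#> 2 synthetic_plastid      +         8344          8359        7.25
#> 3 synthetic_plastid      +         2270          2285        7.00

calls <- detect_editing(simulate_counts(sim, "treatment"),
                        simulate_counts(sim, "control"),
                        sim$genome, factor = fac, table = scoring)
calls[calls$significant,
      c("position", "strand", "edited_treat", "unedited_treat", "p_adj",
        "log_odds_ratio", "percent_edited_treat", "binding_score")]
#>      position strand edited_treat unedited_treat        p_adj log_odds_ratio
#> 2073     4016      +          203            289 2.342538e-70       6.554265
#>      percent_edited_treat binding_score
#> 2073             41.26016            12
```

Reading the output: the planted window is recovered at rank 1
(`window_start` 4001) and its predicted edit position, 4 nt 3′ of the
S2-aligned base, is 4016 — exactly where the generator planted the edited C.
Among ~4,900 candidate Cs, the only call surviving Hochberg correction and
the ln OR > 2 threshold is that site, observed edited in 41.3% of treatment
reads (203 of 492) and carrying the maximal binding score (12, a perfect
12-motif match).

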