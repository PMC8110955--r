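# Pipeline: configured end-to-end off-target analysis with machine-readable
# outputs.

#' Read and validate a run configuration
#'
#' YAML configuration for [run_offtarget_analysis()]. Recognised fields:
#' `factor` (factor definition file), `scoring_table`, `reference` (FASTA),
#' `annotation` (optional GFF3), `counts: {treatment: ..., control: ...}`
#' (base-count TSVs), `contrast` (any of `alpha`, `lor_threshold`,
#' `pseudocount`, `log_base`), `min_coverage`, `circular`, `output_dir`,
#' `seed`. All referenced input files must exist at validation time.
#'
#' @param file Path to a YAML config, or a named list with the same fields.
#' @return A validated list of class `run_config` (with `schema_version`).
#' @export
read_run_config <- function(file) {
  cfg <- if (is.list(file)) file else yaml::read_yaml(file)
  defaults <- list(annotation = NULL, contrast = list(), min_coverage = 1L,
                   circular = FALSE, output_dir = "ppredit_run", seed = 1L,
                   schema_version = 1L)
  cfg <- modifyList(defaults, cfg)
  for (field in c("factor", "scoring_table", "reference")) {
    if (is.null(cfg[[field]])) stop("config is missing '", field, "'")
  }
  if (is.null(cfg$counts$treatment) || is.null(cfg$counts$control)) {
    stop("config must give counts for both 'treatment' and 'control'")
  }
  paths <- c(cfg$factor, cfg$scoring_table, cfg$reference,
             cfg$annotation, cfg$counts$treatment, cfg$counts$control)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("config references missing file(s): ",
         paste(missing, collapse = ", "))
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Run the off-target editing analysis end to end
#'
#' Loads the configured factor, scoring table, reference and base counts;
#' detects editing against the control with binding-score annotation;
#' optionally annotates coding consequences; and writes a report bundle to
#' the output directory:
#'
#' * `calls.tsv` -- every tested candidate with counts, p-values, odds
#'   ratios, binding score and significance;
#' * `highlighted.tsv` -- the subset with `p_adj < alpha` and log odds
#'   ratio above the threshold, ranked by log odds ratio;
#' * `scatter.tsv` -- binding score vs log odds ratio (plus significance)
#'   for re-plotting the off-target landscape;
#' * `run_log.json` -- package/R versions, seed and all parameter values
#'   (no timestamps, so an identical config reruns byte-identically).
#'
#' Any stage failure aborts with an error naming the stage, and files
#' written by the failed run are removed.
#'
#' @param config A `run_config` (or path/list accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list with `calls`, `highlighted` and the output
#'   paths.
#' @export
run_offtarget_analysis <- function(config) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  outdir <- config$output_dir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  inputs <- stage("load", {
    list(factor = read_ppr_factor(config$factor),
         table = read_scoring_table(config$scoring_table),
         reference = Biostrings::readDNAStringSet(config$reference),
         treat = read_base_counts(config$counts$treatment),
         ctrl = read_base_counts(config$counts$control))
  })
  contrast <- stage("contrast", do.call(editing_contrast, config$contrast))
  calls <- stage("detect", detect_editing(
    inputs$treat, inputs$ctrl, inputs$reference, contrast = contrast,
    factor = inputs$factor, table = inputs$table,
    min_coverage = config$min_coverage, circular = isTRUE(config$circular)
  ))
  if (!is.null(config$annotation)) {
    calls <- stage("annotate",
                   annotate_effect(calls, config$annotation, inputs$reference))
  }
  highlighted <- calls[calls$significant, , drop = FALSE]
  highlighted <- highlighted[order(-highlighted$log_odds_ratio), , drop = FALSE]

  paths <- list(calls = file.path(outdir, "calls.tsv"),
                highlighted = file.path(outdir, "highlighted.tsv"),
                scatter = file.path(outdir, "scatter.tsv"),
                log = file.path(outdir, "run_log.json"))
  stage("report", {
    write_editing_calls(calls, paths$calls)
    written <<- c(written, paths$calls)
    write_editing_calls(highlighted, paths$highlighted)
    written <<- c(written, paths$highlighted)
    scatter <- calls[, c("sequence", "position", "strand", "binding_score",
                         "log_odds_ratio", "significant")]
    write.table(scatter, paths$scatter, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <<- c(written, paths$scatter)
    log <- list(
      package = "ppredit",
      package_version = as.character(utils::packageVersion("ppredit")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      schema_version = config$schema_version,
      parameters = list(
        factor = config$factor, scoring_table = config$scoring_table,
        reference = config$reference, annotation = config$annotation,
        counts = config$counts, min_coverage = config$min_coverage,
        circular = isTRUE(config$circular),
        alpha = contrast$alpha, lor_threshold = contrast$lor_threshold,
        pseudocount = contrast$pseudocount, log_base = contrast$log_base
      ),
      n_candidates = nrow(calls),
      n_highlighted = nrow(highlighted)
    )
    jsonlite::write_json(log, paths$log, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <<- c(written, paths$log)
  })
  invisible(list(calls = calls, highlighted = highlighted, paths = paths))
}
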