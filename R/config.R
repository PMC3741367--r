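# Run configuration: every printed constant of the analysis is a default
# here and all are overridable.

#' Pipeline run configuration
#'
#' Bundles the thresholds used across all stages. Defaults follow the
#' published analysis: transcripts longer than 200 bases with more than
#' one exon, at least 1 kb from any protein-coding gene, JS score cutoff
#' 0.5, neighbor correlation cutoff 0.8, MCL inflation 1.8, modules of
#' six or more genes, and a 10,000-pair randomization null.
#'
#' @param min_fpkm minimum max-over-tissues FPKM for a reliably
#'   expressed transcript (surrogate for the original expression/noise
#'   separation; see the methods vignette).
#' @param min_coverage minimum mean per-base read coverage.
#' @param min_length minimum transcript length in nt (strict `>`).
#' @param min_exons minimum exon count (`>=`).
#' @param intergenic_gap minimum distance in bp to any protein-coding
#'   gene (`>=`).
#' @param js_cutoff tissue-specificity call threshold on the JS score.
#' @param corr_cutoff neighbor-pair correlation threshold.
#' @param mcl_inflation MCL inflation parameter.
#' @param min_module_size smallest reported co-expression module.
#' @param n_random_pairs size of the random-pair GO-sharing null.
#' @param edge_threshold absolute Pearson correlation needed for a
#'   co-expression edge.
#' @param seed integer seed for all stochastic stages.
#' @return A `run_config` list.
#' @export
run_config <- function(min_fpkm = 1.0, min_coverage = 3.0,
                       min_length = 200L, min_exons = 2L,
                       intergenic_gap = 1000L, js_cutoff = 0.5,
                       corr_cutoff = 0.8, mcl_inflation = 1.8,
                       min_module_size = 6L, n_random_pairs = 10000L,
                       edge_threshold = 0.9, seed = 1L) {
  cfg <- list(min_fpkm = as.numeric(min_fpkm),
              min_coverage = as.numeric(min_coverage),
              min_length = as.integer(min_length),
              min_exons = as.integer(min_exons),
              intergenic_gap = as.integer(intergenic_gap),
              js_cutoff = as.numeric(js_cutoff),
              corr_cutoff = as.numeric(corr_cutoff),
              mcl_inflation = as.numeric(mcl_inflation),
              min_module_size = as.integer(min_module_size),
              n_random_pairs = as.integer(n_random_pairs),
              edge_threshold = as.numeric(edge_threshold),
              seed = as.integer(seed))
  if (cfg$min_fpkm < 0 || cfg$min_coverage < 0) {
    stop("expression thresholds must be non-negative")
  }
  if (cfg$min_length < 0L || cfg$min_exons < 1L || cfg$intergenic_gap < 0L) {
    stop("structural thresholds out of range")
  }
  if (cfg$js_cutoff < 0 || cfg$js_cutoff > 1) stop("js_cutoff must be in [0,1]")
  if (cfg$corr_cutoff < -1 || cfg$corr_cutoff > 1) {
    stop("corr_cutoff must be in [-1,1]")
  }
  if (cfg$mcl_inflation <= 1) stop("mcl_inflation must exceed 1")
  if (cfg$min_module_size < 1L || cfg$n_random_pairs < 1L) {
    stop("module/null sizes must be positive")
  }
  if (cfg$edge_threshold <= 0 || cfg$edge_threshold > 1) {
    stop("edge_threshold must be in (0,1]")
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration to a YAML file
#' @param cfg A [run_config].
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a run configuration from a YAML file
#'
#' Round-trips losslessly with [write_config()]; unknown keys are an
#' error.
#' @param path YAML file path.
#' @return A [run_config].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}
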