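#' Analysis configuration
#'
#' Bundles every threshold the pipeline applies. Defaults are the study
#' thresholds: DEGs at fold-change > 4 and FDR-corrected p < 0.01;
#' summative (isoform-group) significance at fold > 2 and raw p < 0.05;
#' "moderate" regulation at fold > 1.2; differential compounds at fold
#' > 4 and p < 0.01; metabolite QC at relative standard deviation
#' <= 30% and mass accuracy < 10 ppm.
#'
#' @param deg_fold Fold-change threshold for significant DEGs (> 1).
#' @param deg_fdr FDR threshold for significant DEGs.
#' @param summative_fold,summative_p Thresholds for summative
#'   isoform-group significance (raw p, not FDR).
#' @param moderate_fold Fold threshold for the "moderate" grade.
#' @param dec_fold,dec_p Thresholds for differential compounds.
#' @param rsd_max_percent Maximum relative standard deviation (percent)
#'   a metabolite ion may show before removal.
#' @param ppm_max Mass-accuracy threshold in parts per million (strict
#'   less-than).
#' @param pseudocount Added to both mean abundances before log2 ratios.
#' @param top_n Size of top-ranked gene lists.
#' @param rng_seed Integer seed for any stochastic step.
#' @return A list of class \code{analysis_config}.
#' @export
analysis_config <- function(deg_fold = 4, deg_fdr = 0.01,
                            summative_fold = 2, summative_p = 0.05,
                            moderate_fold = 1.2,
                            dec_fold = 4, dec_p = 0.01,
                            rsd_max_percent = 30, ppm_max = 10,
                            pseudocount = 0.5, top_n = 10,
                            rng_seed = 1L) {
  cfg <- list(deg_fold = deg_fold, deg_fdr = deg_fdr,
              summative_fold = summative_fold, summative_p = summative_p,
              moderate_fold = moderate_fold,
              dec_fold = dec_fold, dec_p = dec_p,
              rsd_max_percent = rsd_max_percent, ppm_max = ppm_max,
              pseudocount = pseudocount, top_n = as.integer(top_n),
              rng_seed = as.integer(rng_seed))
  for (f in c("deg_fold", "summative_fold", "moderate_fold", "dec_fold"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 1)
      stop(f, " must be > 1")
  for (p in c("deg_fdr", "summative_p", "dec_p"))
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0 || cfg[[p]] >= 1)
      stop(p, " must lie in (0, 1)")
  if (cfg$pseudocount <= 0) stop("pseudocount must be positive")
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Keys are exactly the argument names of [analysis_config()]; absent
#' keys take their defaults, unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return An \code{analysis_config}.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}
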