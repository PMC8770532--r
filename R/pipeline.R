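#' Simulate a full experiment and write its file set
#'
#' Writes a counts TSV, sample metadata TSV, annotation TSV, pathway
#' GMT, metabolite intensity + metadata CSVs, ground-truth tables and a
#' JSON run manifest into \code{out_dir}. Reruns with the same seed
#' produce byte-identical files.
#'
#' @param out_dir Output directory; must be empty or absent unless
#'   \code{force}.
#' @param spec A [transcriptome_sim_spec()].
#' @param n_pathways,size_range,n_enriched,enrich_factor Passed to
#'   [simulate_pathway_map()].
#' @param metabolome_args List of arguments for [simulate_metabolome()].
#' @param force Overwrite a non-empty directory.
#' @return Invisibly, the named vector of file paths written.
#' @export
simulate_experiment <- function(out_dir, spec = transcriptome_sim_spec(),
                                n_pathways = 50L, size_range = c(10L, 90L),
                                n_enriched = 5L, enrich_factor = 16,
                                metabolome_args = list(), force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force)
    stop("output directory is not empty (use force = TRUE): ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- simulate_transcriptome(spec)
  pw <- simulate_pathway_map(sim$truth, n_pathways, size_range,
                             n_enriched, enrich_factor,
                             rng_seed = spec$rng_seed)
  metabolome_args$rng_seed <- spec$rng_seed
  met <- do.call(simulate_metabolome, metabolome_args)

  paths <- c(counts = file.path(out_dir, "counts.tsv"),
             sample_meta = file.path(out_dir, "sample_meta.tsv"),
             annotation = file.path(out_dir, "annotation.tsv"),
             pathways = file.path(out_dir, "pathways.gmt"),
             metabolites = file.path(out_dir, "metabolites.csv"),
             metabolite_meta = file.path(out_dir, "metabolite_meta.csv"),
             truth_genes = file.path(out_dir, "truth_genes.tsv"),
             truth_pathways = file.path(out_dir, "truth_pathways.tsv"),
             truth_compounds = file.path(out_dir, "truth_compounds.tsv"),
             manifest = file.path(out_dir, "manifest.json"))

  cm <- sim$matrix
  counts_out <- data.frame(gene_id = rownames(cm$counts),
                           cm$counts, check.names = FALSE)
  utils::write.table(counts_out, paths[["counts"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cm$sample_meta[, c("sample_id", "condition", "replicate")],
                     paths[["sample_meta"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # deterministically assign the built-in route ECs to the first genes
  # so the integration stage is exercised end to end
  graphs <- builtin_pathway_graphs()
  ecs <- unique(unlist(lapply(graphs, function(g)
    g$enzymes$ec[!g$enzymes$absent_from_transcriptome])))
  ann <- data.frame(gene_id = rownames(cm$counts),
                    product = "hypothetical protein",
                    ec_numbers = "", pathway_ids = "",
                    isoform_group = "", stringsAsFactors = FALSE)
  ann$ec_numbers[seq_along(ecs)] <- ecs
  ann$product[seq_along(ecs)] <- "enzyme"
  utils::write.table(ann, paths[["annotation"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_pathway_map(pw$map, paths[["pathways"]])
  write_metabolite_table(met$table, paths[["metabolites"]],
                         paths[["metabolite_meta"]])
  utils::write.table(pw$truth$genes, paths[["truth_genes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pw$truth$pathways, paths[["truth_pathways"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(met$truth, paths[["truth_compounds"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  write_manifest(paths[["manifest"]],
                 config = unclass(spec), seed = spec$rng_seed,
                 inputs = character(0),
                 stage_counts = list(genes = spec$n_genes,
                                     samples = ncol(cm$counts),
                                     pathways = length(pw$map),
                                     compounds = nrow(met$table$intensities)))
  invisible(paths)
}

#' Run the full analysis pipeline on file inputs
#'
#' Stages, in order: differential expression (the three shift-design
#' comparisons), GSR identification, pathway enrichment of the GSR
#' set, metabolome QC + differential compounds, and route integration
#' over the built-in glucose-assimilation graphs. Writes per-stage
#' result tables (TSV + JSON sidecars), a route report, and a run
#' manifest. A stage failure aborts with the stage name; outputs
#' already written are retained.
#'
#' @param counts,sample_meta,annotation,pathways Paths to the
#'   transcriptome inputs (TSV/GMT as in the readers).
#' @param metabolites,metabolite_meta Optional paths to the metabolite
#'   CSVs; the metabolome and integration stages are skipped when NULL.
#' @param out_dir Output directory.
#' @param config An [analysis_config()].
#' @param transcriptome_size N used for enrichment; defaults to the
#'   number of genes in the count matrix.
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(counts, sample_meta, annotation = NULL,
                         pathways = NULL, metabolites = NULL,
                         metabolite_meta = NULL, out_dir,
                         config = analysis_config(),
                         transcriptome_size = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  stages <- integer(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  mat <- stage("read", read_count_matrix(counts, sample_meta))
  N <- if (is.null(transcriptome_size)) nrow(mat$counts) else transcriptome_size

  results$deg <- stage("deg", build_comparisons(mat, config))
  for (nm in names(results$deg))
    write_results_table(results$deg[[nm]],
                        file.path(out_dir, paste0("deg_", nm, ".tsv")))
  stages <- c(stages, deg = sum(vapply(results$deg, nrow, 0L)))

  results$gsr <- stage("gsr", identify_gsr(results$deg, config))
  write_results_table(results$gsr$records, file.path(out_dir, "gsr.tsv"))
  jsonlite::write_json(results$gsr$venn, file.path(out_dir, "venn.json"),
                       auto_unbox = TRUE, digits = NA)
  stages <- c(stages, gsr = nrow(results$gsr$records))

  if (!is.null(pathways)) {
    map <- stage("enrich", read_pathway_map(pathways))
    mono <- results$gsr$records
    mono <- mono$gene_id[mono$classification != "non_monotonic"]
    results$enrichment <- stage("enrich", pathway_enrichment(mono, map, N))
    write_results_table(results$enrichment,
                        file.path(out_dir, "enrichment.tsv"))
    stages <- c(stages, enrich = nrow(results$enrichment))
  }

  if (!is.null(metabolites)) {
    met <- stage("metabolome", {
      tab <- read_metabolite_table(metabolites, metabolite_meta)
      tab <- rsd_filter(tab, config$rsd_max_percent)$table
      tab <- normalize_median(tab)$table
      tab
    })
    results$dec <- stage("metabolome", call_decs(met, config))
    write_results_table(results$dec, file.path(out_dir, "dec.tsv"))
    stages <- c(stages, metabolome = nrow(results$dec))

    if (!is.null(annotation)) {
      results$routes <- stage("integrate", {
        ann <- read_annotation(annotation)
        summ <- summative_call(mat, ann, "ec", "LL", "HH", config)
        graphs <- builtin_pathway_graphs()
        routes <- c("EMP_upper", "ED", "OPP", "EMP_lower")
        verdicts <- lapply(graphs[routes], function(gph) {
          evaluate_route(gph, call_enzymes(gph, summ, config),
                         call_metabolites(gph, results$dec, config))
        })
        compare_routes(verdicts)
      })
      writeLines(results$routes$report, file.path(out_dir, "routes.txt"))
      jsonlite::write_json(results$routes$table,
                           file.path(out_dir, "routes.json"), digits = NA)
      stages <- c(stages, integrate = nrow(results$routes$table))
    }
  }

  write_manifest(file.path(out_dir, "manifest.json"),
                 config = unclass(config), seed = config$rng_seed,
                 inputs = c(counts, sample_meta, annotation, pathways,
                            metabolites, metabolite_meta),
                 stage_counts = as.list(stages))
  invisible(results)
}

# One manifest per output directory: config snapshot, input digests,
# seed, package version, per-stage record counts.
write_manifest <- function(path, config, seed, inputs, stage_counts) {
  digests <- if (length(inputs) > 0L) {
    stats::setNames(as.list(unname(tools::md5sum(inputs))), basename(inputs))
  } else list()
  manifest <- list(
    tool = "gsrpipe",
    version = as.character(utils::packageVersion("gsrpipe")),
    seed = seed,
    config = config,
    input_md5 = digests,
    stage_counts = stage_counts,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
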