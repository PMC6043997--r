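## End-to-end orchestration: differential expression -> gene categorization
## -> category-aware edge filtering -> DPClusO over a density grid ->
## per-cluster enrichment and gene scores -> ROC-based density selection ->
## novel-gene prediction, with an optional written manifest of stage outputs.

#' Run the full prioritization pipeline
#'
#' @param counts a [count_matrix()].
#' @param edges a [scored_edges()] data frame.
#' @param known character vector of known disease genes.
#' @param control_label group label of the control samples.
#' @param reference character vector of reference positives used for
#'   ROC-based density selection (e.g. the union of curated disease-gene
#'   sources, or hidden truth genes in a simulation). Required when the
#'   density grid has more than one value.
#' @param annotation optional annotation map ([read_annotation_map()]) for
#'   the pathway-frequency summary.
#' @param config a [default_run_config()] list.
#' @param out_dir optional directory; when given, every stage output is
#'   written as TSV and listed in the manifest.
#' @return A list of class `pipeline_run` with elements `dge`, `catalog`,
#'   `network`, `grid`, `enrichment` (per density), `scores` (per density),
#'   `selection`, `predictions`, `annotation_freq` (or NULL), `manifest`.
#' @export
run_pipeline <- function(counts, edges, known, control_label,
                         reference = NULL, annotation = NULL,
                         config = default_run_config(), out_dir = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c(); outputs <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
  }

  dge <- run_dge(counts, control_label, config$fdr_threshold)
  tick("dge")

  catalog <- categorize_genes(dge$deg_union, known, edges)
  net <- filter_edges(edges, catalog, config$pair_type_thresholds)
  if (length(net$nodes) == 0L)
    np_stop("stage network_build: no edge survived threshold filtering")
  tick("network_build")

  grid <- cluster_grid(net, config$density_grid, config$cp_threshold)
  tick("clustering")

  enrich <- lapply(grid$sets, function(cs)
    fisher_enrichment(cs, catalog, network_genes = net$nodes))
  scores <- Map(function(tb, cs) sscore(tb, cs, config$sscore_log_base),
                enrich, grid$sets)
  tick("enrichment")

  known_in_net <- catalog$gene[catalog$category == "IDEG"]
  universe <- setdiff(net$nodes, known_in_net)
  if (length(config$density_grid) == 1L) {
    selection <- structure(
      list(auc_table = data.frame(density = config$density_grid, auc = NA_real_),
           selected_density = config$density_grid, selected_index = 1L),
      class = "density_selection")
    if (!is.null(reference) && length(intersect(reference, universe)) > 0L)
      selection$auc_table$auc <- roc_curve(scores[[1L]], reference, universe)$auc
  } else {
    if (is.null(reference))
      np_stop("stage evaluation: a reference positive list is required to ",
              "select among ", length(config$density_grid), " densities")
    selection <- select_density(scores, reference, universe)
  }
  tick("evaluation")

  sel <- selection$selected_index
  predictions <- predict_genes(enrich[[sel]], grid$sets[[sel]], catalog,
                               config$alpha_predict, config$sscore_log_base)
  tick("prediction")

  annotation_freq <- NULL
  if (!is.null(annotation)) {
    annotation_freq <- annotation_frequencies(grid$sets[[sel]], enrich[[sel]],
                                              annotation, config$alpha_predict)
    tick("annotation")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs[[name]] <<- p
    }
    for (nm in names(dge$results)) wt(dge$results[[nm]], paste0("dge_", nm, ".tsv"))
    write_gene_list(dge$deg_union, file.path(out_dir, "deg_union.txt"))
    outputs[["deg_union.txt"]] <- file.path(out_dir, "deg_union.txt")
    wt(catalog, "gene_catalog.tsv")
    wt(net$edges, "network_edges.tsv")
    wt(grid$summary, "cluster_summary.tsv")
    write_clusters(grid$sets[[sel]],
                   file.path(out_dir, "clusters_selected.tsv"))
    outputs[["clusters_selected.tsv"]] <- file.path(out_dir, "clusters_selected.tsv")
    wt(enrich[[sel]], "enrichment_selected.tsv")
    wt(scores[[sel]], "gene_scores_selected.tsv")
    wt(selection$auc_table, "auc_by_density.tsv")
    wt(predictions, "predictions.tsv")
    if (!is.null(annotation_freq)) wt(annotation_freq$frequencies,
                                      "annotation_frequencies.tsv")
  }

  manifest <- list(config = config,
                   n_genes = nrow(counts$counts),
                   n_samples = ncol(counts$counts),
                   n_input_edges = nrow(edges),
                   selected_density = selection$selected_density,
                   n_predictions = nrow(predictions),
                   stage_seconds = unlist(timings),
                   outputs = outputs,
                   package_version = as.character(utils::packageVersion("netprio")))
  structure(list(dge = dge, catalog = catalog, network = net, grid = grid,
                 enrichment = enrich, scores = scores, selection = selection,
                 predictions = predictions, annotation_freq = annotation_freq,
                 manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run\n",
      sprintf("  DEG union: %d genes\n", length(x$dge$deg_union)),
      sprintf("  network: %d nodes, %d edges\n",
              length(x$network$nodes), nrow(x$network$edges)),
      sprintf("  selected density: %s\n", x$selection$selected_density),
      sprintf("  predictions: %d genes\n", nrow(x$predictions)), sep = "")
  invisible(x)
}
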