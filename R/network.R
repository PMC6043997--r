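## Category-aware assembly of the disease-relevant interaction network:
## genes are labelled IDEG (known disease gene that is differentially
## expressed), ODEG (differentially expressed only) or OG (enters the
## network only through interactions with DEGs), and each scored edge is
## kept when its confidence strictly exceeds the threshold of its unordered
## category pair type. OG-OG edges are always dropped: no threshold exists
## for them in the construction criterion, OGs participate only through
## their interactions with differentially expressed genes.

#' Per-pair-type confidence thresholds of the published construction
#'
#' `IDEG-IDEG: 0.1, IDEG-ODEG: 0.1, IDEG-OG: 0.72, ODEG-ODEG: 0.1,
#' ODEG-OG: 0.85`. The two asymmetric thresholds balance the number of
#' differentially expressed genes against other genes in the final network.
#'
#' @return Named numeric vector keyed by unordered pair type.
#' @export
default_pair_thresholds <- function() {
  c("IDEG-IDEG" = 0.1, "IDEG-ODEG" = 0.1, "IDEG-OG" = 0.72,
    "ODEG-ODEG" = 0.1, "ODEG-OG" = 0.85)
}

#' Categorize genes into IDEG / ODEG / OG
#'
#' IDEG = known disease genes that are in the DEG union; ODEG = DEG union
#' minus the known list; OG = any other gene appearing in the edge list
#' (including known disease genes that are not differentially expressed).
#'
#' @param deg_union character vector of differentially expressed genes.
#' @param known character vector of known disease genes.
#' @param edges a [scored_edges()] data frame.
#' @return A data.frame of class `gene_catalog` with columns `gene`,
#'   `category` and `known` covering every gene in `deg_union` or `edges`.
#' @export
categorize_genes <- function(deg_union, known, edges) {
  deg_union <- unique(as.character(deg_union))
  known <- unique(as.character(known))
  edge_genes <- unique(c(edges$gene_a, edges$gene_b))
  genes <- lex_sort(unique(c(deg_union, edge_genes)))
  category <- ifelse(genes %in% deg_union,
                     ifelse(genes %in% known, "IDEG", "ODEG"), "OG")
  if (!any(category == "IDEG"))
    warning("no known disease gene is differentially expressed (empty IDEG set)")
  structure(data.frame(gene = genes, category = category,
                       known = genes %in% known, stringsAsFactors = FALSE),
            class = c("gene_catalog", "data.frame"))
}

unordered_pair_type <- function(cat_a, cat_b) {
  paste(pmin(cat_a, cat_b), pmax(cat_a, cat_b), sep = "-")
}

#' Filter a scored edge list by per-pair-type confidence thresholds
#'
#' An edge is kept iff its confidence is strictly greater than the threshold
#' of its unordered category pair type; OG-OG edges are always dropped and
#' isolated nodes removed.
#'
#' @param edges a [scored_edges()] data frame.
#' @param catalog a [categorize_genes()] catalog covering all edge genes.
#' @param thresholds named numeric vector as in [default_pair_thresholds()].
#' @return A list of class `ppi_network`: `edges` (data.frame gene_a, gene_b,
#'   confidence, pair_type), `nodes`, and `kept_dropped` (per-type counts).
#' @export
filter_edges <- function(edges, catalog, thresholds = default_pair_thresholds()) {
  cat_of <- stats::setNames(catalog$category, catalog$gene)
  ca <- cat_of[edges$gene_a]; cb <- cat_of[edges$gene_b]
  if (any(is.na(ca)) || any(is.na(cb)))
    np_stop("edge gene(s) missing from the catalog: ",
            paste(utils::head(unique(c(edges$gene_a[is.na(ca)],
                                       edges$gene_b[is.na(cb)])), 3L),
                  collapse = ", "))
  type <- unordered_pair_type(ca, cb)
  needed <- setdiff(unique(type), "OG-OG")
  missing <- setdiff(needed, names(thresholds))
  if (length(missing) > 0L)
    np_stop("no threshold configured for pair type(s): ",
            paste(missing, collapse = ", "))
  keep <- type != "OG-OG" & edges$confidence > thresholds[type]
  keep[is.na(keep)] <- FALSE
  kept_n <- tapply(keep, type, sum)
  drop_n <- tapply(!keep, type, sum)
  kept_dropped <- data.frame(pair_type = names(kept_n),
                             kept = as.integer(kept_n),
                             dropped = as.integer(drop_n),
                             stringsAsFactors = FALSE, row.names = NULL)
  kept_edges <- edges[keep, , drop = FALSE]
  kept_edges$pair_type <- type[keep]
  rownames(kept_edges) <- NULL
  nodes <- lex_sort(unique(c(kept_edges$gene_a, kept_edges$gene_b)))
  np_msg(sum(keep), "/", length(keep), " edges kept; ", length(nodes), " nodes")
  structure(list(edges = as.data.frame(kept_edges), nodes = nodes,
                 kept_dropped = kept_dropped),
            class = "ppi_network")
}

#' Treat a raw scored edge list as a network (no category filtering)
#'
#' @param edges a [scored_edges()] data frame.
#' @return A `ppi_network`.
#' @export
as_network <- function(edges) {
  e <- as.data.frame(edges)
  nodes <- lex_sort(unique(c(e$gene_a, e$gene_b)))
  structure(list(edges = e, nodes = nodes, kept_dropped = NULL),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

np_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Global properties of a network
#'
#' Degree histogram, per-category node and edge counts, global clustering
#' coefficient (transitivity: 3 x triangles / connected triples), and the
#' average shortest-path length and diameter of the largest connected
#' component. Also reports the DEG (IDEG + ODEG) to OG balance when the
#' edge table carries pair types.
#'
#' @param net a `ppi_network`.
#' @param catalog optional `gene_catalog` for per-category counts.
#' @return A list of class `network_report`.
#' @export
network_report <- function(net, catalog = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  if (length(net$nodes) == 0L) np_stop("empty network")
  g <- np_igraph(net)
  comp <- igraph::components(g)
  big <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  deg <- igraph::degree(g)
  rep <- list(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    degree_histogram = table(deg),
    clustering_coefficient = igraph::transitivity(g, type = "global"),
    avg_path_length = igraph::mean_distance(big),
    diameter = igraph::diameter(big),
    largest_component_size = max(comp$csize)
  )
  if (!is.null(catalog)) {
    cat_of <- stats::setNames(catalog$category, catalog$gene)
    node_cat <- table(factor(cat_of[net$nodes], c("IDEG", "ODEG", "OG")))
    rep$nodes_per_category <- node_cat
    rep$deg_og_balance <- unname((node_cat["IDEG"] + node_cat["ODEG"]) /
                                   max(1L, node_cat["OG"]))
    if (!is.null(net$edges$pair_type))
      rep$edges_per_pair_type <- table(net$edges$pair_type)
  }
  structure(rep, class = "network_report")
}
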