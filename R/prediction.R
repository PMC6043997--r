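## Novel-gene prediction from significant clusters, and per-cluster
## annotation (pathway-style) frequency summaries.

#' Predict novel disease genes from significant clusters
#'
#' The prediction set is the union of member genes of clusters with
#' `adjusted_p < alpha`, minus the known disease genes (IDEGs). Each gene is
#' annotated with its minimum adjusted p over containing clusters and its
#' SScore; the list is sorted by ascending adjusted p, then descending
#' SScore, then id.
#'
#' @param table an `enrichment_table`.
#' @param clusters the `cluster_set` the table was computed from.
#' @param catalog a `gene_catalog` (IDEGs are excluded from predictions).
#' @param alpha strict significance threshold on adjusted p (default 0.05).
#' @param log_base SScore log base.
#' @return A data.frame of class `prediction_list`: `gene`, `min_adj_p`,
#'   `sscore`, `n_significant_clusters`, `rank`.
#' @export
predict_genes <- function(table, clusters, catalog, alpha = 0.05,
                          log_base = 10) {
  stopifnot(inherits(table, "enrichment_table"),
            inherits(clusters, "cluster_set"))
  sig <- which(table$adjusted_p < alpha)
  scores <- sscore(table, clusters, log_base)
  known <- catalog$gene[catalog$category == "IDEG"]
  if (length(sig) == 0L) {
    warning("no significant cluster at alpha = ", alpha)
    out <- data.frame(gene = character(0), min_adj_p = numeric(0),
                      sscore = numeric(0), n_significant_clusters = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("prediction_list", "data.frame")
    return(out)
  }
  sig_members <- unlist(clusters$clusters[sig])
  sig_idx <- rep(sig, lengths(clusters$clusters[sig]))
  n_sig <- tapply(sig_idx, sig_members, length)
  genes <- setdiff(unique(sig_members), known)
  sc <- scores[match(genes, scores$gene), ]
  out <- data.frame(gene = genes,
                    min_adj_p = sc$min_adj_p,
                    sscore = sc$sscore,
                    n_significant_clusters = as.integer(n_sig[genes]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$min_adj_p, -out$sscore, out$gene, method = "radix"), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("prediction_list", "data.frame")
  out
}

#' Top-annotation frequencies across significant clusters
#'
#' For every significant cluster (`adjusted_p < alpha`), terms are ranked by
#' the number of member genes mapped to them and the top three kept (ties at
#' the cut broken lexicographically, with a message); frequencies count in
#' how many clusters each term made the top three.
#'
#' @param clusters a `cluster_set`.
#' @param table the matching `enrichment_table`.
#' @param annotation an annotation map from [read_annotation_map()].
#' @param alpha strict significance threshold on adjusted p.
#' @param top_n how many top terms to keep per cluster (default 3).
#' @return A list of class `annotation_frequency`: `per_cluster` (named list
#'   of character term vectors) and `frequencies` (data.frame term, name,
#'   frequency, sorted by decreasing frequency then term).
#' @export
annotation_frequencies <- function(clusters, table, annotation, alpha = 0.05,
                                   top_n = 3L) {
  stopifnot(inherits(clusters, "cluster_set"),
            inherits(table, "enrichment_table"))
  sig <- which(table$adjusted_p < alpha)
  per_cluster <- list()
  for (i in sig) {
    genes <- clusters$clusters[[i]]
    terms <- unlist(annotation$term_of[genes], use.names = FALSE)
    if (is.null(terms) || length(terms) == 0L) {
      np_msg("cluster ", table$cluster_id[i], " has no annotated gene")
      next
    }
    cnt <- sort(table(terms), decreasing = TRUE)
    ## deterministic cut: order by count desc, then term lexicographically
    o <- order(-as.integer(cnt), names(cnt), method = "radix")
    ranked <- names(cnt)[o]
    counts <- as.integer(cnt)[o]
    k <- min(top_n, length(ranked))
    if (length(counts) > k && counts[k + 1L] == counts[k])
      np_msg("tie at rank ", k, " in cluster ", table$cluster_id[i],
             " broken lexicographically")
    per_cluster[[table$cluster_id[i]]] <- ranked[seq_len(k)]
  }
  all_terms <- unlist(per_cluster, use.names = FALSE)
  freq <- if (length(all_terms)) {
    tb <- table(all_terms)
    df <- data.frame(term = names(tb), frequency = as.integer(tb),
                     stringsAsFactors = FALSE)
    df$name <- unname(annotation$term_names[df$term])
    df <- df[order(-df$frequency, df$term, method = "radix"),
             c("term", "name", "frequency")]
    rownames(df) <- NULL
    df
  } else data.frame(term = character(0), name = character(0),
                    frequency = integer(0))
  structure(list(per_cluster = per_cluster, frequencies = freq),
            class = "annotation_frequency")
}
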