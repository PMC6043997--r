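## Per-cluster enrichment of known disease genes and the per-gene
## significance score. Each cluster yields a 2x2 table (a: known disease
## genes in the cluster, b: other cluster genes, c: known disease genes
## outside, d: all remaining network genes); the one-sided Fisher p-value is
## the upper hypergeometric tail P(X >= a), and BH adjustment is applied
## across the clusters of one cluster set. A gene's SScore is -log of the
## smallest raw p-value over the clusters containing it.

#' Fisher enrichment of known disease genes in each cluster
#'
#' @param clusters a `cluster_set`.
#' @param catalog a `gene_catalog`; the known disease genes used are the
#'   IDEGs (known and differentially expressed) present in the network.
#' @param network_genes character vector of all network genes (the
#'   universe `n` of the 2x2 tables); defaults to the union of cluster
#'   members, which equals the node set under DPClusO coverage.
#' @param alternative `"greater"` (default, over-enrichment) or
#'   `"two.sided"` (minimum-likelihood method).
#' @return A data.frame of class `enrichment_table`: per cluster `a`, `b`,
#'   `c`, `d`, `n`, `fisher_p`, `adjusted_p` plus `cluster_id`, `size`,
#'   `members`.
#' @export
fisher_enrichment <- function(clusters, catalog,
                              network_genes = NULL,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(clusters, "cluster_set"))
  network_genes <- network_genes %||% lex_sort(unique(unlist(clusters$clusters)))
  outside <- setdiff(unique(unlist(clusters$clusters)), network_genes)
  if (length(outside) > 0L)
    np_stop("cluster member(s) outside the network universe: ",
            paste(utils::head(outside, 3L), collapse = ", "))
  known <- catalog$gene[catalog$category == "IDEG"]
  known <- intersect(known, network_genes)
  if (length(known) == 0L)
    np_stop("no known disease gene (IDEG) present in the network")
  n <- length(network_genes)
  K <- length(known)
  a <- vapply(clusters$clusters, function(m) length(intersect(m, known)), 0L)
  size <- lengths(clusters$clusters)
  b <- size - a
  c_ <- K - a
  d <- n - K - b
  p <- if (alternative == "greater") {
    stats::phyper(a - 1L, K, n - K, size, lower.tail = FALSE)
  } else {
    vapply(seq_along(a), function(i)
      stats::fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), 2L))$p.value, 0)
  }
  p <- pmin(1, p)
  structure(data.frame(cluster_id = sprintf("c%04d", seq_along(a)),
                       size = size, a = a, b = b, c = c_, d = d, n = n,
                       fisher_p = p, adjusted_p = bh_adjust(p),
                       members = vapply(clusters$clusters, paste, "",
                                        collapse = ","),
                       stringsAsFactors = FALSE),
            class = c("enrichment_table", "data.frame"))
}

#' Per-gene significance scores from cluster enrichment
#'
#' Every gene takes the smallest raw Fisher p-value over the clusters that
#' contain it (DPClusO coverage guarantees at least one) and
#' `SScore = -log(min p)` in the configured base. A zero p-value is mapped
#' to the smallest representable positive double, with a warning.
#'
#' @param table an `enrichment_table`.
#' @param clusters the `cluster_set` the table was computed from.
#' @param log_base base of the logarithm (default 10; the ranking is
#'   invariant to this choice).
#' @return A data.frame of class `gene_score_table`: `gene`, `n_clusters`,
#'   `min_p`, `min_adj_p`, `sscore`, sorted by decreasing `sscore` then id.
#' @export
sscore <- function(table, clusters, log_base = 10) {
  stopifnot(inherits(table, "enrichment_table"),
            inherits(clusters, "cluster_set"))
  genes <- unlist(clusters$clusters)
  idx <- rep(seq_along(clusters$clusters), lengths(clusters$clusters))
  min_p <- tapply(table$fisher_p[idx], genes, min)
  min_adj <- tapply(table$adjusted_p[idx], genes, min)
  n_cl <- tapply(idx, genes, length)
  g <- names(min_p)
  p <- as.numeric(min_p)
  if (any(p == 0)) {
    warning(sum(p == 0), " gene(s) with p = 0 mapped to the smallest ",
            "representable positive p")
    p[p == 0] <- .Machine$double.xmin
  }
  res <- data.frame(gene = g, n_clusters = as.integer(n_cl),
                    min_p = as.numeric(min_p),
                    min_adj_p = as.numeric(min_adj),
                    sscore = -log(p, base = log_base),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$sscore, res$gene, method = "radix"), ]
  rownames(res) <- NULL
  class(res) <- c("gene_score_table", "data.frame")
  res
}
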