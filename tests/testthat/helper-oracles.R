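# Independent reference implementations used as test oracles. These are
# deliberately naive (direct enumeration / direct formulas) and share no code
# with the package internals they check.

# upper-tail hypergeometric P(X >= a) by direct enumeration over log-binomials
oracle_hyper_upper <- function(a, K, n, size) {
  xs <- max(0, a):min(K, size)
  if (a > min(K, size)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(n - K, size - xs) - lchoose(n, size)))
}

# Benjamini-Hochberg by the direct sorted step-up formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# AUC as the mean over all positive x negative pairs of
# [score_p > score_n] + 0.5 [score_p == score_n]
oracle_auc_pairwise <- function(scores, is_pos) {
  sp <- scores[is_pos]; sn <- scores[!is_pos]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# build a scored_edges frame from a plain pair list, default confidence 1
edge_fixture <- function(pairs, confidence = 1) {
  scored_edges(vapply(pairs, `[`, "", 1L), vapply(pairs, `[`, "", 2L),
               rep_len(confidence, length(pairs)))
}

# small named graphs used across clustering tests
graph_triangle <- function() as_network(edge_fixture(
  list(c("a", "b"), c("b", "c"), c("a", "c"))))

graph_two_triangles_bridge <- function() as_network(edge_fixture(
  list(c("a", "b"), c("b", "c"), c("a", "c"),
       c("d", "e"), c("e", "f"), c("d", "f"),
       c("c", "d"))))

# clique on the given node names, plus optional extra edges
graph_cliques <- function(..., extra = list()) {
  cliques <- list(...)
  pairs <- list()
  for (cl in cliques) {
    cb <- utils::combn(cl, 2L)
    for (k in seq_len(ncol(cb))) pairs[[length(pairs) + 1L]] <- cb[, k]
  }
  for (e in extra) pairs[[length(pairs) + 1L]] <- e
  as_network(edge_fixture(pairs))
}

# recompute a cluster's density directly from a network's edge table
recount_density <- function(net, members) {
  if (length(members) == 1L) return(1)
  e <- net$edges
  inside <- e$gene_a %in% members & e$gene_b %in% members
  sum(inside) / (length(members) * (length(members) - 1) / 2)
}

# is the induced subgraph on `members` connected?
is_connected_subgraph <- function(net, members) {
  if (length(members) <= 1L) return(TRUE)
  e <- net$edges
  inside <- e$gene_a %in% members & e$gene_b %in% members
  g <- igraph::graph_from_data_frame(e[inside, 1:2], directed = FALSE,
                                     vertices = data.frame(name = members))
  igraph::is_connected(g)
}

# tiny deterministic count_matrix fixture
counts_fixture <- function(n_genes = 6L, groups = c(A = 3L, B = 3L),
                           seed = 42L) {
  set.seed(seed)
  samples <- unlist(lapply(names(groups), function(g)
    paste0(g, seq_len(groups[[g]]))))
  m <- matrix(rpois(n_genes * sum(groups), 50), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)), samples))
  count_matrix(m, setNames(rep(names(groups), groups), samples))
}
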