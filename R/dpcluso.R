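## DPClusO: greedy overlapping density-based graph clustering.
##
## A cluster k has density d_k = |E_k| / (N_k (N_k - 1) / 2) (singletons have
## density 1 by convention) and a candidate node n has cluster property
## cp_nk = E_nk / (d_k * N_k), where E_nk counts edges between n and the
## cluster members. Clusters are grown greedily from a max-weight seed and
## the algorithm repeats on the graph minus already-clustered nodes, so
## every node ends up in at least one cluster (coverage); a completed
## cluster is extended once against the original graph, which is what makes
## clusters overlap.
##
## All tie-breaks are deterministic: candidate priority is larger E_nk, then
## larger node weight, then lexicographically smaller id; seed priority is
## larger weight, then larger degree, then lexicographically smaller id.

EPS <- 1e-9

## 0/1 numeric adjacency matrix over lexicographically sorted node names
adjacency_matrix <- function(net) {
  nodes <- lex_sort(net$nodes)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(net$edges) > 0L) {
    ia <- match(net$edges$gene_a, nodes)
    ib <- match(net$edges$gene_b, nodes)
    A[cbind(ia, ib)] <- 1
    A[cbind(ib, ia)] <- 1
  }
  A
}

## node weight = sum over incident edges of the endpoints' common-neighbor
## count (the edge weight); zero for nodes in no triangle
weights_from_adjacency <- function(A) {
  if (nrow(A) == 0L) return(numeric(0))
  common <- A %*% A
  stats::setNames(rowSums(A * common), rownames(A))
}

#' DPClusO node weights
#'
#' The weight of an edge is the number of common neighbors of its endpoints;
#' the weight of a node is the sum of its incident edge weights. Seeds are
#' chosen by decreasing weight.
#'
#' @param net a `ppi_network`.
#' @return Named numeric vector of node weights.
#' @export
node_weights <- function(net) {
  weights_from_adjacency(adjacency_matrix(net))
}

## Greedy growth on adjacency A starting from member index set; E_in is the
## current internal edge count and Evec the per-node count of edges into the
## cluster. active restricts candidates (NULL = all nodes).
grow_on <- function(A, w, members, E_in, Evec, d_in, cp_in, active = NULL) {
  in_cluster <- logical(nrow(A))
  in_cluster[members] <- TRUE
  repeat {
    cand <- which(Evec > 0 & !in_cluster)
    if (!is.null(active)) cand <- cand[active[cand]]
    if (length(cand) == 0L) break
    ## top candidate: larger E_nk, then larger weight, then smaller id
    o <- order(-Evec[cand], -w[cand], cand)[1L]
    top <- cand[o]
    Nk <- sum(in_cluster)
    dk <- if (Nk == 1L) 1 else E_in / (Nk * (Nk - 1) / 2)
    cp <- Evec[top] / (dk * Nk)
    d_new <- (E_in + Evec[top]) / ((Nk + 1) * Nk / 2)
    if (d_new >= d_in - EPS && cp >= cp_in - EPS) {
      in_cluster[top] <- TRUE
      E_in <- unname(E_in + Evec[top])
      Evec <- unname(Evec + A[, top])
    } else break
  }
  list(members = which(in_cluster), E_in = E_in, Evec = Evec)
}

#' Grow a single DPClusO cluster from a seed node
#'
#' Starting from the seed, the highest-priority neighbor of the current
#' members (largest number of edges into the cluster, ties by node weight
#' then id) is added as long as the augmented density stays `>= d_in` and
#' the candidate's cluster property `cp_nk >= cp_in`; growth stops at the
#' first rejected top candidate.
#'
#' @param net a `ppi_network`.
#' @param seed seed node id.
#' @param d_in density threshold in (0, 1].
#' @param cp_in cluster-property threshold.
#' @return Character vector of member ids (lexicographic order) with
#'   attribute `density`.
#' @export
grow_cluster <- function(net, seed, d_in, cp_in = 0.5) {
  A <- adjacency_matrix(net)
  if (!seed %in% rownames(A)) np_stop("seed '", seed, "' not in network")
  w <- weights_from_adjacency(A)
  s <- match(seed, rownames(A))
  g <- grow_on(A, w, s, 0, A[, s], d_in, cp_in)
  members <- rownames(A)[g$members]
  nk <- length(members)
  structure(members,
            density = if (nk == 1L) 1 else g$E_in / (nk * (nk - 1) / 2))
}

#' Cluster a network with DPClusO
#'
#' Repeatedly: compute node weights on the working graph (the original graph
#' restricted to not-yet-clustered nodes), grow a cluster from the
#' max-weight seed, extend the completed cluster once against the original
#' graph with the same acceptance rule (candidates may already belong to
#' other clusters, producing overlap), record it, and remove its working
#' members. Every node is assigned to at least one cluster.
#'
#' @param net a `ppi_network`.
#' @param d_in density threshold in (0, 1].
#' @param cp_in cluster-property threshold (default 0.5, the DPClus
#'   convention).
#' @return A list of class `cluster_set`: `clusters` (list of character
#'   member vectors), `density` (recomputed per cluster on the original
#'   graph), `d_in`, `cp_in`, `coverage` (fraction of nodes in >= 1
#'   cluster, always 1).
#' @export
cluster_network <- function(net, d_in, cp_in = 0.5) {
  stopifnot(inherits(net, "ppi_network"))
  if (d_in <= 0 || d_in > 1) np_stop("d_in must be in (0, 1]")
  A <- adjacency_matrix(net)
  n <- nrow(A)
  if (n == 0L)
    return(structure(list(clusters = list(), density = numeric(0),
                          d_in = d_in, cp_in = cp_in, coverage = 1),
                     class = "cluster_set"))
  w_full <- weights_from_adjacency(A)
  active <- rep(TRUE, n)
  ## working-graph state, updated incrementally as clustered nodes are
  ## deleted: Aw is the adjacency restricted to active nodes, Cw the matrix
  ## of common-neighbor counts and w_act / deg_act the node weights and
  ## degrees on the working graph
  Aw <- A
  Cw <- A %*% A
  w_act <- rowSums(Aw * Cw)
  deg_act <- rowSums(Aw)
  clusters <- list(); densities <- numeric(0)
  keys <- new.env(hash = TRUE)
  while (any(active)) {
    ## max-weight active seed; ties by degree, then smaller id
    act <- which(active)
    cand <- act[w_act[act] == max(w_act[act])]
    if (length(cand) > 1L) cand <- cand[deg_act[cand] == max(deg_act[cand])]
    seed <- cand[1L]
    ## grow on the working graph
    g <- grow_on(Aw, w_act, seed, 0, Aw[, seed], d_in, cp_in)
    ## extend once against the original graph
    mem <- g$members
    E_in <- sum(A[mem, mem]) / 2
    Evec <- colSums(A[mem, , drop = FALSE])
    ext <- grow_on(A, w_full, mem, E_in, Evec, d_in, cp_in)
    members <- ext$members
    nk <- length(members)
    dens <- if (nk == 1L) 1 else ext$E_in / (nk * (nk - 1) / 2)
    key <- paste(members, collapse = ",")
    if (!exists(key, envir = keys, inherits = FALSE)) {
      assign(key, TRUE, envir = keys)
      clusters[[length(clusters) + 1L]] <- rownames(A)[members]
      densities <- c(densities, dens)
    }
    ## delete the cluster's working-graph members; common-neighbor counts,
    ## weights and degrees are patched locally (O(degree^2) per node)
    for (v in members[active[members]]) {
      nb <- which(Aw[, v] > 0)
      if (length(nb) > 0L) {
        ## v no longer a common neighbor of its neighbor pairs; where such a
        ## pair is itself an edge, both endpoints lose weight
        Cw[nb, nb] <- Cw[nb, nb] - 1
        if (length(nb) > 1L) {
          adj_nb <- Aw[nb, nb, drop = FALSE]
          w_act[nb] <- w_act[nb] - rowSums(adj_nb)
        }
        ## remove the edges incident to v
        w_act[nb] <- w_act[nb] - Cw[nb, v]
        deg_act[nb] <- deg_act[nb] - 1
        Aw[v, nb] <- 0; Aw[nb, v] <- 0
      }
      Cw[v, ] <- 0; Cw[, v] <- 0
      w_act[v] <- 0; deg_act[v] <- 0
      active[v] <- FALSE
    }
  }
  structure(list(clusters = clusters, density = densities,
                 d_in = d_in, cp_in = cp_in, coverage = 1),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters (d_in=%.2f, cp_in=%.2f), max size %d\n",
              length(x$clusters), x$d_in, x$cp_in,
              if (length(x$clusters)) max(lengths(x$clusters)) else 0L))
  invisible(x)
}

#' Run DPClusO over a grid of density thresholds
#'
#' @param net a `ppi_network`.
#' @param density_grid strictly increasing densities in (0, 1].
#' @param cp_in cluster-property threshold shared by all runs.
#' @return A list of class `cluster_grid`: `sets` (named list of
#'   `cluster_set`, names are the densities) and `summary` (data.frame with
#'   density, n_clusters, max_size, avg_size).
#' @export
cluster_grid <- function(net, density_grid = seq(0.1, 0.9, by = 0.1),
                         cp_in = 0.5) {
  sets <- lapply(density_grid, function(d) cluster_network(net, d, cp_in))
  names(sets) <- format(density_grid)
  structure(list(sets = sets, summary = cluster_summary(sets, density_grid)),
            class = "cluster_grid")
}

#' Summary table of a list of cluster sets
#'
#' @param sets list of `cluster_set` objects.
#' @param densities numeric vector of the density thresholds used.
#' @return data.frame with one row per density: number of clusters, size of
#'   the biggest cluster and average cluster size.
#' @export
cluster_summary <- function(sets, densities = vapply(sets, `[[`, 0, "d_in")) {
  data.frame(
    density = densities,
    n_clusters = vapply(sets, function(s) length(s$clusters), 0L),
    max_size = vapply(sets, function(s)
      if (length(s$clusters)) max(lengths(s$clusters)) else 0L, 0L),
    avg_size = vapply(sets, function(s)
      if (length(s$clusters)) mean(lengths(s$clusters)) else 0, 0),
    row.names = NULL)
}

#' Write a cluster set as TSV (cluster id, size, density, members)
#' @param x a `cluster_set`.
#' @param path output path.
#' @export
write_clusters <- function(x, path) {
  df <- data.frame(
    cluster_id = sprintf("c%04d", seq_along(x$clusters)),
    size = lengths(x$clusters),
    density = x$density,
    members = vapply(x$clusters, paste, "", collapse = "\t"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
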