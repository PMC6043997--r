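## ROC assessment of the significance score against reference disease-gene
## lists, density selection by maximum AUC, and hypergeometric validation of
## predicted-gene overlap with an external reference.

#' ROC curve of gene scores against a positive reference list
#'
#' Thresholds are the distinct scores in decreasing order; at threshold `th`
#' a gene is called positive when its score is `>= th`. TP counts reference
#' genes called, FP non-reference genes called, `TPR = TP / (TP + FN)`,
#' `FPR = FP / (FP + TN)`. The AUC is the trapezoid area over (FPR, TPR)
#' including the (0,0) and (1,1) endpoints, which equals the probability
#' that a random positive outranks a random negative with ties counted 1/2.
#'
#' @param scores a `gene_score_table` or a named numeric vector of scores.
#' @param positives character vector of reference positive genes.
#' @param universe genes to evaluate; typically the network genes minus the
#'   known disease genes that produced the scores. Genes of the universe
#'   absent from `scores` get score 0 (they were in no scored cluster).
#' @return A list of class `roc_curve`: `curve` (data.frame th, TP, FP, TN,
#'   FN, TPR, FPR) and `auc`.
#' @export
roc_curve <- function(scores, positives, universe = NULL) {
  s <- if (inherits(scores, "gene_score_table"))
    stats::setNames(scores$sscore, scores$gene) else scores
  universe <- universe %||% names(s)
  sc <- stats::setNames(rep(0, length(universe)), universe)
  shared <- intersect(universe, names(s))
  sc[shared] <- s[shared]
  is_pos <- universe %in% positives
  P <- sum(is_pos); N <- sum(!is_pos)
  if (P == 0L || N == 0L)
    np_stop("need at least one positive and one negative in the universe")
  th <- sort(unique(unname(sc)), decreasing = TRUE)
  TP <- vapply(th, function(t) sum(sc[is_pos] >= t), 0)
  FP <- vapply(th, function(t) sum(sc[!is_pos] >= t), 0)
  curve <- data.frame(th = th, TP = TP, FP = FP,
                      TN = N - FP, FN = P - TP,
                      TPR = TP / P, FPR = FP / N)
  x <- c(0, curve$FPR); y <- c(0, curve$TPR)
  if (x[length(x)] != 1 || y[length(y)] != 1) { x <- c(x, 1); y <- c(y, 1) }
  auc <- sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
  structure(list(curve = curve, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d thresholds, AUC = %.4f\n", nrow(x$curve), x$auc))
  invisible(x)
}

#' Select the clustering density with the highest AUC
#'
#' @param score_tables named list of `gene_score_table`s, one per density
#'   (names are the densities).
#' @param positives reference positive genes.
#' @param universe evaluation universe (see [roc_curve()]).
#' @return A list of class `density_selection`: `auc_table` (data.frame
#'   density, auc), `selected_density`, `selected_index`. Ties go to the
#'   smaller density (with a message).
#' @export
select_density <- function(score_tables, positives, universe = NULL) {
  if (length(score_tables) == 0L) np_stop("need at least one cluster set")
  dens <- as.numeric(names(score_tables))
  auc <- vapply(score_tables, function(s)
    roc_curve(s, positives, universe)$auc, 0)
  best <- max(auc)
  cand <- which(auc >= best - 1e-12)
  if (length(cand) > 1L)
    np_msg("AUC tie between densities ",
           paste(dens[cand], collapse = ", "), "; smaller density selected")
  sel <- cand[which.min(dens[cand])]
  structure(list(auc_table = data.frame(density = dens, auc = unname(auc)),
                 selected_density = dens[sel], selected_index = sel),
            class = "density_selection")
}

#' Hypergeometric validation of a predicted gene list against a reference
#'
#' Upper-tail p-value of observing at least `k` overlaps when `n_pred` genes
#' are drawn from a universe of `N` genes containing `K` reference genes.
#'
#' @param predicted character vector of predicted genes.
#' @param reference character vector of reference genes.
#' @param N universe size (default 20000, a conventional human gene count).
#' @return A list of class `overlap_validation`: `N`, `n_pred`, `K`, `k`,
#'   `p_value`.
#' @export
overlap_validation <- function(predicted, reference, N = 20000) {
  predicted <- unique(predicted); reference <- unique(reference)
  if (N < length(union(predicted, reference)))
    np_stop("N smaller than |predicted U reference|")
  k <- length(intersect(predicted, reference))
  n_pred <- length(predicted); K <- length(reference)
  p <- stats::phyper(k - 1L, K, N - K, n_pred, lower.tail = FALSE)
  structure(list(N = N, n_pred = n_pred, K = K, k = k,
                 p_value = min(1, p)),
            class = "overlap_validation")
}

#' Per-source and union overlap counts of a predicted list
#'
#' @param predicted character vector of predicted genes.
#' @param reference_lists named list of reference gene vectors (e.g. several
#'   curated databases).
#' @return A list: `per_source` (named integer overlap counts), `union_count`
#'   and `union_fraction` (fraction of predictions found in any source).
#' @export
reference_overlaps <- function(predicted, reference_lists) {
  if (length(reference_lists) == 0L) np_stop("need at least one reference list")
  predicted <- unique(predicted)
  per <- vapply(reference_lists, function(l)
    length(intersect(predicted, l)), 0L)
  u <- unique(unlist(reference_lists))
  uc <- length(intersect(predicted, u))
  list(per_source = per, union_count = uc,
       union_fraction = if (length(predicted)) uc / length(predicted) else 0)
}
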