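## Differential-expression stage: trimmed-mean-of-M-values (TMM) library
## normalization, a conditional negative-binomial exact test per two-group
## comparison, Benjamini-Hochberg FDR, and the union of DEG sets across
## comparisons. This is a self-contained NB exact-test implementation with a
## pooled method-of-moments common dispersion and simple common-scale
## pseudocounts; numerical parity with any particular GLM toolkit is not a
## design goal, the conditional-exact-test semantics are.

#' Remove genes whose counts are zero in every sample
#'
#' @param x a [count_matrix()].
#' @return The filtered [count_matrix()]; gene order otherwise preserved.
#' @export
filter_all_zero <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- rowSums(x$counts) > 0L
  if (!any(keep)) np_stop("all genes have zero counts in every sample")
  np_msg(sum(!keep), " all-zero gene(s) removed")
  count_matrix(x$counts[keep, , drop = FALSE], x$groups)
}

#' TMM normalization factors
#'
#' For each sample, the factor is `2^w`, where `w` is the weighted mean of
#' per-gene M-values (log2 ratio of library-size-normalized proportions
#' against a reference sample) after trimming the most extreme 30% of
#' M-values and 5% of A-values on each side; weights are inverse asymptotic
#' (delta-method binomial) variances. Genes with a zero count in either the
#' sample or the reference are excluded. Factors are centered so their
#' geometric mean is 1.
#'
#' @param x a [count_matrix()].
#' @param ref_sample reference sample id; default is the sample whose
#'   upper-quartile proportion is closest to the mean upper-quartile.
#' @param trim_m,trim_a two-sided trim fractions for M and A values.
#' @return A data.frame of class `norm_factors` with columns `sample`,
#'   `lib_size`, `factor` and `effective_lib_size`.
#' @export
tmm_factors <- function(x, ref_sample = NULL, trim_m = 0.3, trim_a = 0.05) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  lib <- colSums(counts)
  if (any(lib == 0)) np_stop("sample with zero library size: ",
                             colnames(counts)[lib == 0][1])
  if (is.null(ref_sample)) {
    uq <- apply(counts, 2L, function(v) stats::quantile(v, 0.75)) / lib
    ref_sample <- colnames(counts)[which.min(abs(uq - mean(uq)))]
  }
  if (!ref_sample %in% colnames(counts)) np_stop("unknown reference sample")
  r <- counts[, ref_sample]; nr <- lib[ref_sample]
  f <- vapply(colnames(counts), function(s) {
    if (s == ref_sample) return(1)
    y <- counts[, s]; ny <- lib[s]
    ok <- y > 0 & r > 0
    if (!any(ok)) { warning("all genes trimmed for sample ", s,
                            "; factor set to 1"); return(1) }
    yk <- y[ok]; rk <- r[ok]
    m <- log2((yk / ny) / (rk / nr))
    a <- 0.5 * log2((yk / ny) * (rk / nr))
    keep_m <- m >= stats::quantile(m, trim_m) & m <= stats::quantile(m, 1 - trim_m)
    keep_a <- a >= stats::quantile(a, trim_a) & a <= stats::quantile(a, 1 - trim_a)
    keep <- keep_m & keep_a
    if (!any(keep)) { warning("all genes trimmed for sample ", s,
                              "; factor set to 1"); return(1) }
    w <- 1 / ((ny - yk[keep]) / (ny * yk[keep]) + (nr - rk[keep]) / (nr * rk[keep]))
    2^(sum(w * m[keep]) / sum(w))
  }, 0)
  f <- f / exp(mean(log(f))) # center to geometric mean 1
  structure(data.frame(sample = colnames(counts), lib_size = unname(lib),
                       factor = unname(f),
                       effective_lib_size = unname(lib * f),
                       stringsAsFactors = FALSE),
            class = c("norm_factors", "data.frame"))
}

## Scale counts of the given samples to a common effective library size
## (geometric mean of the samples' effective sizes) and round.
pseudo_counts <- function(counts, eff_sizes) {
  common <- exp(mean(log(eff_sizes)))
  round(sweep(counts, 2L, common / eff_sizes, `*`))
}

## Pooled method-of-moments common dispersion across genes:
## within-group sample mean m and variance v per gene; phi solves
## v = m + phi m^2 pooled over genes and groups, clamped at >= 0.
pooled_dispersion <- function(pseudo, group_idx) {
  num <- 0; den <- 0
  for (idx in group_idx) {
    if (length(idx) < 2L) next
    m <- rowMeans(pseudo[, idx, drop = FALSE])
    v <- apply(pseudo[, idx, drop = FALSE], 1L, stats::var)
    ok <- m > 0
    num <- num + sum(v[ok] - m[ok])
    den <- den + sum(m[ok]^2)
  }
  if (den == 0) return(0)
  max(0, num / den)
}

## Two-sided conditional exact p-value for one gene: given group totals
## (ta, tb) of na and nb samples sharing per-sample mean mu and dispersion
## phi, condition on t = ta + tb and sum the probabilities of all group-A
## totals whose probability does not exceed that of the observed one.
nb_exact_p <- function(ta, tb, na, nb, phi) {
  t <- ta + tb
  if (t == 0) return(1)
  mu <- t / (na + nb)
  xs <- 0:t
  if (phi <= 0) {
    ## Poisson limit: conditional distribution is Binomial(t, na/(na+nb))
    lp <- stats::dbinom(xs, t, na / (na + nb), log = TRUE)
  } else {
    lp <- stats::dnbinom(xs, size = na / phi, mu = na * mu, log = TRUE) +
      stats::dnbinom(t - xs, size = nb / phi, mu = nb * mu, log = TRUE)
    lp <- lp - log(sum(exp(lp - max(lp)))) - max(lp)
  }
  p_obs <- lp[ta + 1L]
  min(1, sum(exp(lp[lp <= p_obs + 1e-12])))
}

#' Conditional NB exact test for one two-group comparison
#'
#' Counts are scaled to a common effective library size (rounded
#' pseudocounts), a common dispersion is estimated across genes by a pooled
#' method of moments (clamped at zero), and each gene gets a two-sided exact
#' p-value conditional on its total pseudocount: the sum of probabilities of
#' all group-A totals at most as probable as the observed one under NB group
#' sums with a shared per-sample mean.
#'
#' @param x a [count_matrix()].
#' @param group_a,group_b group labels to compare (a vs b).
#' @param factors optional [tmm_factors()] result; computed from `x` when
#'   missing.
#' @return A data.frame of class `de_result`: per gene, normalized group
#'   means, `log2fc` (a over b), `pvalue` and BH `fdr`; attributes
#'   `comparison` and `dispersion`.
#' @export
nb_exact_test <- function(x, group_a, group_b, factors = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  sel_a <- names(x$groups)[x$groups == group_a]
  sel_b <- names(x$groups)[x$groups == group_b]
  if (length(sel_a) < 2L || length(sel_b) < 2L)
    np_stop("both groups need >= 2 samples")
  factors <- factors %||% tmm_factors(x)
  eff <- stats::setNames(factors$effective_lib_size, factors$sample)
  if (all(colSums(x$counts[, sel_a, drop = FALSE]) == 0))
    np_stop("group '", group_a, "' has all-zero libraries")
  if (all(colSums(x$counts[, sel_b, drop = FALSE]) == 0))
    np_stop("group '", group_b, "' has all-zero libraries")
  sel <- c(sel_a, sel_b)
  pseudo <- pseudo_counts(x$counts[, sel, drop = FALSE], eff[sel])
  ia <- seq_along(sel_a); ib <- length(sel_a) + seq_along(sel_b)
  phi <- pooled_dispersion(pseudo, list(ia, ib))
  ta <- rowSums(pseudo[, ia, drop = FALSE])
  tb <- rowSums(pseudo[, ib, drop = FALSE])
  na <- length(ia); nb <- length(ib)
  ## genes sharing (ta, tb) share a p-value; compute unique pairs once
  key <- paste(ta, tb)
  uk <- !duplicated(key)
  pu <- vapply(which(uk), function(i) nb_exact_p(ta[i], tb[i], na, nb, phi), 0)
  p <- stats::setNames(pu, key[uk])[key]
  mean_a <- ta / na; mean_b <- tb / nb
  res <- data.frame(gene = rownames(x$counts),
                    mean_a = mean_a, mean_b = mean_b,
                    log2fc = log2((mean_a + 0.125) / (mean_b + 0.125)),
                    pvalue = unname(p),
                    fdr = bh_adjust(unname(p)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "comparison") <- c(group_a, group_b)
  attr(res, "dispersion") <- phi
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted values (monotone in rank, `>=` raw, `<=` 1).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    np_stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Union of differentially expressed genes across comparisons
#'
#' @param results list of `de_result` data frames (one per comparison).
#' @param fdr_threshold strict FDR cutoff (a gene is called when
#'   `fdr < fdr_threshold` in at least one comparison).
#' @return A character vector of the union (lexicographic order) with
#'   attributes `per_comparison` (named list of per-comparison DEG sets) and
#'   `overlap_counts` (matrix of pairwise intersection sizes).
#' @export
deg_union <- function(results, fdr_threshold = 0.05) {
  if (length(results) == 0L) np_stop("need at least one comparison")
  sets <- lapply(results, function(r) r$gene[r$fdr < fdr_threshold])
  nm <- names(results) %||% vapply(results, function(r)
    paste(attr(r, "comparison"), collapse = "_vs_"), "")
  names(sets) <- nm
  k <- length(sets)
  ov <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k))
    ov[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  structure(lex_sort(unique(unlist(sets))),
            per_comparison = sets, overlap_counts = ov)
}

#' Run the differential-expression stage for all case groups vs control
#'
#' @param x a [count_matrix()] (all-zero rows are removed first).
#' @param control_label the control group label.
#' @param fdr_threshold strict FDR cutoff for the DEG union.
#' @return A list: `results` (named list of `de_result`), `factors`,
#'   `deg_union`.
#' @export
run_dge <- function(x, control_label, fdr_threshold = 0.05) {
  x <- filter_all_zero(x)
  cases <- setdiff(unique(x$groups), control_label)
  if (length(cases) == 0L) np_stop("no case group besides '", control_label, "'")
  factors <- tmm_factors(x)
  results <- lapply(cases, function(g)
    nb_exact_test(x, g, control_label, factors))
  names(results) <- paste0(cases, "_vs_", control_label)
  list(results = results, factors = factors,
       deg_union = deg_union(results, fdr_threshold))
}
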