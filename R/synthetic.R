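## Fully synthetic study generator. Counts follow a negative-binomial model
## (var = mu + phi * mu^2) with planted differentially expressed genes in two
## case groups versus control; the interaction network is an Erdos-Renyi
## background with planted dense modules whose members are drawn from the
## planted DE genes, a subset of which are flagged as "known" disease genes
## and a disjoint subset withheld as "hidden" disease genes for recovery
## experiments.

#' Specification of a synthetic study
#'
#' Defaults define the package's reference scenario: a three-group design
#' (control and two case groups, as in a Crohn's-disease / ulcerative-colitis
#' style cohort), 4000 genes with log-normal baseline expression,
#' NB dispersion 0.1, 15% of genes differentially expressed per case group at
#' |log2 fold-change| 2 with half of each group's DE genes shared between the
#' two groups; a network of 20 planted 10-node modules (within-module edge
#' probability 0.8) whose members are planted DE genes, over an 800-node
#' Erdos-Renyi background at edge probability 0.015; the first 8 modules are
#' "disease" modules carrying 5 known and 3 hidden disease genes each.
#' Module-edge confidences are Beta(8, 2); background confidences are a
#' bimodal mixture of a diffuse Beta(2, 4) bulk and a 15% Beta(12, 2)
#' high-confidence component, so that confidence thresholds separate signal
#' from noise without being clean-cut and a periphery of non-DE genes
#' survives filtering, keeping the known-gene fraction of the network
#' realistically small.
#'
#' @param n_genes number of genes in the count matrix.
#' @param n_samples_per_group named integer vector of group sizes; the first
#'   group is the control. Two-group designs are accepted.
#' @param nb_dispersion NB dispersion phi >= 0 (phi = 0 gives Poisson counts).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of per-gene
#'   baseline mean expression.
#' @param de_fraction fraction of genes differentially expressed in each case
#'   group.
#' @param de_shared_fraction fraction of each case group's DE genes shared
#'   with the other case group.
#' @param de_log2fc absolute log2 fold-change of DE genes (sign random).
#' @param n_background_nodes network nodes outside planted modules.
#' @param planted_modules data.frame with columns `size` and `intra_prob`.
#' @param n_disease_modules number of leading modules that carry disease genes.
#' @param known_disease_per_module,hidden_disease_per_module counts of known /
#'   hidden disease genes planted per disease module (disjoint sets).
#' @param module_conf_shape1,module_conf_shape2 Beta parameters of
#'   within-module edge confidences.
#' @param background_conf_shape1,background_conf_shape2 Beta parameters of
#'   background edge confidences.
#' @param background_edge_prob Erdos-Renyi edge probability.
#' @param rng_seed integer seed making both generators deterministic.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 4000L,
                            n_samples_per_group = c(control = 6L, CD = 6L, UC = 6L),
                            nb_dispersion = 0.1,
                            baseline_meanlog = log(50),
                            baseline_sdlog = 1,
                            de_fraction = 0.15,
                            de_shared_fraction = 0.5,
                            de_log2fc = 2,
                            n_background_nodes = 800L,
                            background_edge_prob = 0.015,
                            planted_modules = data.frame(size = rep(10L, 20L),
                                                         intra_prob = 0.8),
                            n_disease_modules = 8L,
                            known_disease_per_module = 5L,
                            hidden_disease_per_module = 3L,
                            module_conf_shape1 = 8,
                            module_conf_shape2 = 2,
                            background_conf_shape1 = 2,
                            background_conf_shape2 = 4,
                            background_highconf_weight = 0.15,
                            background_highconf_shape1 = 12,
                            background_highconf_shape2 = 2,
                            rng_seed = 1L) {
  if (nb_dispersion < 0) np_stop("nb_dispersion must be >= 0")
  if (length(n_samples_per_group) < 2L || is.null(names(n_samples_per_group)))
    np_stop("n_samples_per_group must be a named vector with >= 2 groups")
  if (any(planted_modules$size < 3L)) np_stop("module sizes must be >= 3")
  probs <- c(de_fraction, de_shared_fraction, background_edge_prob,
             planted_modules$intra_prob)
  if (any(probs < 0) || any(probs > 1)) np_stop("probabilities must be in [0, 1]")
  if (n_disease_modules > nrow(planted_modules))
    np_stop("n_disease_modules exceeds the number of planted modules")
  if (known_disease_per_module + hidden_disease_per_module >
      min(planted_modules$size[seq_len(max(n_disease_modules, 1L))]))
    np_stop("known + hidden disease genes exceed the disease module size")
  structure(as.list(environment()), class = "simulation_spec")
}

#' Simulate a count matrix with planted differential expression
#'
#' Counts are drawn NB(mu, phi) with variance mu + phi mu^2; a DE gene's mean
#' in its case group is the baseline multiplied by `2^(s * de_log2fc)` with
#' random sign `s`. Comparisons are each case group versus the first
#' (control) group.
#'
#' @param spec a [simulation_spec()].
#' @return A list: `counts` (a [count_matrix()]) and `truth` (per-comparison
#'   DE gene sets, their union, and per-gene signed log2 fold-changes).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(derive_seed(spec$rng_seed, 1L))
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  groups_n <- spec$n_samples_per_group
  group_names <- names(groups_n)
  samples <- unlist(lapply(group_names, function(g)
    sprintf("%s_s%02d", g, seq_len(groups_n[[g]]))))
  group_of <- rep(group_names, times = as.integer(groups_n))
  names(group_of) <- samples

  mu0 <- stats::rlnorm(spec$n_genes, spec$baseline_meanlog, spec$baseline_sdlog)
  names(mu0) <- genes

  case_groups <- group_names[-1L]
  n_de <- round(spec$de_fraction * spec$n_genes)
  n_shared <- round(spec$de_shared_fraction * n_de)
  shared <- if (n_shared > 0L) sample(genes, n_shared) else character(0)
  de_sets <- list(); lfc <- list()
  pool <- setdiff(genes, shared)
  for (g in case_groups) {
    extra <- if (n_de - n_shared > 0L) sample(pool, n_de - n_shared) else character(0)
    pool <- setdiff(pool, extra)
    de <- c(shared, extra)
    de_sets[[g]] <- lex_sort(de)
    fc <- sample(c(-1, 1), length(de), replace = TRUE) * spec$de_log2fc
    lfc[[g]] <- stats::setNames(fc, de)
  }

  counts <- matrix(0L, spec$n_genes, length(samples),
                   dimnames = list(genes, samples))
  phi <- spec$nb_dispersion
  for (g in group_names) {
    mu <- mu0
    if (g %in% case_groups && length(de_sets[[g]]) > 0L)
      mu[de_sets[[g]]] <- mu[de_sets[[g]]] * 2^lfc[[g]][de_sets[[g]]]
    idx <- which(group_of == g)
    for (j in idx) {
      counts[, j] <- if (phi == 0) stats::rpois(spec$n_genes, mu)
                     else stats::rnbinom(spec$n_genes, size = 1 / phi, mu = mu)
    }
  }

  truth <- list(de_genes = de_sets,
                de_union = lex_sort(unique(unlist(de_sets))),
                log2fc = lfc)
  list(counts = count_matrix(counts, group_of), truth = truth)
}

#' Simulate a scored interaction network with planted modules
#'
#' Planted module members are sampled from the planted DE genes recorded in
#' `truth` (so that, downstream, modules survive category-aware edge
#' filtering); background nodes are sampled from the remaining genes.
#' Within-module node pairs receive an edge with the module's `intra_prob`,
#' all other pairs with `background_edge_prob`. Disease modules have
#' `known_disease_per_module` members labelled as known disease genes and a
#' disjoint `hidden_disease_per_module` members recorded only in the truth.
#'
#' @param spec a [simulation_spec()].
#' @param truth the `truth` element of [simulate_counts()], or `NULL` for a
#'   standalone network over synthetic node ids `n0001...`.
#' @return A list: `edges` (a [scored_edges()] data frame), and `truth` with
#'   `module_members` (list of character vectors), `known_disease_genes` and
#'   `hidden_disease_genes`.
#' @export
simulate_network <- function(spec, truth = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(derive_seed(spec$rng_seed, 2L))
  mods <- spec$planted_modules
  n_module_nodes <- sum(mods$size)
  if (is.null(truth)) {
    nodes <- sprintf("n%04d", seq_len(n_module_nodes + spec$n_background_nodes))
    module_pool <- nodes
    rest_pool <- nodes
  } else {
    if (length(truth$de_union) < n_module_nodes)
      np_stop("not enough planted DE genes (", length(truth$de_union),
              ") for ", n_module_nodes, " module member slots")
    module_pool <- truth$de_union
    rest_pool <- NULL # filled below
  }

  ## disjoint module memberships
  picked <- sample(module_pool, n_module_nodes)
  module_members <- split(picked, rep(seq_len(nrow(mods)), times = mods$size))
  module_members <- lapply(module_members, lex_sort)
  names(module_members) <- sprintf("module_%02d", seq_len(nrow(mods)))

  if (is.null(truth)) {
    background <- setdiff(module_pool, picked)
    nodes <- lex_sort(c(picked, background))
  } else {
    rest_pool <- setdiff(sprintf("g%04d", seq_len(spec$n_genes)), picked)
    background <- sample(rest_pool, min(spec$n_background_nodes, length(rest_pool)))
    nodes <- lex_sort(c(picked, background))
  }

  known <- character(0); hidden <- character(0)
  for (m in seq_len(spec$n_disease_modules)) {
    mem <- sample(module_members[[m]])
    known <- c(known, mem[seq_len(spec$known_disease_per_module)])
    hidden <- c(hidden, mem[spec$known_disease_per_module +
                            seq_len(spec$hidden_disease_per_module)])
  }
  known <- lex_sort(known); hidden <- lex_sort(hidden)

  n <- length(nodes)
  idx_of <- stats::setNames(seq_len(n), nodes)
  ## module edges
  ea <- character(0); eb <- character(0); conf <- numeric(0)
  in_module_pair <- new.env(hash = TRUE)
  for (m in seq_len(nrow(mods))) {
    mem <- module_members[[m]]
    pr <- t(utils::combn(mem, 2L))
    keep <- stats::runif(nrow(pr)) < mods$intra_prob[m]
    for (k in seq_len(nrow(pr))) # mark every within-module pair, kept or not
      assign(paste(pr[k, 1L], pr[k, 2L], sep = "\r"), TRUE, envir = in_module_pair)
    if (any(keep)) {
      ea <- c(ea, pr[keep, 1L]); eb <- c(eb, pr[keep, 2L])
      conf <- c(conf, stats::rbeta(sum(keep), spec$module_conf_shape1,
                                   spec$module_conf_shape2))
    }
  }
  ## background Erdos-Renyi over all node pairs not internal to a module
  if (spec$background_edge_prob > 0 && n >= 2L) {
    n_draw <- stats::rbinom(1L, n * (n - 1L) / 2L, spec$background_edge_prob)
    if (n_draw > 0L) {
      pair_idx <- sample.int(n * (n - 1L) / 2L, n_draw)
      ## map linear index of the upper triangle to (i, j), i < j
      j <- ceiling((1 + sqrt(1 + 8 * pair_idx)) / 2)
      i <- pair_idx - (j - 1) * (j - 2) / 2
      a <- nodes[i]; b <- nodes[j]
      is_mod <- vapply(seq_along(a), function(k)
        exists(paste(min(a[k], b[k]), max(a[k], b[k]), sep = "\r"),
               envir = in_module_pair, inherits = FALSE), FALSE)
      a <- a[!is_mod]; b <- b[!is_mod]
      if (length(a) > 0L) {
        ea <- c(ea, a); eb <- c(eb, b)
        ## bimodal background confidences: a diffuse bulk plus a small
        ## high-confidence component, so some non-DE genes enter the
        ## filtered network as a realistic OG periphery
        hi <- stats::runif(length(a)) < spec$background_highconf_weight
        cf <- stats::rbeta(length(a), spec$background_conf_shape1,
                           spec$background_conf_shape2)
        if (any(hi))
          cf[hi] <- stats::rbeta(sum(hi), spec$background_highconf_shape1,
                                 spec$background_highconf_shape2)
        conf <- c(conf, cf)
      }
    }
  }
  edges <- if (length(ea) > 0L) scored_edges(ea, eb, conf) else
    structure(data.frame(gene_a = character(0), gene_b = character(0),
                         confidence = numeric(0)),
              class = c("scored_edges", "data.frame"))
  truth_out <- c(truth %||% list(),
                 list(module_members = module_members,
                      known_disease_genes = known,
                      hidden_disease_genes = hidden,
                      network_nodes = nodes))
  list(edges = edges, truth = truth_out)
}

#' Simulate a complete study (counts, network, gene lists)
#'
#' Convenience wrapper running [simulate_counts()] then [simulate_network()]
#' with a shared truth record.
#'
#' @param spec a [simulation_spec()].
#' @return A list: `counts`, `edges`, `known` (character vector of known
#'   disease genes) and `truth`.
#' @export
simulate_study <- function(spec = simulation_spec()) {
  cm <- simulate_counts(spec)
  net <- simulate_network(spec, cm$truth)
  list(counts = cm$counts, edges = net$edges,
       known = net$truth$known_disease_genes, truth = net$truth)
}

#' Write a simulated study to a directory as plain TSV/TXT files
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             groups = file.path(dir, "groups.tsv"),
             edges = file.path(dir, "edges.tsv"),
             known = file.path(dir, "known_genes.txt"),
             hidden = file.path(dir, "hidden_genes.txt"),
             modules = file.path(dir, "module_members.tsv"))
  write_counts(sim$counts, paths["counts"], paths["groups"])
  write_edges(sim$edges, paths["edges"])
  write_gene_list(sim$known, paths["known"])
  write_gene_list(sim$truth$hidden_disease_genes, paths["hidden"])
  mm <- sim$truth$module_members
  utils::write.table(
    data.frame(module = rep(names(mm), lengths(mm)), gene = unlist(mm)),
    paths["modules"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
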