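## Readers and writers for the plain-text interchange formats used by the
## pipeline: a gene x sample count TSV plus a sample/group TSV, a scored
## edge TSV, one-gene-per-line lists, GMT annotation maps and a flat
## key=value run configuration.

#' Construct a count matrix with sample group labels
#'
#' @param counts integer matrix, genes in rows and samples in columns, with
#'   row and column names.
#' @param groups named character vector mapping every sample (names) to its
#'   group label.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `groups` (named character vector aligned to the
#'   matrix columns).
#' @export
count_matrix <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    np_stop("count matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    np_stop("duplicate gene id: ",
            rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    np_stop("duplicate sample id: ",
            colnames(counts)[duplicated(colnames(counts))][1])
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    np_stop("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  groups <- groups[colnames(counts)]
  if (any(is.na(groups)))
    np_stop("sample without a group label: ",
            paste(setdiff(colnames(counts), names(groups)), collapse = ", "))
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L))
    np_stop("need >= 2 groups with >= 2 samples each")
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Read a count matrix and its sample groups
#'
#' The counts file is a TSV whose first column holds gene ids and whose
#' header row holds sample ids; the groups file is a two-column TSV
#' (sample, group) with or without a header. All-zero rows are retained
#' (removal is an explicit analysis step, [filter_all_zero()]).
#'
#' @param counts_path path to the counts TSV.
#' @param groups_path path to the sample/group TSV.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, groups_path) {
  df <- utils::read.delim(counts_path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) np_stop(counts_path, ": expected gene id column plus samples")
  gene_ids <- df[[1L]]
  if (anyDuplicated(gene_ids))
    np_stop(counts_path, ": duplicate gene id '",
            gene_ids[duplicated(gene_ids)][1], "'")
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    np_stop(counts_path, ": non-integer or negative count '",
            body[bad[1L, 1L], bad[1L, 2L]], "' at gene ", gene_ids[bad[1L, 1L]],
            ", sample ", colnames(df)[-1L][bad[1L, 2L]])
  counts <- num
  dimnames(counts) <- list(gene_ids, colnames(df)[-1L])
  groups <- read_groups(groups_path)
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing) > 0L)
    np_stop(groups_path, ": no group label for sample(s) ",
            paste(missing, collapse = ", "))
  count_matrix(counts, groups)
}

read_groups <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) < 2L) np_stop(path, ": expected two columns (sample, group)")
  if (identical(tolower(df[1L, 1L]), "sample")) df <- df[-1L, , drop = FALSE]
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write a count matrix (and optionally its groups file)
#'
#' @param x a [count_matrix()].
#' @param counts_path output TSV path.
#' @param groups_path optional output path for the sample/group TSV.
#' @export
write_counts <- function(x, counts_path, groups_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(groups_path))
    utils::write.table(
      data.frame(sample = names(x$groups), group = unname(x$groups)),
      groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' Construct a scored undirected edge list
#'
#' Self-loops are dropped (with a message) and duplicate records of the same
#' unordered pair are collapsed keeping the maximum confidence.
#'
#' @param gene_a,gene_b character vectors of interactor ids.
#' @param confidence numeric in \[0, 1\].
#' @return A `data.frame` of class `scored_edges` with columns `gene_a`,
#'   `gene_b` (lexicographically ordered within each row) and `confidence`.
#' @export
scored_edges <- function(gene_a, gene_b, confidence) {
  gene_a <- as.character(gene_a); gene_b <- as.character(gene_b)
  confidence <- as.numeric(confidence)
  if (any(is.na(confidence)) || any(confidence < 0) || any(confidence > 1))
    np_stop("confidence must lie in [0, 1]")
  loops <- gene_a == gene_b
  if (any(loops)) {
    np_msg(sum(loops), " self-loop(s) dropped")
    gene_a <- gene_a[!loops]; gene_b <- gene_b[!loops]
    confidence <- confidence[!loops]
  }
  a <- pmin(gene_a, gene_b); b <- pmax(gene_a, gene_b)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    conf <- tapply(confidence, key, max)
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]
    confidence <- as.numeric(conf[paste(a, b, sep = "\r")])
  }
  ord <- lex_order(paste(a, b, sep = "\r"))
  structure(data.frame(gene_a = a[ord], gene_b = b[ord],
                       confidence = confidence[ord],
                       stringsAsFactors = FALSE),
            class = c("scored_edges", "data.frame"))
}

#' Read a scored edge list TSV
#'
#' Columns are gene_a, gene_b, confidence; a header row is detected by a
#' non-numeric third field.
#'
#' @param path TSV path.
#' @return A [scored_edges()] data frame.
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) < 3L) np_stop(path, ": expected columns gene_a, gene_b, confidence")
  if (is.na(suppressWarnings(as.numeric(df[1L, 3L]))))
    df <- df[-1L, , drop = FALSE]
  if (nrow(df) == 0L) np_stop(path, ": no edges")
  conf <- suppressWarnings(as.numeric(df[[3L]]))
  bad <- which(is.na(conf) | conf < 0 | conf > 1)
  if (length(bad) > 0L)
    np_stop(path, ": line ", bad[1L], ": confidence '", df[bad[1L], 3L],
            "' outside [0, 1]")
  scored_edges(df[[1L]], df[[2L]], conf)
}

#' Write a scored edge list TSV
#' @param x a [scored_edges()] data frame.
#' @param path output path.
#' @export
write_edges <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one id per line; blank lines skipped)
#'
#' @param path file path.
#' @param label free-text label attached to the list.
#' @return A character vector of unique ids with attribute `label`.
#' @export
read_gene_list <- function(path, label = basename(path)) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (length(x) == 0L) np_stop(path, ": empty gene list")
  structure(unique(x), label = label)
}

#' Write a gene list, one id per line
#' @param genes character vector.
#' @param path output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read a gene-to-term annotation map
#'
#' Accepts GMT (`term<TAB>description<TAB>gene1<TAB>gene2...`) or a plain
#' two-column TSV (`gene<TAB>term`).
#'
#' @param path file path.
#' @param format `"gmt"` or `"two_column"`; `"auto"` treats files whose lines
#'   all have exactly two fields as two-column.
#' @return A list with `term_of` (named list: gene -> character vector of
#'   terms) and `term_names` (named character: term -> display name).
#' @export
read_annotation_map <- function(path, format = c("auto", "gmt", "two_column")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) np_stop(path, ": empty annotation file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "auto")
    format <- if (all(lengths(fields) == 2L)) "two_column" else "gmt"
  term_of <- list(); term_names <- character(0)
  if (format == "gmt") {
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) < 3L)
        np_stop(path, ": line ", i, ": GMT record needs term, description ",
                "and at least one gene")
      term <- f[1L]
      term_names[term] <- f[2L]
      for (g in unique(f[-c(1L, 2L)]))
        term_of[[g]] <- union(term_of[[g]], term)
    }
  } else {
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) != 2L)
        np_stop(path, ": line ", i, ": expected gene<TAB>term")
      term_of[[f[1L]]] <- union(term_of[[f[1L]]], f[2L])
      if (is.na(term_names[f[2L]])) term_names[f[2L]] <- f[2L]
    }
    term_names <- term_names[!is.na(names(term_names))]
  }
  list(term_of = term_of, term_names = term_names)
}

#' Default run configuration
#'
#' Defaults follow the published analysis settings: FDR threshold 0.05 for
#' differential expression, the per-pair-type confidence thresholds used to
#' assemble the disease-relevant network, a clustering density grid of
#' 0.1-0.9 in steps of 0.1 with cluster property threshold 0.5, prediction
#' alpha 0.05, base-10 significance scores, and a genome size of 20000 for
#' hypergeometric validation.
#'
#' @param ... named overrides of any default field.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    fdr_threshold = 0.05,
    pair_type_thresholds = default_pair_thresholds(),
    density_grid = seq(0.1, 0.9, by = 0.1),
    cp_threshold = 0.5,
    alpha_predict = 0.05,
    sscore_log_base = 10,
    genome_size_for_validation = 20000,
    rng_seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    np_stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  th <- cfg$pair_type_thresholds
  if (any(th < 0) || any(th > 1)) np_stop("pair-type thresholds must be in [0, 1]")
  dg <- cfg$density_grid
  if (any(dg <= 0) || any(dg > 1) || is.unsorted(dg, strictly = TRUE))
    np_stop("density_grid must be strictly increasing values in (0, 1]")
  if (cfg$alpha_predict <= 0 || cfg$alpha_predict >= 1)
    np_stop("alpha_predict must be in (0, 1)")
  structure(cfg, class = "run_config")
}

#' Read a flat key=value run configuration file
#'
#' Recognized keys are the fields of [default_run_config()]. Values with
#' commas are parsed as numeric vectors; `pair_type_thresholds` uses the
#' form `IDEG-IDEG:0.1,IDEG-ODEG:0.1,...`. Unknown keys are an error.
#'
#' @param path config file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  over <- list()
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[i], "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      np_stop(path, ": line ", i, ": expected key=value, got '", lines[i], "'")
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    over[[key]] <- if (key == "pair_type_thresholds") {
      parts <- strsplit(strsplit(val, ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
      stats::setNames(vapply(parts, function(p) as.numeric(p[2L]), 0),
                      vapply(parts, `[`, "", 1L))
    } else if (grepl(",", val, fixed = TRUE)) {
      as.numeric(strsplit(val, ",", fixed = TRUE)[[1L]])
    } else if (!is.na(suppressWarnings(as.numeric(val)))) {
      as.numeric(val)
    } else val
  }
  do.call(default_run_config, over)
}
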