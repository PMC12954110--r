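#' Construct a labeled single-cell dataset
#'
#' Bundles a cells x genes count matrix with per-cell cluster labels (from
#' any upstream community-detection step) and, optionally, per-cell ground
#' truth labels for evaluation.
#'
#' @param counts cells x genes non-negative count matrix (base matrix or
#'   `Matrix` sparse matrix); column names are gene identifiers, row names
#'   cell identifiers (generated when absent).
#' @param cluster_labels per-cell cluster labels, length `nrow(counts)`.
#' @param truth_labels optional per-cell ground-truth labels.
#' @return an object of class `"labeled_dataset"` with fields `counts`,
#'   `cluster`, `truth`.
#' @export
labeled_dataset <- function(counts, cluster_labels, truth_labels = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("gene%04d", seq_len(ncol(counts)))
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("cell%05d", seq_len(nrow(counts)))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("gene identifiers must be distinct", call. = FALSE)
  }
  cluster_labels <- as.character(cluster_labels)
  if (length(cluster_labels) != nrow(counts)) {
    stop("cluster_labels must have one entry per cell", call. = FALSE)
  }
  sizes <- table(cluster_labels)
  if (any(sizes < 2L)) {
    stop("every cluster needs >= 2 cells (offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), ")", call. = FALSE)
  }
  if (!is.null(truth_labels)) {
    truth_labels <- as.character(truth_labels)
    if (length(truth_labels) != nrow(counts)) {
      stop("truth_labels must have one entry per cell", call. = FALSE)
    }
  }
  structure(list(counts = counts, cluster = cluster_labels,
                 truth = truth_labels),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled dataset:", nrow(x$counts), "cells x", ncol(x$counts),
      "genes,", length(unique(x$cluster)), "clusters",
      if (!is.null(x$truth))
        paste0("(", length(unique(x$truth)), " truth labels)") else "",
      "\n")
  invisible(x)
}

#' Library-size log-normalization
#'
#' Scales each cell's counts to the median library size of the dataset and
#' applies `log1p`. Deterministic; cells with a zero total count are an
#' error.
#'
#' @param x a `"labeled_dataset"` or a cells x genes count matrix.
#' @return cells x genes matrix of log-normalized expression.
#' @export
lognormalize <- function(x) {
  counts <- if (inherits(x, "labeled_dataset")) x$counts else as.matrix(x)
  lib <- rowSums(counts)
  if (any(lib == 0)) {
    bad <- rownames(counts)[lib == 0][1L]
    stop("cell ", bad, " has zero total count; remove it before ",
         "normalization", call. = FALSE)
  }
  target <- stats::median(lib)
  log1p(counts * (target / lib))
}

## Per-gene Wilcoxon machinery shared across clusters: mid-ranks of every
## gene across all cells and the tie-correction term, computed once.
rank_matrix <- function(normed) {
  apply(normed, 2L, rank)  # mid-ranks handle ties
}

tie_term <- function(normed) {
  apply(normed, 2L, function(v) {
    t <- rle(sort(v))$lengths
    sum(t^3 - t)
  })
}

#' One-vs-rest Wilcoxon marker ranking for one cluster
#'
#' For each gene, performs a two-sample Wilcoxon rank-sum test (normal
#' approximation with tie correction, no continuity correction) of the
#' cluster's cells against all remaining cells on log-normalized expression.
#' Genes are ordered by the signed enrichment z (over-expression in the
#' cluster first); ties broken by `|log2 fold change|` descending, then by
#' gene identifier, so the ranking is total and deterministic. Reported
#' p-values are one-sided (enrichment) with Benjamini-Hochberg adjustment
#' for display; the ranking itself does not depend on the adjustment.
#'
#' @param data a `"labeled_dataset"`.
#' @param cluster_id which cluster to contrast against the rest.
#' @param normed optional precomputed [lognormalize()] matrix (to avoid
#'   recomputation across clusters).
#' @return a `data.frame` of class `"marker_table"` with columns
#'   `cluster_id`, `gene`, `score` (Wilcoxon z), `p_value`, `p_adj`,
#'   `log_fold_change`, `rank`, sorted by rank.
#' @export
rank_genes_vs_rest <- function(data, cluster_id, normed = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  cluster_id <- as.character(cluster_id)
  in_grp <- data$cluster == cluster_id
  if (!any(in_grp)) stop("unknown cluster: ", cluster_id, call. = FALSE)
  if (sum(in_grp) < 2L) {
    stop("cluster ", cluster_id, " has fewer than 2 cells", call. = FALSE)
  }
  if (!any(!in_grp)) stop("rest group is empty", call. = FALSE)
  if (is.null(normed)) normed <- lognormalize(data)
  marker_stats(normed, in_grp, cluster_id)
}

## Core rank-sum statistics given the normalized matrix and a group mask.
marker_stats <- function(normed, in_grp, cluster_id,
                         ranks = NULL, ties = NULL) {
  n <- nrow(normed)
  n1 <- sum(in_grp)
  n2 <- n - n1
  if (is.null(ranks)) ranks <- rank_matrix(normed)
  if (is.null(ties)) ties <- tie_term(normed)
  w <- colSums(ranks[in_grp, , drop = FALSE])   # rank sum in cluster
  mu <- n1 * (n + 1) / 2
  sig2 <- n1 * n2 / 12 * ((n + 1) - ties / (n * (n - 1)))
  z <- ifelse(sig2 > 0, (w - mu) / sqrt(sig2), 0)
  p <- stats::pnorm(z, lower.tail = FALSE)
  mean_in <- colMeans(normed[in_grp, , drop = FALSE])
  mean_out <- colMeans(normed[!in_grp, , drop = FALSE])
  eps <- 1e-9
  lfc <- log2((expm1(mean_in) + eps) / (expm1(mean_out) + eps))
  genes <- colnames(normed)
  ord <- order(-z, -abs(lfc), genes)
  out <- data.frame(cluster_id = cluster_id, gene = genes[ord],
                    score = z[ord], p_value = p[ord],
                    p_adj = stats::p.adjust(p, "BH")[ord],
                    log_fold_change = lfc[ord],
                    rank = seq_along(genes), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_table", "data.frame")
  out
}

#' One-vs-rest marker tables for every cluster
#'
#' Runs [rank_genes_vs_rest()] for each cluster, sharing the normalized
#' matrix and per-gene rank computations.
#'
#' @inheritParams rank_genes_vs_rest
#' @return named list of `"marker_table"` data frames, one per cluster
#'   (alphabetical order).
#' @export
rank_all_clusters <- function(data, normed = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (is.null(normed)) normed <- lognormalize(data)
  ranks <- rank_matrix(normed)
  ties <- tie_term(normed)
  ids <- sort(unique(data$cluster))
  out <- lapply(ids, function(id) {
    marker_stats(normed, data$cluster == id, id, ranks = ranks, ties = ties)
  })
  names(out) <- ids
  out
}

#' Union of the top-k marker genes across clusters
#'
#' The global marker set: the union of each cluster's first `k` ranked
#' genes. Its size lies in `[k, K * k]` for `K` clusters.
#'
#' @param tables list of `"marker_table"` data frames.
#' @param k number of top genes taken from each cluster.
#' @return character vector of gene identifiers (order of first appearance).
#' @export
top_k_union <- function(tables, k) {
  if (length(tables) == 0L) stop("no marker tables supplied", call. = FALSE)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  tops <- lapply(tables, function(tb) {
    if (k > nrow(tb)) {
      stop("k = ", k, " exceeds the ", nrow(tb), "-gene universe",
           call. = FALSE)
    }
    tb$gene[seq_len(k)]
  })
  unique(unlist(tops, use.names = FALSE))
}

#' Per-cluster rankings restricted to the global marker set
#'
#' Orders the union genes by each cluster's own full differential-expression
#' ranking, preserving relative order, so every cluster gets an equal-length
#' ranked list over the same universe — the input to [pairwise_ao()].
#'
#' @param tables named list of `"marker_table"` data frames.
#' @param union gene identifiers (subset of every table's universe).
#' @return named list of [ranked_list] objects, all of length
#'   `length(union)`.
#' @export
rankings_on_union <- function(tables, union) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (is.null(names(tables))) {
    names(tables) <- vapply(tables, function(tb) tb$cluster_id[1L],
                            character(1))
  }
  union <- unique(as.character(union))
  lapply(tables, function(tb) {
    missing <- setdiff(union, tb$gene)
    if (length(missing) > 0L) {
      stop("union gene(s) absent from cluster ", tb$cluster_id[1L],
           "'s table: ", paste(utils::head(missing, 3L), collapse = ", "),
           call. = FALSE)
    }
    ranked_list(tb$gene[tb$gene %in% union])
  })
}

#' Write marker tables to a CSV file
#'
#' @param tables list of `"marker_table"` data frames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_tables <- function(tables, path) {
  df <- do.call(rbind, lapply(tables, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read marker tables from a CSV file written by [write_marker_tables()]
#'
#' @param path input path.
#' @return named list of `"marker_table"` data frames.
#' @export
read_marker_tables <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$cluster_id), function(d) {
    d <- d[order(d$rank), , drop = FALSE]
    rownames(d) <- NULL
    class(d) <- c("marker_table", "data.frame")
    d
  })
  out[order(names(out))]
}
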