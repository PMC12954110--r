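## Contingency table machinery shared by the agreement indices.
pair_counts <- function(truth, pred) {
  tab <- table(truth, pred)
  n <- sum(tab)
  list(tab = tab, n = n,
       sum_ij = sum(choose(tab, 2)),
       sum_a = sum(choose(rowSums(tab), 2)),
       sum_b = sum(choose(colSums(tab), 2)))
}

adjusted_rand <- function(pc) {
  expected <- pc$sum_a * pc$sum_b / choose(pc$n, 2)
  denom <- (pc$sum_a + pc$sum_b) / 2 - expected
  if (abs(denom) < .Machine$double.eps) return(1)
  (pc$sum_ij - expected) / denom
}

fowlkes_mallows <- function(pc) {
  if (pc$sum_a == 0 || pc$sum_b == 0) {
    return(if (pc$sum_a == pc$sum_b) 1 else 0)
  }
  pc$sum_ij / sqrt(pc$sum_a * pc$sum_b)
}

entropy_counts <- function(cnt) {
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log(p))
}

mutual_information <- function(tab) {
  n <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      nij <- tab[i, j]
      if (nij > 0) mi <- mi + nij / n * log(n * nij / (a[i] * b[j]))
    }
  }
  unname(mi)
}

## Expected mutual information under the permutation (hypergeometric) model.
expected_mutual_information <- function(tab) {
  n <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (lo > hi) next
      nij <- lo:hi
      term <- nij / n * log(n * nij / (ai * bj))
      lp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
        lgamma(n - bj + 1) - lgamma(n + 1) - lgamma(nij + 1) -
        lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
        lgamma(n - ai - bj + nij + 1)
      emi <- emi + sum(term * exp(lp))
    }
  }
  emi
}

adjusted_mutual_information <- function(tab) {
  hu <- entropy_counts(rowSums(tab))
  hv <- entropy_counts(colSums(tab))
  if (hu == 0 && hv == 0) return(1)   # both partitions trivial and equal
  mi <- mutual_information(tab)
  emi <- expected_mutual_information(tab)
  denom <- (hu + hv) / 2 - emi        # arithmetic-mean normalization
  if (abs(denom) < .Machine$double.eps) return(1)
  (mi - emi) / denom
}

#' Partition agreement metrics: ARI, AMI and FMS
#'
#' Computes the adjusted Rand index (pair counting, chance-adjusted),
#' adjusted mutual information (arithmetic-mean normalization, chance-
#' adjusted under the hypergeometric permutation model) and the
#' Fowlkes-Mallows score (geometric mean of pairwise precision and recall)
#' between two labelings of the same cells. All three are invariant to
#' renaming labels and equal 1 when the partitions coincide.
#'
#' @param truth,pred label vectors of equal length.
#' @return named numeric vector `c(ari, ami, fms)`.
#' @export
agreement_metrics <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length", call. = FALSE)
  }
  pc <- pair_counts(truth, pred)
  c(ari = adjusted_rand(pc),
    ami = adjusted_mutual_information(pc$tab),
    fms = fowlkes_mallows(pc))
}

#' Average cluster purity
#'
#' For each predicted cluster, the fraction of its cells carrying the
#' cluster's majority ground-truth label. By default clusters are weighted
#' by size (the result is then the overall fraction of cells whose cluster
#' majority matches their truth label); `weighted = FALSE` averages the
#' per-cluster purities uniformly.
#'
#' @param truth,pred label vectors of equal length.
#' @param weighted cell-weighted (default) or unweighted mean over clusters.
#' @return purity in `(0, 1]`.
#' @export
average_cluster_purity <- function(truth, pred, weighted = TRUE) {
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length", call. = FALSE)
  }
  tab <- table(pred, truth)
  per_cluster <- apply(tab, 1L, max) / rowSums(tab)
  if (weighted) {
    sum(apply(tab, 1L, max)) / sum(tab)
  } else {
    mean(per_cluster)
  }
}

## Log-normalize and standardize each gene to zero mean / unit variance
## across cells; zero-variance genes are dropped with a warning.
standardized_expression <- function(data) {
  normed <- lognormalize(data)
  v <- apply(normed, 2L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped before ",
            "standardization", call. = FALSE)
    normed <- normed[, v > 0, drop = FALSE]
  }
  scale(normed)
}

## Majority-truth population of each predicted cluster; ties go to the
## larger truth population, then lexicographically.
majority_truth <- function(truth, pred) {
  tab <- table(pred, truth)
  truth_sizes <- colSums(tab)
  vapply(rownames(tab), function(cl) {
    counts <- tab[cl, ]
    top <- names(counts)[counts == max(counts)]
    if (length(top) > 1L) {
      top <- top[order(-truth_sizes[top], top)]
    }
    top[1L]
  }, character(1))
}

#' Centroid expression distance between merged clusters and truth
#'
#' Log-normalizes the counts, standardizes every gene to zero mean and unit
#' variance across cells, matches each merged cluster to its majority
#' ground-truth population, and returns the Euclidean distances between the
#' matched centroid expression vectors (and their mean). Perfect recovery of
#' the truth partition gives all-zero distances.
#'
#' @param data a `"labeled_dataset"` with `truth` labels.
#' @param merged per-cell merged cluster labels.
#' @return list with `per_cluster` (named distances), `mean`, and
#'   `matching` (cluster -> truth population).
#' @export
centroid_expression_distance <- function(data, merged) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (is.null(data$truth)) {
    stop("centroid distances require ground-truth labels", call. = FALSE)
  }
  merged <- as.character(merged)
  if (length(merged) != nrow(data$counts)) {
    stop("merged labels must have one entry per cell", call. = FALSE)
  }
  z <- standardized_expression(data)
  centroid <- function(labels) {
    ids <- sort(unique(labels))
    t(vapply(ids, function(id)
      colMeans(z[labels == id, , drop = FALSE]), numeric(ncol(z))))
  }
  cl_cent <- centroid(merged)
  tr_cent <- centroid(data$truth)
  match_to <- majority_truth(data$truth, merged)
  d <- vapply(rownames(cl_cent), function(cl) {
    sqrt(sum((cl_cent[cl, ] - tr_cent[match_to[cl], ])^2))
  }, numeric(1))
  list(per_cluster = d, mean = mean(d), matching = match_to)
}

#' Baseline cluster-distance matrices
#'
#' Builds the K x K distance matrix between clusters for any of the
#' benchmarked metrics. Correlation metrics (`pearson`, `spearman`,
#' `kendall`) and `euclidean` act on cluster-level feature vectors: the
#' mean log-normalized expression of the global top-`n_markers` marker-gene
#' union per cluster (`features = "marker_expression"`), or the cluster
#' means of cell scores on the first `n_pcs` principal components of the
#' standardized expression (`features = "principal_components"`).
#' Correlations are converted to distances as `1 - r`. `direct_overlap` is
#' the unranked set-intersection baseline `1 - |top-k(a) ∩ top-k(b)| / k`,
#' and `ao` is `1 - AO` on the union rankings; both ignore `features`.
#'
#' @param data a `"labeled_dataset"`.
#' @param tables marker tables from [rank_all_clusters()].
#' @param metric one of `"pearson"`, `"spearman"`, `"kendall"`,
#'   `"euclidean"`, `"direct_overlap"`, `"ao"`.
#' @param features `"marker_expression"` (default) or
#'   `"principal_components"` (correlation/Euclidean metrics only).
#' @param n_markers top marker genes per cluster (default 25).
#' @param n_pcs number of principal components (default 50, capped at the
#'   data's rank).
#' @param normed optional precomputed [lognormalize()] matrix.
#' @return symmetric K x K distance matrix with zero diagonal.
#' @export
baseline_distance_matrix <- function(data, tables,
                                     metric = c("pearson", "spearman",
                                                "kendall", "euclidean",
                                                "direct_overlap", "ao"),
                                     features = c("marker_expression",
                                                  "principal_components"),
                                     n_markers = 25L, n_pcs = 50L,
                                     normed = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  metric <- match.arg(metric)
  features <- match.arg(features)
  ids <- names(tables)
  k <- length(ids)

  if (metric == "direct_overlap") {
    tops <- lapply(tables, function(tb) tb$gene[seq_len(n_markers)])
    d <- matrix(0, k, k, dimnames = list(ids, ids))
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        d[i, j] <- 1 - length(intersect(tops[[i]], tops[[j]])) / n_markers
      }
    }
    diag(d) <- 0
    return(d)
  }
  if (metric == "ao") {
    union <- top_k_union(tables, n_markers)
    rankings <- rankings_on_union(tables, union)
    n <- length(union)
    sim <- matrix(1, k, k, dimnames = list(ids, ids))
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        sim[i, j] <- sim[j, i] <- average_overlap(rankings[[i]],
                                                  rankings[[j]])
      }
    }
    return(1 - sim)
  }

  if (is.null(normed)) normed <- lognormalize(data)
  feat <- if (features == "marker_expression") {
    union <- top_k_union(tables, n_markers)
    sub <- normed[, union, drop = FALSE]
    t(vapply(ids, function(id)
      colMeans(sub[data$cluster == id, , drop = FALSE]),
      numeric(length(union))))
  } else {
    z <- scale(normed)
    z <- z[, !is.nan(colSums(z)), drop = FALSE]   # zero-variance genes
    n_pcs <- min(n_pcs, nrow(z) - 1L, ncol(z))
    pcs <- stats::prcomp(z, center = FALSE, scale. = FALSE,
                         rank. = n_pcs)$x
    t(vapply(ids, function(id)
      colMeans(pcs[data$cluster == id, , drop = FALSE]), numeric(n_pcs)))
  }
  d <- if (metric == "euclidean") {
    as.matrix(stats::dist(feat))
  } else {
    1 - stats::cor(t(feat), method = metric)
  }
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  d
}

#' Stouffer's combined z-score
#'
#' Combines independent z-values as `sum(z) / sqrt(n)`.
#'
#' @param z_values numeric vector of z-scores (length >= 1).
#' @return the composite z.
#' @export
stouffer_composite <- function(z_values) {
  z_values <- as.numeric(z_values)
  if (length(z_values) < 1L) {
    stop("need at least one z-value", call. = FALSE)
  }
  sum(z_values) / sqrt(length(z_values))
}

#' Composite-z profile of a marker set across reference populations
#'
#' For annotating de novo clusters against sorted bulk populations: each
#' reference gene's expression is z-scored across populations, then the
#' marker genes' z-values are Stouffer-combined per population. High
#' composite z in a population means the marker set is specifically
#' expressed there.
#'
#' @param markers gene identifiers (a cluster's top marker genes).
#' @param reference genes x populations expression matrix with dimnames.
#' @return named numeric vector: composite z per reference population.
#' @export
score_marker_set_on_reference <- function(markers, reference) {
  reference <- as.matrix(reference)
  if (is.null(rownames(reference)) || is.null(colnames(reference))) {
    stop("reference needs gene row names and population column names",
         call. = FALSE)
  }
  sds <- apply(reference, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant reference row(s) dropped ",
            "(z-score undefined)", call. = FALSE)
    reference <- reference[sds > 0, , drop = FALSE]
  }
  present <- intersect(as.character(markers), rownames(reference))
  if (length(present) == 0L) {
    stop("no marker genes present in the reference", call. = FALSE)
  }
  z <- t(scale(t(reference[present, , drop = FALSE])))
  apply(z, 2L, stouffer_composite)
}
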