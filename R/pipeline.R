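#' Full average-overlap pipeline on a labeled dataset
#'
#' Runs the whole workflow: one-vs-rest Wilcoxon marker ranking per
#' cluster, top-`n_markers` union, per-cluster rankings over the union,
#' pairwise AO and z-scores, the AO-distance tree, and (optionally)
#' z-guided merging down to `k_target` groups.
#'
#' @param data a `"labeled_dataset"`.
#' @param n_markers top marker genes per cluster for the union (default
#'   25).
#' @param k_target target group count for merging; `NULL` skips merging.
#' @param linkage linkage for the cluster tree (default `"average"`).
#' @param m_shuffles,seed AO null-model parameters.
#' @param recompute if `TRUE`, merging recomputes markers and AO after
#'   every step ([merge_with_recompute()]) instead of following the fixed
#'   tree.
#' @return list with `tables`, `union`, `rankings`, `ao`, `tree`,
#'   `merged_labels` (or `NULL`) and `params`.
#' @export
run_ao_pipeline <- function(data, n_markers = 25L, k_target = NULL,
                            linkage = "average", m_shuffles = 1000L,
                            seed = 1L, recompute = FALSE) {
  stopifnot(inherits(data, "labeled_dataset"))
  tables <- rank_all_clusters(data)
  union <- top_k_union(tables, min(n_markers, ncol(data$counts)))
  rankings <- rankings_on_union(tables, union)
  ao <- pairwise_ao(rankings, m_shuffles = m_shuffles, seed = seed)
  tree <- if (length(tables) >= 2L) linkage_from_ao(ao, linkage) else NULL
  merged <- NULL
  if (!is.null(k_target)) {
    merged <- if (recompute) {
      merge_with_recompute(data, k_target, n_markers = n_markers,
                           m_shuffles = m_shuffles, seed = seed)
    } else {
      merge_to_k(data$cluster, tree, k_target, ao = ao)
    }
  }
  list(tables = tables, union = union, rankings = rankings, ao = ao,
       tree = tree, merged_labels = merged,
       params = list(n_markers = n_markers, k_target = k_target,
                     linkage = linkage, m_shuffles = m_shuffles,
                     seed = seed, recompute = recompute))
}

#' Evaluate merged labels against ground truth
#'
#' @param data a `"labeled_dataset"` with truth labels.
#' @param merged per-cell merged labels.
#' @param centroids include centroid expression distances (default TRUE;
#'   the slowest part on large data).
#' @return list: `ari`, `ami`, `fms`, `purity`, `centroid_distance`.
#' @export
evaluate_merge <- function(data, merged, centroids = TRUE) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (is.null(data$truth)) stop("truth labels required", call. = FALSE)
  m <- agreement_metrics(data$truth, merged)
  out <- list(ari = unname(m["ari"]), ami = unname(m["ami"]),
              fms = unname(m["fms"]),
              purity = average_cluster_purity(data$truth, merged))
  out$centroid_distance <- if (centroids) {
    centroid_expression_distance(data, merged)$mean
  } else {
    NA_real_
  }
  out
}

#' Benchmark cluster-distance metrics on simulated data
#'
#' For each seed, simulates the configured dataset, over-clusters it by
#' splitting the configured populations, then for every
#' (metric, n_markers) condition builds the cluster-distance matrix, the
#' tree, merges back to the true number of populations, and scores the
#' result against the truth. Mirrors a truth-known benchmarking harness:
#' AO and direct overlap act on marker-gene rankings/sets, the
#' correlation and Euclidean metrics on marker expression (or principal
#' components).
#'
#' @param config a `"sim_config"` (its `seed` field is overridden per
#'   run).
#' @param seeds integer vector of simulation seeds.
#' @param metrics metrics to benchmark (see
#'   [baseline_distance_matrix()]).
#' @param n_markers_values top-marker counts to sweep.
#' @param features feature space for correlation/Euclidean metrics.
#' @param linkage tree linkage.
#' @param centroids include centroid expression distances per run.
#' @return long-format `data.frame`: seed, metric, features, n_markers,
#'   ari, ami, fms, purity, centroid_distance.
#' @export
run_benchmark <- function(config = simulation_config(),
                          seeds = 1:20,
                          metrics = c("ao", "pearson", "spearman",
                                      "kendall", "euclidean",
                                      "direct_overlap"),
                          n_markers_values = 25L,
                          features = "marker_expression",
                          linkage = "average",
                          centroids = FALSE) {
  rows <- list()
  for (s in seeds) {
    cfg <- config
    cfg$seed <- as.integer(s)
    sim <- simulate_dataset(cfg)
    labels <- split_clusters(sim, seed = s + 1L)
    data <- labeled_dataset(sim$counts, labels, sim$truth)
    k_target <- length(unique(sim$truth))
    normed <- lognormalize(data)
    tables <- rank_all_clusters(data, normed = normed)
    for (metric in metrics) {
      for (nm in n_markers_values) {
        d <- baseline_distance_matrix(data, tables, metric = metric,
                                      features = features,
                                      n_markers = nm, normed = normed)
        tree <- linkage_from_distance(d, linkage)
        merged <- merge_to_k(data$cluster, tree, k_target)
        ev <- evaluate_merge(data, merged, centroids = centroids)
        rows[[length(rows) + 1L]] <- data.frame(
          seed = s, metric = metric, features = features, n_markers = nm,
          ari = ev$ari, ami = ev$ami, fms = ev$fms, purity = ev$purity,
          centroid_distance = ev$centroid_distance,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
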